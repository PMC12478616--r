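#' Enumerate all attribute mastery patterns
#'
#' Builds the ordered space of the \eqn{2^K} binary attribute mastery
#' patterns (the latent classes of a diagnostic classification model).
#' The canonical order is binary counting with attribute 1 the most
#' significant bit: class index \eqn{c = 1 + \sum_k \alpha_k 2^{K-k}}, so the
#' all-zeros pattern comes first and the all-ones pattern last.  All tables
#' in this package (ideal responses, centroids, mixing proportions, pattern
#' probabilities) are indexed in this order, and ties are always broken
#' towards the lower class index.
#'
#' @param K number of attributes (positive integer).
#' @return An integer matrix with \eqn{2^K} rows and `K` columns; row `c` is
#'   the pattern of latent class `c`.  Row names are the pattern strings
#'   (e.g. `"011"`), column names `A1..AK`.
#' @seealso [pattern_index()], [pattern_labels()], [ideal_response()]
#' @examples
#' attribute_patterns(2)
#' @export
attribute_patterns <- function(K) {
  if (length(K) != 1L || is.na(K) || K < 1 || K != round(K))
    stop("'K' must be a positive integer", call. = FALSE)
  K <- as.integer(K)
  L <- 2L^K
  pat <- matrix(0L, L, K)
  for (k in seq_len(K)) {
    # attribute k flips every 2^(K-k) rows: attribute 1 most significant
    pat[, k] <- rep(rep(c(0L, 1L), each = 2L^(K - k)), length.out = L)
  }
  dimnames(pat) <- list(apply(pat, 1L, paste, collapse = ""),
                        paste0("A", seq_len(K)))
  pat
}

#' Map attribute patterns to canonical class indices
#'
#' @param alpha a binary vector of length `K`, or an N x K binary matrix of
#'   patterns (one per row).
#' @return Integer class index (or vector of indices) in `1:2^K`, under the
#'   canonical order of [attribute_patterns()].
#' @examples
#' pattern_index(c(0, 1, 1))  # class 4 of 8
#' @export
pattern_index <- function(alpha) {
  if (is.vector(alpha)) alpha <- matrix(alpha, nrow = 1L)
  alpha <- as.matrix(alpha)
  .check_binary(alpha, "alpha")
  K <- ncol(alpha)
  as.integer(1L + alpha %*% 2L^((K - 1L):0L))
}

#' Pattern strings for class indices
#'
#' @param x integer class indices, or a binary pattern matrix.
#' @param K number of attributes (required when `x` holds indices).
#' @return Character vector of pattern strings like `"011"`.
#' @export
pattern_labels <- function(x, K = NULL) {
  if (is.matrix(x)) return(apply(x, 1L, paste, collapse = ""))
  if (is.null(K)) stop("'K' is required when 'x' holds class indices", call. = FALSE)
  rownames(attribute_patterns(K))[x]
}

#' Validate a Q-matrix
#'
#' Checks that a Q-matrix is a binary J x K incidence matrix in which every
#' item requires at least one attribute (no all-zero rows) and coerces it to
#' an integer matrix.
#'
#' @param Q a J x K matrix-like of 0/1 entries.
#' @return The validated integer matrix (invisibly usable downstream).
#' @export
validate_q <- function(Q) {
  Q <- as.matrix(Q)
  if (nrow(Q) < 1L || ncol(Q) < 1L)
    stop("Q-matrix must have at least one item and one attribute", call. = FALSE)
  .check_binary(Q, "Q")
  zero <- which(rowSums(Q) == 0)
  if (length(zero))
    stop("Q-matrix row(s) ", paste(zero, collapse = ", "),
         " are all zero: every item must require at least one attribute",
         call. = FALSE)
  storage.mode(Q) <- "integer"
  if (is.null(colnames(Q))) colnames(Q) <- paste0("A", seq_len(ncol(Q)))
  Q
}

#' Validate a binary response matrix
#'
#' @param X an N x J matrix-like of 0/1 item responses, no missing values.
#' @param J optional expected item count (e.g. `nrow(Q)`).
#' @return The validated integer matrix.
#' @export
validate_responses <- function(X, J = NULL) {
  X <- as.matrix(X)
  if (anyNA(X))
    stop("response matrix contains missing values; these are not supported",
         call. = FALSE)
  .check_binary(X, "X")
  if (!is.null(J) && ncol(X) != J)
    stop("response matrix has ", ncol(X), " items but the Q-matrix has ", J,
         call. = FALSE)
  storage.mode(X) <- "integer"
  X
}

.check_binary <- function(M, name) {
  bad <- which(!(M %in% c(0, 1)) | is.na(M))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(M)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(M)) + 1L
    stop("'", name, "' must be binary (0/1); offending value '",
         M[bad[1L]], "' at row ", i, ", column ", j, call. = FALSE)
  }
  invisible(M)
}

#' Ideal response table under the DINA or DINO rule
#'
#' The ideal response is the error-free answer a latent class would give to
#' an item.  Under the conjunctive DINA rule it is 1 iff the pattern masters
#' *all* attributes the item requires; under the disjunctive DINO rule, 1 iff
#' it masters *at least one*.
#'
#' @param Q a J x K Q-matrix (validated with [validate_q()]).
#' @param rule `"dina"` or `"dino"`.
#' @param patterns optional pattern matrix; defaults to
#'   [attribute_patterns()] on `ncol(Q)` attributes.
#' @return An integer \eqn{2^K} x J matrix; row `c`, column `j` is the ideal
#'   response of class `c` to item `j`.
#' @examples
#' Q <- rbind(c(1, 0), c(0, 1), c(1, 1))
#' ideal_response(Q, "dina")
#' ideal_response(Q, "dino")
#' @export
ideal_response <- function(Q, rule = c("dina", "dino"), patterns = NULL) {
  rule <- match.arg(rule)
  Q <- validate_q(Q)
  if (is.null(patterns)) patterns <- attribute_patterns(ncol(Q))
  if (ncol(patterns) != ncol(Q))
    stop("pattern matrix and Q-matrix disagree on the attribute count",
         call. = FALSE)
  hits <- patterns %*% t(Q)             # attributes mastered among required
  need <- matrix(colSums(t(Q)), nrow(patterns), nrow(Q), byrow = TRUE)
  eta <- if (rule == "dina") (hits == need) else (hits > 0)
  eta <- eta * 1L
  dimnames(eta) <- list(rownames(patterns), rownames(Q))
  eta
}

#' Free weight positions of the generalized ideal response
#'
#' A (class, item) position is *free* when the DINA and DINO ideals differ
#' there, i.e. the class masters some but not all attributes the item
#' requires; only there does the blending weight matter.
#'
#' @inheritParams ideal_response
#' @return A logical \eqn{2^K} x J matrix, `TRUE` at free positions.
#' @export
free_weight_mask <- function(Q, patterns = NULL) {
  ideal_response(Q, "dina", patterns) != ideal_response(Q, "dino", patterns)
}

#' Generalized ideal responses (centroids)
#'
#' Blends the conjunctive and disjunctive ideal responses into the centroid
#' \eqn{\eta_{cj}(w) = w_{cj}\,\eta^{DINA}_{cj} + (1-w_{cj})\,\eta^{DINO}_{cj}}.
#' A weight near 1 makes the item behave conjunctively (DINA-like), near 0
#' disjunctively (DINO-like).  At positions where the two ideals agree the
#' weight is irrelevant.
#'
#' @param dina,dino ideal response tables from [ideal_response()].
#' @param W a matrix of weights in \[0, 1\], same shape as the tables.
#' @return A numeric matrix of centroids in \[0, 1\].
#' @examples
#' Q <- rbind(c(1, 0), c(0, 1), c(1, 1))
#' d1 <- ideal_response(Q, "dina"); d0 <- ideal_response(Q, "dino")
#' generalized_centroid(d1, d0, matrix(0.6, 4, 3))
#' @export
generalized_centroid <- function(dina, dino, W) {
  if (!all(dim(dina) == dim(dino)) || !all(dim(dina) == dim(W)))
    stop("'dina', 'dino' and 'W' must have identical dimensions", call. = FALSE)
  if (anyNA(W) || any(W < 0 | W > 1))
    stop("weights must lie in [0, 1]", call. = FALSE)
  W * dina + (1 - W) * dino
}

#' Check monotonicity of an item response probability table
#'
#' Verifies the partial-order constraints on correct-response probabilities:
#' for every item, if pattern `a` masters (at least) every required attribute
#' that pattern `b` masters, then `a`'s probability may not be smaller than
#' `b`'s.  In particular the all-mastery classes attain the item maximum and
#' the no-required-mastery classes the minimum.
#'
#' @param theta a \eqn{2^K} x J numeric table of correct-response
#'   probabilities (rows: classes in canonical order, columns: items).
#' @param Q the J x K Q-matrix.
#' @param patterns optional pattern matrix.
#' @return A list with `ok` (logical) and `violations`, a data frame with
#'   columns `item`, `class_low`, `class_high` listing ordered class pairs
#'   whose probabilities are inverted (empty when `ok`).
#' @export
check_monotonicity <- function(theta, Q, patterns = NULL) {
  Q <- validate_q(Q)
  if (is.null(patterns)) patterns <- attribute_patterns(ncol(Q))
  L <- nrow(patterns)
  if (nrow(theta) != L || ncol(theta) != nrow(Q))
    stop("'theta' must be 2^K x J matching the Q-matrix", call. = FALSE)
  viol <- list()
  for (j in seq_len(nrow(Q))) {
    req <- which(Q[j, ] == 1)
    m <- patterns[, req, drop = FALSE]       # masked mastery on required attrs
    for (a in seq_len(L)) {
      # classes dominated by a on the required attributes must not exceed it
      dominated <- which(colSums(t(m) * m[a, ]) == rowSums(m))  # b: m_b <= m_a
      bad <- dominated[theta[dominated, j] > theta[a, j]]
      bad <- setdiff(bad, a)
      if (length(bad))
        viol[[length(viol) + 1L]] <-
          data.frame(item = j, class_low = bad, class_high = a)
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(item = integer(), class_low = integer(), class_high = integer())
  list(ok = nrow(violations) == 0L, violations = violations)
}
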