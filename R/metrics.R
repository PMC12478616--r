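#' Attribute-level agreement ratio (AAR)
#'
#' Fraction of (person, attribute, replication) triples where the estimated
#' mastery equals the truth.  Single replications may be passed as plain
#' N x K matrices; several replications as lists of matrices.
#'
#' @param estimated,truth N x K binary matrices, or lists of such matrices
#'   (one per replication, shapes matching pairwise).
#' @return A number in \[0, 1\].
#' @export
attribute_agreement <- function(estimated, truth) {
  pairs <- .as_rep_list(estimated, truth)
  eq <- vapply(pairs, function(p) c(sum(p$est == p$tru), length(p$tru)),
               numeric(2))
  sum(eq[1, ]) / sum(eq[2, ])
}

#' Pattern-level agreement ratio (PAR)
#'
#' Fraction of (person, replication) pairs whose full attribute pattern
#' matches the truth exactly.
#'
#' @inheritParams attribute_agreement
#' @return A number in \[0, 1\].
#' @export
pattern_agreement <- function(estimated, truth) {
  pairs <- .as_rep_list(estimated, truth)
  eq <- vapply(pairs, function(p)
    c(sum(rowSums(p$est != p$tru) == 0), nrow(p$tru)), numeric(2))
  sum(eq[1, ]) / sum(eq[2, ])
}

.as_rep_list <- function(estimated, truth) {
  if (!is.list(estimated)) estimated <- list(estimated)
  if (!is.list(truth)) truth <- list(truth)
  if (length(estimated) != length(truth))
    stop("'estimated' and 'truth' must have the same number of replications",
         call. = FALSE)
  mapply(function(e, t) {
    e <- as.matrix(e); t <- as.matrix(t)
    if (!all(dim(e) == dim(t)))
      stop("estimated and true pattern matrices must have identical shape",
           call. = FALSE)
    list(est = e, tru = t)
  }, estimated, truth, SIMPLIFY = FALSE)
}

#' Half-split stability correlation of MCMC attribute probabilities
#'
#' Splits the retained draws into first and second halves, estimates each
#' person's attribute mastery probabilities from each half, and correlates
#' the two estimates across persons, per attribute (Pearson).  A stable
#' chain yields correlations near 1.  Attributes whose half-estimates are
#' constant in either half have no defined correlation and are returned as
#' `NA` (to be excluded from averages), not propagated as an error.
#'
#' @param draws retained draws of per-person attribute probabilities (or
#'   mastery indicators): an array `draws x persons x attributes`, or a
#'   `draws x persons` matrix for a single attribute.  At least 4 draws are
#'   required.
#' @return A named numeric vector of per-attribute correlations (`NA` where
#'   undefined).
#' @export
half_split_correlation <- function(draws) {
  if (is.matrix(draws)) draws <- array(draws, c(dim(draws), 1L))
  if (length(dim(draws)) != 3L)
    stop("'draws' must be a draws x persons x attributes array", call. = FALSE)
  Tn <- dim(draws)[1L]
  if (Tn < 4L) stop("at least 4 retained draws are required", call. = FALSE)
  h <- Tn %/% 2L
  m1 <- apply(draws[seq_len(h), , , drop = FALSE], c(2L, 3L), mean)
  m2 <- apply(draws[(h + 1L):Tn, , , drop = FALSE], c(2L, 3L), mean)
  out <- .half_cor(m1, m2)
  names(out) <- dimnames(draws)[[3L]] %||% paste0("A", seq_along(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate attribute mastery patterns
#'
#' Counts and ratios of the \eqn{2^K} patterns in a set of classifications.
#'
#' @param x an N x K binary pattern matrix, or a vector of canonical class
#'   indices (then `K` is required).
#' @param K number of attributes when `x` holds class indices.
#' @return A data frame with columns `pattern` (string label, canonical
#'   order), `count` and `ratio`; counts sum to N, ratios to 1.
#' @export
tabulate_patterns <- function(x, K = NULL) {
  if (is.matrix(x)) {
    K <- ncol(x)
    idx <- pattern_index(x)
  } else {
    if (is.null(K)) stop("'K' is required when 'x' holds class indices", call. = FALSE)
    idx <- as.integer(x)
  }
  L <- 2L^K
  if (any(idx < 1L | idx > L)) stop("class index out of range", call. = FALSE)
  counts <- tabulate(idx, L)
  data.frame(pattern = rownames(attribute_patterns(K)),
             count = counts, ratio = counts / length(idx))
}

#' Contingency table of two pattern classifications
#'
#' Cross-tabulates the attribute mastery patterns assigned by two methods to
#' the same persons; row and column margins reproduce each method's pattern
#' counts.
#'
#' @param a,b N x K binary pattern matrices, or vectors of canonical class
#'   indices (then `K` is required).
#' @param K number of attributes when indices are given.
#' @return A \eqn{2^K} x \eqn{2^K} integer matrix, rows indexed by the
#'   patterns of `a`, columns by those of `b`.
#' @export
cross_tab <- function(a, b, K = NULL) {
  ia <- if (is.matrix(a)) pattern_index(a) else as.integer(a)
  ib <- if (is.matrix(b)) pattern_index(b) else as.integer(b)
  if (is.matrix(a)) K <- ncol(a)
  if (is.null(K)) stop("'K' is required when class indices are given", call. = FALSE)
  if (length(ia) != length(ib))
    stop("'a' and 'b' must classify the same persons", call. = FALSE)
  L <- 2L^K
  labs <- rownames(attribute_patterns(K))
  tab <- table(factor(ia, levels = seq_len(L), labels = labs),
               factor(ib, levels = seq_len(L), labels = labs))
  m <- matrix(as.integer(tab), L, L, dimnames = dimnames(tab))
  m
}
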