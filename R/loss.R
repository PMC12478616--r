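#' Element-wise loss between a response vector and a class centroid
#'
#' The three loss kinds of the unified loss-function framework:
#' \describe{
#'   \item{`hamming`}{\eqn{\sum_j |x_j - \eta_j|} against a *binary* ideal
#'     response (the NPC discrepancy);}
#'   \item{`sq_euclid`}{\eqn{\sum_j (x_j - \eta_j)^2} against centroids in
#'     \[0, 1\] (the GNPC discrepancy);}
#'   \item{`cross_entropy`}{\eqn{-\sum_j [x_j \log\theta_j +
#'     (1-x_j)\log(1-\theta_j)]} against probabilities strictly inside
#'     (0, 1); summed over persons it is the negative complete-data
#'     log-likelihood up to the mixing term.}
#' }
#'
#' @param x binary response vector of length J.
#' @param centroid numeric vector of length J in the loss kind's domain.
#' @param kind one of `"hamming"`, `"sq_euclid"`, `"cross_entropy"`.
#' @return A single non-negative number.
#' @examples
#' person_loss(c(1, 0), c(0.4, 0.4), "sq_euclid")  # 0.6^2 + 0.4^2 = 0.52
#' @export
person_loss <- function(x, centroid, kind = c("hamming", "sq_euclid", "cross_entropy")) {
  kind <- match.arg(kind)
  if (length(x) != length(centroid))
    stop("'x' and 'centroid' must have equal length", call. = FALSE)
  .check_centroid_domain(centroid, kind)
  switch(kind,
    hamming      = sum(abs(x - centroid)),
    sq_euclid    = sum((x - centroid)^2),
    cross_entropy = -sum(x * log(centroid) + (1 - x) * log1p(-centroid))
  )
}

.check_centroid_domain <- function(centroid, kind) {
  if (anyNA(centroid)) stop("centroid contains missing values", call. = FALSE)
  if (kind == "hamming" && !all(centroid %in% c(0, 1)))
    stop("the Hamming loss requires a binary centroid", call. = FALSE)
  if (kind == "sq_euclid" && any(centroid < 0 | centroid > 1))
    stop("squared-Euclidean centroids must lie in [0, 1]", call. = FALSE)
  if (kind == "cross_entropy" && any(centroid <= 0 | centroid >= 1))
    stop("cross-entropy centroids must lie strictly inside (0, 1)", call. = FALSE)
  invisible(centroid)
}

#' Total dataset loss under a class assignment
#'
#' Sums the element-wise person loss over all persons, each compared with the
#' centroid row of the class it is assigned to (the double sum over classes
#' and their members).
#'
#' @param X N x J binary response matrix.
#' @param assignment integer class index per person (into the rows of
#'   `centroids`).
#' @param centroids \eqn{2^K} x J centroid table.
#' @inheritParams person_loss
#' @return A single non-negative number.
#' @export
total_loss <- function(X, assignment, centroids, kind = c("hamming", "sq_euclid", "cross_entropy")) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  assignment <- as.integer(assignment)
  if (length(assignment) != nrow(X))
    stop("'assignment' must give one class per person", call. = FALSE)
  if (any(assignment < 1L | assignment > nrow(centroids)))
    stop("class index out of range in 'assignment'", call. = FALSE)
  .check_centroid_domain(centroids, kind)
  D <- X - centroids[assignment, , drop = FALSE]
  switch(kind,
    hamming   = sum(abs(D)),
    sq_euclid = sum(D * D),
    cross_entropy = -sum(X * log(centroids[assignment, , drop = FALSE]) +
                         (1 - X) * log1p(-centroids[assignment, , drop = FALSE]))
  )
}

# N x L matrix of person losses to every class centroid; the workhorse
# behind the NPC/GNPC assignment steps and the Gibbs conditional.
loss_matrix <- function(X, centroids, kind) {
  X <- as.matrix(X)
  C <- as.matrix(centroids)
  switch(kind,
    hamming   = X %*% t(1 - C) + (1 - X) %*% t(C),
    sq_euclid = {
      cross <- X %*% t(C)
      matrix(rowSums(X * X), nrow(X), nrow(C)) - 2 * cross +
        matrix(rowSums(C * C), nrow(X), nrow(C), byrow = TRUE)
    },
    cross_entropy = -(X %*% t(log(C)) + (1 - X) %*% t(log1p(-C)))
  )
}
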