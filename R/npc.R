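#' Nonparametric classification (NPC) of attribute mastery patterns
#'
#' Assigns each examinee to the attribute mastery pattern whose DINA ideal
#' response vector minimizes the Hamming distance to the observed responses.
#' Ties are broken deterministically towards the lower canonical class index
#' and flagged so they can be audited.
#'
#' @param X N x J binary response matrix.
#' @param Q J x K binary Q-matrix.
#' @return An object of class `"npc"`: a list with `assignment` (class index
#'   per person), `pattern` (N x K binary matrix of estimated patterns),
#'   `loss` (each person's minimal Hamming distance), `tie` (logical, `TRUE`
#'   when the minimum was attained by several classes), plus the pattern
#'   space and Q-matrix used.
#' @examples
#' Q <- rbind(c(1, 0), c(0, 1), c(1, 1))
#' X <- rbind(c(1, 0, 0), c(1, 1, 1))
#' fit <- npc(X, Q)
#' fit$pattern
#' @seealso [gnpc()] for the weighted-ideal-response generalization,
#'   [gbdcm()] for the generalized Bayesian counterparts.
#' @export
npc <- function(X, Q) {
  Q <- validate_q(Q)
  X <- validate_responses(X, nrow(Q))
  patterns <- attribute_patterns(ncol(Q))
  eta <- ideal_response(Q, "dina", patterns)
  D <- loss_matrix(X, eta, "hamming")
  assignment <- max.col(-D, ties.method = "first")
  minloss <- D[cbind(seq_len(nrow(X)), assignment)]
  tie <- rowSums(D == minloss) > 1L
  out <- list(assignment = assignment,
              pattern = patterns[assignment, , drop = FALSE],
              loss = minloss, tie = tie,
              patterns = patterns, Q = Q, ideal = eta,
              N = nrow(X), call = match.call())
  rownames(out$pattern) <- rownames(X)
  class(out) <- "npc"
  out
}

#' @export
print.npc <- function(x, ...) {
  cat("Nonparametric classification (NPC, Hamming loss on DINA ideals)\n")
  cat(sprintf("  %d examinees, %d items, %d attributes (%d classes)\n",
              x$N, nrow(x$Q), ncol(x$Q), nrow(x$patterns)))
  cat(sprintf("  total Hamming loss %g; %d tied classification(s)\n",
              sum(x$loss), sum(x$tie)))
  invisible(x)
}

#' @export
coef.npc <- function(object, ...) object$pattern

#' Generalized nonparametric classification (GNPC)
#'
#' Alternates between (a) updating the generalized ideal responses -- at each
#' free (class, item) position the centroid is set to the mean response of
#' the class's current members, which minimizes the within-class squared
#' error -- and (b) reassigning each examinee to the class with the smallest
#' squared-Euclidean distance to its centroid row.  The total loss is
#' non-increasing across iterations; the algorithm stops when its decrease
#' drops below `tol` or after `max_iter` sweeps.
#'
#' At free positions the DINA and DINO ideals are 0 and 1, so the centroid
#' determines the weight via \eqn{w = 1 - \bar x}.  Empty classes keep their
#' previous weight (initially the prior mean 2/3); degenerate class means of
#' exactly 0 or 1 are encoded as weights 0.999/0.001, i.e. fixed to a value
#' close to one or zero.
#'
#' @inheritParams npc
#' @param init optional initial class assignment (defaults to the NPC fit).
#' @param max_iter maximum number of alternating sweeps.
#' @param tol absolute tolerance on the total-loss decrease.
#' @return An object of class `"gnpc"`: `assignment`, `pattern`, `W` (the
#'   \eqn{2^K} x J weight table, meaningful at `free` positions),
#'   `centroids`, `total_loss`, `loss_trace`, `iterations`, `converged`,
#'   `tie`, plus the pattern space and Q-matrix.
#' @export
gnpc <- function(X, Q, init = NULL, max_iter = 100L, tol = 1e-6) {
  Q <- validate_q(Q)
  X <- validate_responses(X, nrow(Q))
  if (max_iter < 1L) stop("'max_iter' must be at least 1", call. = FALSE)
  patterns <- attribute_patterns(ncol(Q))
  L <- nrow(patterns)
  dina <- ideal_response(Q, "dina", patterns)
  free <- free_weight_mask(Q, patterns)
  if (is.null(init)) init <- npc(X, Q)$assignment
  assignment <- as.integer(init)
  if (length(assignment) != nrow(X) || any(assignment < 1L | assignment > L))
    stop("'init' must assign every person a class in 1:2^K", call. = FALSE)

  W <- matrix(2 / 3, L, nrow(Q), dimnames = dimnames(dina))
  centroids <- .gnpc_centroids(dina, free, W)
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  tie <- rep(FALSE, nrow(X))
  for (iter in seq_len(max_iter)) {
    upd <- .gnpc_weight_update(X, assignment, W, free, L)
    W <- upd
    centroids <- .gnpc_centroids(dina, free, W)
    D <- loss_matrix(X, centroids, "sq_euclid")
    assignment <- max.col(-D, ties.method = "first")
    minloss <- D[cbind(seq_len(nrow(X)), assignment)]
    tie <- (rowSums(abs(D - minloss) < 1e-12) > 1L)
    tl <- sum(minloss)
    trace <- c(trace, tl)
    if (prev - tl < tol) { converged <- TRUE; break }
    prev <- tl
  }
  out <- list(assignment = assignment,
              pattern = patterns[assignment, , drop = FALSE],
              W = W, free = free, centroids = centroids,
              total_loss = trace[length(trace)], loss_trace = trace,
              iterations = iter, converged = converged, tie = tie,
              patterns = patterns, Q = Q, N = nrow(X), call = match.call())
  rownames(out$pattern) <- rownames(X)
  class(out) <- "gnpc"
  out
}

# class-mean centroid update expressed on the weight scale; free positions
# have (dina, dino) = (0, 1) so centroid = 1 - w
.gnpc_weight_update <- function(X, assignment, W, free, L) {
  counts <- tabulate(assignment, L)
  S <- matrix(0, L, ncol(X))
  agg <- rowsum(X, assignment)
  S[as.integer(rownames(agg)), ] <- agg
  means <- S / pmax(counts, 1L)
  Wnew <- 1 - means
  Wnew[means <= 0] <- 0.999          # class mean exactly 0: near-conjunctive
  Wnew[means >= 1] <- 0.001          # class mean exactly 1: near-disjunctive
  Wnew[counts == 0L, ] <- W[counts == 0L, , drop = FALSE]  # empty class: keep
  W[free] <- Wnew[free]
  W
}

.gnpc_centroids <- function(dina, free, W) {
  centroids <- dina * 1.0
  centroids[free] <- 1 - W[free]
  centroids
}

#' @export
print.gnpc <- function(x, ...) {
  cat("Generalized nonparametric classification (GNPC, squared-Euclidean loss)\n")
  cat(sprintf("  %d examinees, %d items, %d attributes (%d classes)\n",
              x$N, nrow(x$Q), ncol(x$Q), nrow(x$patterns)))
  cat(sprintf("  total loss %.4f after %d iteration(s)%s; %d tied classification(s)\n",
              x$total_loss, x$iterations,
              if (x$converged) " (converged)" else " (max_iter reached)",
              sum(x$tie)))
  invisible(x)
}

#' @export
coef.gnpc <- function(object, ...) object$pattern
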