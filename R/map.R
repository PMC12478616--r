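#' MAP estimation by coordinate descent under the Q-matrix constraint
#'
#' Minimizes the penalized generalized-posterior objective
#' \deqn{\omega \sum_i \ell(x_i, \theta_{c_i}) - \sum_i \log \pi_{c_i}
#'       - \delta_0 \sum_c \log \pi_c}
#' over class assignments, item parameters and mixing proportions, by
#' blockwise minimization:
#' \enumerate{
#'   \item *item step*: within each item, classes sharing the same mastery
#'     of the required attributes (the Q-matrix constraint
#'     \eqn{\theta_{jc} = \theta_{jc'}} whenever
#'     \eqn{\alpha_c \circ q_j = \alpha_{c'} \circ q_j}) are pooled and set
#'     to the pooled mean response of their members, clipped to the loss
#'     domain (rounded to \{0, 1\} for the Hamming loss, clamped to
#'     \[1e-10, 1-1e-10\] for cross-entropy);
#'   \item *proportion step*: \eqn{\pi_c = (n_c + \delta_0)/(N + 2^K
#'     \delta_0)};
#'   \item *assignment step*: each person to
#'     \eqn{\arg\min_c\, \omega\,\ell(x_i, \theta_c) - \log \pi_c}
#'     (ties to the lower class index).
#' }
#' Each block minimizes the objective, so the objective sequence is
#' non-increasing.  With the cross-entropy loss, flat priors
#' (\eqn{\delta_0 = 0}) and learning rate 1 the objective is the negative
#' complete-data log-likelihood and the result is the joint maximum
#' likelihood estimate.
#'
#' @inheritParams gbdcm
#' @param loss `"cross_entropy"` (default), `"sq_euclid"` or `"hamming"`.
#' @param delta0 non-negative strength of the \eqn{-\delta_0\sum_c\log\pi_c}
#'   regularizer on the proportions (0 = flat).
#' @param max_iter,tol iteration cap and absolute tolerance on the objective
#'   decrease.
#' @param init initial class assignment; defaults to the NPC fit.
#' @return An object of class `"map_dcm"`: `assignment`, `pattern`, `theta`
#'   (the \eqn{2^K} x J item probability/centroid table), `pi`, `objective`
#'   (trace), `iterations`, `converged`.
#' @export
map_dcm <- function(X, Q, loss = c("cross_entropy", "sq_euclid", "hamming"),
                    learning_rate = 1, delta0 = 0, max_iter = 100L,
                    tol = 1e-8, init = NULL) {
  loss <- match.arg(loss)
  Q <- validate_q(Q)
  X <- validate_responses(X, nrow(Q))
  if (delta0 < 0) stop("'delta0' must be non-negative", call. = FALSE)
  N <- nrow(X); J <- nrow(Q); K <- ncol(Q)
  patterns <- attribute_patterns(K)
  L <- nrow(patterns)
  eps <- 1e-10

  # per item: equivalence classes of latent classes under the Q constraint
  groups <- lapply(seq_len(J), function(j) {
    key <- patterns[, Q[j, ] == 1, drop = FALSE]
    match(apply(key, 1L, paste, collapse = ""),
          unique(apply(key, 1L, paste, collapse = "")))
  })

  if (is.null(init)) init <- npc(X, Q)$assignment
  assignment <- as.integer(init)
  theta <- matrix(0.5, L, J, dimnames = list(rownames(patterns), rownames(Q)))
  trace <- numeric(0)
  prev <- Inf; converged <- FALSE; iter <- 0L

  for (iter in seq_len(max_iter)) {
    ## item step: pooled class means under the constraint
    counts <- tabulate(assignment, L)
    S <- matrix(0, L, J)
    aggr <- rowsum(X, assignment)
    S[as.integer(rownames(aggr)), ] <- aggr
    for (j in seq_len(J)) {
      g <- groups[[j]]
      n_g <- tapply(counts, g, sum)
      s_g <- tapply(S[, j], g, sum)
      mean_g <- ifelse(n_g > 0, s_g / pmax(n_g, 1), NA_real_)
      new <- mean_g[as.character(g)]
      keep <- is.na(new)                   # empty pooled group: keep previous
      theta[, j] <- ifelse(keep, theta[, j], new)
    }
    theta <- switch(loss,
      hamming       = round(theta + eps),  # majority vote, ties to 1
      sq_euclid     = pmin(pmax(theta, 0), 1),
      cross_entropy = pmin(pmax(theta, eps), 1 - eps))

    ## proportion step
    counts <- tabulate(assignment, L)
    pi_cur <- (counts + delta0) / (N + L * delta0)

    ## assignment step
    D <- loss_matrix(X, theta, if (loss == "hamming") "sq_euclid" else loss)
    obj_mat <- learning_rate * D - rep(log(pi_cur), each = N)
    assignment <- max.col(-obj_mat, ties.method = "first")

    ## objective after the sweep
    counts <- tabulate(assignment, L)
    pi_cur <- (counts + delta0) / (N + L * delta0)
    obj <- learning_rate * total_loss(X, assignment, theta,
                                      if (loss == "hamming") "sq_euclid" else loss) -
      sum(log(pi_cur[assignment])) -
      (if (delta0 > 0) delta0 * sum(log(pi_cur)) else 0)
    trace <- c(trace, obj)
    if (is.finite(prev) && prev - obj < tol) { converged <- TRUE; break }
    prev <- obj
  }

  out <- list(assignment = assignment,
              pattern = patterns[assignment, , drop = FALSE],
              theta = theta, pi = pi_cur,
              objective = trace, iterations = iter, converged = converged,
              loss = loss, learning_rate = learning_rate, delta0 = delta0,
              patterns = patterns, Q = Q, N = N, call = match.call())
  names(out$pi) <- rownames(patterns)
  rownames(out$pattern) <- rownames(X)
  class(out) <- "map_dcm"
  out
}

#' @export
print.map_dcm <- function(x, ...) {
  cat("MAP estimate (coordinate descent,", x$loss, "loss)\n")
  cat(sprintf("  %d examinees, %d items, %d attributes; learning rate %g, delta0 %g\n",
              x$N, nrow(x$Q), ncol(x$Q), x$learning_rate, x$delta0))
  cat(sprintf("  objective %.6g after %d iteration(s)%s\n",
              x$objective[length(x$objective)], x$iterations,
              if (x$converged) " (converged)" else " (max_iter reached)"))
  invisible(x)
}

#' @export
coef.map_dcm <- function(object, ...) object$pattern
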