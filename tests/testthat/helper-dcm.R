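# shared fixture builders: everything is generated in code, nothing stored

# random valid Q-matrix: binary, no zero rows, every attribute covered by at
# least one single-attribute item (completeness)
rand_q <- function(J, K) {
  stopifnot(J >= K)
  Q <- matrix(rbinom(J * K, 1, 0.4), J, K)
  Q[seq_len(K), ] <- diag(K)
  for (i in which(rowSums(Q) == 0)) Q[i, sample.int(K, 1)] <- 1L
  Q
}

rand_x <- function(N, J, p = 0.5) matrix(rbinom(N * J, 1, p), N, J)

# independent joint-MLE coordinate descent (cross-entropy loss, flat priors)
# under the Q-matrix equivalence constraint, written as plain loops
jmle_oracle <- function(X, Q, max_iter = 100) {
  pat <- gbdcm::attribute_patterns(ncol(Q))
  L <- nrow(pat); N <- nrow(X); J <- ncol(X)
  eps <- 1e-10
  z <- npc_brute(X, Q)$assignment
  theta <- matrix(0.5, L, J)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(J)) {
      key <- apply(pat[, Q[j, ] == 1, drop = FALSE], 1, paste, collapse = "")
      for (g in unique(key)) {
        cls <- which(key == g)
        members <- which(z %in% cls)
        if (length(members))
          theta[cls, j] <- min(max(mean(X[members, j]), eps), 1 - eps)
      }
    }
    piv <- tabulate(z, L) / N
    znew <- integer(N)
    for (i in seq_len(N)) {
      val <- numeric(L)
      for (c in seq_len(L))
        val[c] <- -sum(X[i, ] * log(theta[c, ]) +
                       (1 - X[i, ]) * log(1 - theta[c, ])) - log(piv[c])
      znew[i] <- which.min(val)
    }
    if (identical(znew, z)) { z <- znew; break }
    z <- znew
  }
  list(assignment = z, theta = theta)
}

# brute-force NPC oracle: plain loops over persons and patterns
npc_brute <- function(X, Q) {
  pat <- gbdcm::attribute_patterns(ncol(Q))
  eta <- gbdcm::ideal_response(Q, "dina", pat)
  assignment <- integer(nrow(X))
  loss <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    d <- numeric(nrow(pat))
    for (c in seq_len(nrow(pat))) d[c] <- sum(abs(X[i, ] - eta[c, ]))
    assignment[i] <- which.min(d)   # which.min takes the first minimum
    loss[i] <- min(d)
  }
  list(assignment = assignment, loss = loss)
}
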