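test_that("threshold convention yields decreasing marginal mastery rates", {
  alpha <- simulate_attributes(100000, 4, rho = 0, seed = 1)
  expect_equal(unname(colMeans(alpha)), c(0.8, 0.6, 0.4, 0.2), tolerance = 0.01)
  # correlation changes dependence, not the marginals
  alpha8 <- simulate_attributes(100000, 4, rho = 0.8, seed = 2)
  expect_equal(unname(colMeans(alpha8)), c(0.8, 0.6, 0.4, 0.2), tolerance = 0.01)
  # determinism
  expect_identical(simulate_attributes(50, 3, 0.8, seed = 9),
                   simulate_attributes(50, 3, 0.8, seed = 9))
  expect_error(simulate_attributes(10, 2, rho = 1), "\\[0, 1\\)")
})

test_that("correlated attributes show larger pairwise phi than independent ones", {
  phi_mean <- function(a) {
    cm <- cor(a)
    mean(cm[upper.tri(cm)])
  }
  set.seed(3)
  p0 <- mean(replicate(5, phi_mean(simulate_attributes(500, 4, 0))))
  p8 <- mean(replicate(5, phi_mean(simulate_attributes(500, 4, 0.8))))
  expect_gt(p8, p0 + 0.2)
})

test_that("Q-matrix composition builder honours counts and completeness", {
  Q <- sim_q_matrix(c(8, 6, 5, 1), K = 4)
  expect_equal(nrow(Q), 20L)
  expect_equal(sum(rowSums(Q) == 1), 8L)
  expect_equal(sum(rowSums(Q) == 2), 6L)
  expect_equal(sum(rowSums(Q) == 3), 5L)
  expect_equal(sum(rowSums(Q) == 4), 1L)
  expect_true(all(colSums(Q[rowSums(Q) == 1, ]) >= 1))  # simple coverage
  # identity stack
  expect_equal(unname(sim_q_matrix(c(3), K = 3)), diag(3L))
  # a composition that cannot cover every attribute with simple items fails
  expect_error(sim_q_matrix(c(2, 4), K = 3), "single-attribute")
})

test_that("item probability tables match the stated endpoints and monotonicity", {
  Q <- sim_q_matrix(c(5, 4, 3), K = 5)
  pat <- attribute_patterns(5)
  th_hi <- sim_item_probs(Q, "dina", "high")
  expect_true(all(th_hi %in% c(0.1, 0.9)))
  expect_equal(unname(th_hi[1, ]), rep(0.1, nrow(Q)))       # no mastery
  expect_equal(unname(th_hi[nrow(pat), ]), rep(0.9, nrow(Q)))  # full mastery
  th_lo <- sim_item_probs(Q, "dina", "low")
  expect_true(all(th_lo %in% c(0.3, 0.7)))
  # general model: a 2-of-3 class lies strictly between a 1-of-3 class and 0.9
  thg <- sim_item_probs(Q, "general", "high")
  j3 <- which(rowSums(Q) == 3)[1]
  hits <- pat %*% Q[j3, ]
  v1 <- thg[which(hits == 1)[1], j3]
  v2 <- thg[which(hits == 2)[1], j3]
  expect_true(v1 < v2 && v2 < 0.9)
  expect_true(check_monotonicity(thg, Q)$ok)
  expect_true(check_monotonicity(
    sim_item_probs(Q, "general", "low", jitter = TRUE, seed = 4), Q)$ok)
})

test_that("responses are Bernoulli draws from the class-selected rows", {
  Q <- sim_q_matrix(c(2, 1), K = 2)
  alpha <- simulate_attributes(200, 2, 0, seed = 5)
  ones <- matrix(1, 4, 3)
  expect_true(all(sim_responses(alpha, ones) == 1))
  half <- matrix(0.5, 4, 3)
  X <- sim_responses(alpha, half, seed = 6)
  se <- sqrt(0.25 / 200)
  expect_true(all(abs(colMeans(X) - 0.5) < 3 * se))
  expect_identical(sim_responses(alpha, half, seed = 7),
                   sim_responses(alpha, half, seed = 7))
})

test_that("design runner derives distinct replication seeds and aggregates means", {
  res <- run_design(20, c(3, 2), K = 3, quality = "high", rho = 0,
                    methods = "npc", replications = 3, seed = 11)
  expect_equal(nrow(res$results), 3L)
  expect_equal(res$aggregate$aar, mean(res$results$aar))
  # distinct derived seeds give distinct datasets, hence (generically)
  # distinct per-replication scores
  expect_gt(length(unique(res$results$aar)), 1L)
})

test_that("near-deterministic responses make every method recover the truth", {
  # push the endpoints to 0.001/0.999 by generating DINA responses from the
  # ideals with tiny noise
  set.seed(12)
  Q <- sim_q_matrix(c(8, 6, 5, 1), K = 4)
  alpha <- simulate_attributes(300, 4, 0, seed = 13)
  theta <- 0.001 + 0.998 * ideal_response(Q, "dina")
  X <- sim_responses(alpha, theta, seed = 14)
  expect_gt(attribute_agreement(npc(X, Q)$pattern, alpha), 0.99)
  expect_gt(attribute_agreement(gnpc(X, Q)$pattern, alpha), 0.99)
  for (loss in c("sq_euclid", "hamming")) {
    fit <- gbdcm(X, Q, loss = loss, n_iter = 300, burn_in = 150, seed = 15)
    expect_gt(attribute_agreement(fit$classification, alpha), 0.99)
  }
})
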