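test_that("the categorical class conditional is the tempered softmax", {
  # K=1, J=1 toy: centroids (0, 1), pi uniform, lr 1, x = 1
  # unnormalized (0.5 e^-1, 0.5) -> (0.2689, 0.7311)
  p <- pattern_conditional(1, matrix(c(0, 1)), c(0.5, 0.5), 1, "sq_euclid")
  expect_equal(unname(p[1, ]), c(exp(-1), 1) / (exp(-1) + 1), tolerance = 1e-12)
  expect_equal(round(unname(p[1, ]), 4), c(0.2689, 0.7311))
  # learning rate 0 returns the mixing proportions unchanged
  p0 <- pattern_conditional(1, matrix(c(0, 1)), c(0.3, 0.7), 0, "sq_euclid")
  expect_equal(unname(p0[1, ]), c(0.3, 0.7))
  # a degenerate prior is a point mass regardless of the data
  pd <- pattern_conditional(0, matrix(c(0, 1)), c(0, 1), 5, "sq_euclid")
  expect_equal(unname(pd[1, ]), c(0, 1))
  expect_error(pattern_conditional(1, matrix(c(0, 1)), c(0.5, 0.4), 1), "probability")
})

test_that("identical persons get identical conditionals; rows sum to one", {
  set.seed(2)
  Q <- rand_q(6, 2)
  pat <- attribute_patterns(2)
  C <- gbdcm:::.gnpc_centroids(ideal_response(Q, "dina", pat),
                               free_weight_mask(Q, pat), matrix(0.6, 4, 6))
  X <- rbind(c(1, 0, 1, 1, 0, 0), c(1, 0, 1, 1, 0, 0))
  P <- pattern_conditional(X, C, rep(0.25, 4), 1, "sq_euclid")
  expect_equal(P[1, ], P[2, ])
  expect_equal(rowSums(P), c(1, 1))
  # a large learning rate concentrates on the unique zero-loss class
  eta <- ideal_response(Q, "dina", pat)
  Pbig <- pattern_conditional(eta[3, , drop = FALSE], eta * 1.0, rep(0.25, 4),
                              200, "sq_euclid")
  expect_gt(Pbig[1, 3], 0.999)
})

test_that("the Dirichlet conditional uses learning-rate-scaled counts", {
  # Dirichlet(4, 2) has mean (2/3, 1/3); check by Monte Carlo on the draw path
  set.seed(31)
  draws <- t(replicate(4000, sample_dirichlet(c(1, 1), counts = c(3, 1),
                                              learning_rate = 1)))
  expect_equal(colMeans(draws), c(2 / 3, 1 / 3), tolerance = 0.02)
  # learning rate 0: the counts are ignored and the prior is sampled
  set.seed(32)
  d0 <- t(replicate(4000, sample_dirichlet(c(1, 1), counts = c(50, 0),
                                           learning_rate = 0)))
  expect_equal(colMeans(d0), c(0.5, 0.5), tolerance = 0.02)
  expect_error(sample_dirichlet(c(0, 1)), "positive")
})

test_that("the weight Metropolis acceptance ratio matches hand arithmetic", {
  # one member with x=1 at a free position, w 0.5 -> 0.52, lr 1, Beta(2,1):
  # delta loss = (1-0.48)^2 - (1-0.5)^2 = 0.0204;
  # ratio = exp(-0.0204) * (2*0.52)/(2*0.5) ~ 1.0190 -> sure acceptance
  la <- gbdcm:::.mh_weight_log_accept(0.5, 0.52, n = 1, s = 1,
                                      learning_rate = 1, beta_a = 2, beta_b = 1)
  expect_equal(exp(la), exp(-0.0204) * 0.52 / 0.5, tolerance = 1e-12)
  expect_gt(la, 0)
  # proposals outside the unit interval are rejected outright
  expect_identical(gbdcm:::.mh_weight_log_accept(0.02, -0.01, 1, 1, 1, 2, 1), -Inf)
  # no members and a flat prior: acceptance probability exactly 1
  expect_equal(gbdcm:::.mh_weight_log_accept(0.4, 0.42, 0, 0, 1, 1, 1), 0)
})

test_that("a fixed seed makes the whole fit bit-reproducible", {
  set.seed(400)
  Q <- rand_q(8, 3)
  X <- rand_x(15, 8)
  f1 <- gbdcm(X, Q, n_iter = 120, burn_in = 60, seed = 99)
  f2 <- gbdcm(X, Q, n_iter = 120, burn_in = 60, seed = 99)
  expect_identical(f1$attr_prob, f2$attr_prob)
  expect_identical(f1$pattern_prob, f2$pattern_prob)
  expect_identical(f1$pi, f2$pi)
  expect_identical(f1$W, f2$W)
  f3 <- gbdcm(X, Q, n_iter = 120, burn_in = 60, seed = 100)
  expect_false(identical(f1$attr_prob, f3$attr_prob))
})

test_that("learning rate 0 with uniform priors gives ~0.5 mastery everywhere", {
  set.seed(8)
  Q <- rand_q(6, 2)
  X <- rand_x(12, 6)
  fit <- gbdcm(X, Q, learning_rate = 0, n_iter = 3000, burn_in = 500,
               seed = 17)
  # prior-only posterior: pattern marginals uniform in expectation
  expect_equal(unname(fit$attr_prob), matrix(0.5, 12, 2), tolerance = 0.05)
  expect_equal(unname(fit$pi), rep(0.25, 4), tolerance = 0.05)
})

test_that("posterior summaries are coherent probabilities", {
  set.seed(55)
  Q <- rand_q(8, 3)
  dat <- sim_dcm(25, Q, model = "dina", quality = "high", rho = 0.8, seed = 56)
  for (loss in c("sq_euclid", "hamming")) {
    fit <- gbdcm(dat$X, Q, loss = loss, n_iter = 200, burn_in = 100, seed = 57)
    expect_equal(unname(rowSums(fit$pattern_prob)), rep(1, 25), tolerance = 1e-9)
    expect_equal(fit$attr_prob, fit$pattern_prob %*% fit$patterns,
                 ignore_attr = TRUE)
    expect_true(all(fit$pattern_prob >= 0))
    expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
    if (loss == "hamming") expect_null(fit$W) else
      expect_true(all(fit$W >= 0 & fit$W <= 1))
  }
})

test_that("indicator averaging agrees with Rao-Blackwellization in expectation", {
  set.seed(90)
  Q <- rand_q(6, 2)
  dat <- sim_dcm(20, Q, model = "dina", quality = "high", seed = 91)
  frb <- gbdcm(dat$X, Q, n_iter = 1500, burn_in = 250, seed = 92)
  find <- gbdcm(dat$X, Q, n_iter = 1500, burn_in = 250, seed = 93,
                rao_blackwell = FALSE)
  expect_equal(frb$attr_prob, find$attr_prob, tolerance = 0.12)
})

test_that("classification applies the >=cutoff mastery rule", {
  expect_equal(unname(classify(rbind(c(0.9, 0.1)))), rbind(c(1L, 0L)))
  # a probability of exactly 0.5 counts as mastered
  expect_equal(unname(classify(rbind(c(0.5, 0.499)))), rbind(c(1L, 0L)))
  # near-cutoff mastery: 0.516 is classified as mastered at the 0.5 cutoff
  expect_equal(unname(classify(rbind(c(0.516, 0.9, 0.9)))), rbind(c(1L, 1L, 1L)))
  expect_error(classify(rbind(c(0.5, 0.5)), cutoff = 1), "cutoff")
})

test_that("methods on the fitted object are consistent with its contents", {
  set.seed(60)
  Q <- rand_q(6, 2)
  dat <- sim_dcm(18, Q, model = "general", quality = "low", rho = 0.8, seed = 61)
  fit <- gbdcm(dat$X, Q, n_iter = 200, burn_in = 100, seed = 62)
  expect_identical(coef(fit, "pattern"), fit$classification)
  expect_equal(sum(summary(fit)$pattern_table$count), 18)
  f <- fitted(fit)
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(residuals(fit), fit$X - f)
  expect_output(print(fit), "Generalized Bayesian")
  expect_silent(grDevices::pdf(NULL))
  plot(fit); grDevices::dev.off()
})

test_that("invalid sampler configurations are rejected", {
  Q <- rbind(c(1, 0), c(0, 1))
  X <- rand_x(5, 2)
  expect_error(gbdcm(X, Q, burn_in = 100, n_iter = 100), "burn_in")
  expect_error(gbdcm(X, Q, mh_step = 0), "mh_step")
  expect_error(gbdcm(X, Q, learning_rate = -1), "non-negative")
  expect_error(gbdcm(X, Q, init = rep(9L, 5)), "1:2\\^K")
})
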