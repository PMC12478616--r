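test_that("pattern enumeration follows the canonical binary-counting order", {
  expect_equal(unname(attribute_patterns(1)), matrix(c(0L, 1L), 2, 1))
  expect_equal(unname(attribute_patterns(2)),
               rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)))
  p4 <- attribute_patterns(4)
  expect_equal(nrow(p4), 16L)
  expect_equal(nrow(unique(p4)), 16L)
  expect_equal(unname(p4[1, ]), rep(0L, 4))
  expect_equal(unname(p4[16, ]), rep(1L, 4))
  # index is a bijection that round-trips through the pattern matrix
  for (K in 1:4) {
    p <- attribute_patterns(K)
    expect_equal(pattern_index(p), seq_len(2^K))
  }
  expect_equal(pattern_labels(c(2L, 3L), K = 2), c("01", "10"))
  expect_error(attribute_patterns(0), "positive integer")
})

test_that("DINA and DINO ideal responses implement all/any mastery of required attributes", {
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1))
  dina <- ideal_response(Q, "dina")
  dino <- ideal_response(Q, "dino")
  # pattern (1,1) with q=(1,0): all required mastered
  expect_equal(dina["11", 1], c("11" = 1L))
  # pattern (0,1) with q=(1,1): DINA 0, DINO 1
  expect_equal(unname(dina["01", 3]), 0L)
  expect_equal(unname(dino["01", 3]), 1L)
  # the no-mastery pattern answers 0 everywhere under either rule
  expect_true(all(dina["00", ] == 0L))
  expect_true(all(dino["00", ] == 0L))
  expect_error(ideal_response(rbind(c(1, 1, 1)), patterns = attribute_patterns(2)),
               "attribute count")
})

test_that("DINA implies DINO, and the free mask is exactly partial mastery", {
  set.seed(11)
  for (K in 1:5) {
    Q <- rand_q(max(K, 6), K)
    pat <- attribute_patterns(K)
    dina <- ideal_response(Q, "dina", pat)
    dino <- ideal_response(Q, "dino", pat)
    expect_true(all(dina <= dino))
    # brute enumeration of partial mastery of required attributes
    expected <- matrix(FALSE, nrow(pat), nrow(Q))
    for (c in seq_len(nrow(pat))) for (j in seq_len(nrow(Q))) {
      hit <- sum(pat[c, ] * Q[j, ])
      expected[c, j] <- hit > 0 && hit < sum(Q[j, ])
    }
    expect_equal(unname(free_weight_mask(Q, pat)), expected)
  }
})

test_that("generalized centroids blend the ideals and respect endpoints", {
  set.seed(7)
  Q <- rand_q(8, 3)
  pat <- attribute_patterns(3)
  dina <- ideal_response(Q, "dina", pat)
  dino <- ideal_response(Q, "dino", pat)
  ones <- matrix(1, nrow(dina), ncol(dina))
  expect_equal(generalized_centroid(dina, dino, ones), dina * 1.0)
  expect_equal(generalized_centroid(dina, dino, 0 * ones), dino * 1.0)
  # hand arithmetic at a free position: w 0.6, dina 0, dino 1 -> 0.4
  expect_equal(generalized_centroid(matrix(0), matrix(1), matrix(0.6))[1, 1], 0.4)
  # monotone in w at free positions, constant elsewhere
  free <- free_weight_mask(Q, pat)
  c_lo <- generalized_centroid(dina, dino, 0.2 * ones)
  c_hi <- generalized_centroid(dina, dino, 0.8 * ones)
  expect_true(all(c_hi[free] < c_lo[free]))
  expect_equal(c_lo[!free], c_hi[!free])
  expect_error(generalized_centroid(dina, dino, 1.5 * ones), "\\[0, 1\\]")
})

test_that("monotonicity check accepts DINA tables and flags constructed inversions", {
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1))
  theta <- 0.1 + 0.8 * ideal_response(Q, "dina")
  expect_true(check_monotonicity(theta, Q)$ok)
  bad <- theta
  bad["00", 3] <- 0.95   # no-mastery class above the full-mastery class
  res <- check_monotonicity(bad, Q)
  expect_false(res$ok)
  expect_true(any(res$violations$item == 3 & res$violations$class_low == 1))
  # simulator-generated general tables satisfy the partial order
  set.seed(21)
  Qg <- sim_q_matrix(c(4, 3, 2), K = 4)
  expect_true(check_monotonicity(sim_item_probs(Qg, "general", "high"), Qg)$ok)
  expect_true(check_monotonicity(
    sim_item_probs(Qg, "general", "low", jitter = TRUE, seed = 5), Qg)$ok)
})

test_that("Q-matrix and response validation fail fast with located diagnostics", {
  expect_error(validate_q(rbind(c(1, 0), c(0, 0))), "row\\(s\\) 2")
  expect_error(validate_q(rbind(c(1, 2))), "row 1, column 2")
  expect_error(validate_responses(rbind(c(1, NA))), "missing")
})
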