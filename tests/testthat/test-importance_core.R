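test_that("rank_transform orders by importance with average-rank ties", {
  strict <- rank_transform(model_importance("m", c(A = 0.5, B = 0.3, C = 0.2)))
  expect_equal(strict, c(A = 1, B = 2, C = 3))

  tied <- rank_transform(model_importance("m", c(A = 0.4, B = 0.4, C = 0.2)))
  expect_equal(tied, c(A = 1.5, B = 1.5, C = 3))

  expect_equal(rank_transform(model_importance("m", c(A = 7.3))), c(A = 1))
})

test_that("rank_transform is scale-invariant and order-independent", {
  set.seed(3)
  for (i in 1:20) {
    v <- stats::setNames(rexp(7), letters[1:7])
    r1 <- rank_transform(model_importance("m", v))
    r2 <- rank_transform(model_importance("m", v * runif(1, 0.01, 100)))
    expect_identical(r1, r2)
    shuffled <- sample(v)
    r3 <- rank_transform(model_importance("m", shuffled))
    expect_equal(r3[names(r1)], r1)
  }
})

test_that("non-finite importances are rejected, naming the feature", {
  expect_error(model_importance("m", c(A = 1, B = Inf)), "B")
  expect_error(model_importance("m", c(A = NaN)), "A")
})

test_that("sum_scale yields shares summing to one and is idempotent", {
  s <- sum_scale(model_importance("m", c(A = 2, B = 3, C = 5)))
  expect_equal(s, c(A = 0.2, B = 0.3, C = 0.5))
  expect_equal(sum_scale(model_importance("m", c(A = 4))), c(A = 1))

  set.seed(5)
  for (i in 1:10) {
    v <- stats::setNames(rexp(6), letters[1:6])
    once <- sum_scale(model_importance("m", v))
    expect_equal(sum(once), 1, tolerance = 1e-12)
    expect_equal(sum_scale(model_importance("m", once)), once,
                 tolerance = 1e-12)
    expect_identical(order(once), order(v))
  }
})

test_that("an all-zero importance vector is an error", {
  expect_error(sum_scale(model_importance("m", c(A = 0, B = 0))),
               "uninformative")
})

test_that("build_rank_matrix assembles per-model rank columns", {
  outs <- list(model_importance("m1", c(A = 5, B = 2)),
               model_importance("m2", c(A = 9, B = 1)))
  m <- build_rank_matrix(outs, wisfc_config())
  expect_identical(m$orientation, "RANK_LOW_BEST")
  expect_equal(unname(m$entries[, "m1"]), c(1, 2))
  expect_equal(unname(m$entries[, "m2"]), c(1, 2))
  expect_identical(m$features, c("A", "B"))
})

test_that("absent features are filled with the worst rank over the pool", {
  outs <- list(model_importance("m1", c(A = 3, B = 2, C = 1)),
               model_importance("m2", c(A = 3, B = 2)))
  m <- build_rank_matrix(outs, wisfc_config())
  expect_equal(m$entries["C", "m2"], 3)  # p = 3 in the union
  expect_identical(m$fill_policy_applied$feature, "C")
  expect_identical(m$fill_policy_applied$model, "m2")

  m_sum <- build_rank_matrix(outs, wisfc_config(normalization = "sum"))
  expect_equal(m_sum$entries["C", "m2"], 0)

  m_ex <- build_rank_matrix(outs, wisfc_config(fill = "exclude"))
  expect_true(is.na(m_ex$entries["C", "m2"]))
})

test_that("pre-ranked inputs are preserved verbatim", {
  ranks <- cbind(c(`Blood Pressure` = 1, Cholesterol = 1),
                 c(2, 8), c(4, 2), c(1, 15), c(3, 1))
  rownames(ranks) <- c("Blood Pressure", "Cholesterol")
  m <- build_rank_matrix(preranked_outputs(ranks), wisfc_config())
  expect_equal(unname(m$entries["Blood Pressure", ]), c(1, 2, 4, 1, 3))
  expect_equal(unname(m$entries["Cholesterol", ]), c(1, 8, 2, 15, 1))
  expect_equal(m$pool_size, 15)  # the max observed rank implies the pool
  expect_error(build_rank_matrix(preranked_outputs(ranks),
                                 wisfc_config(normalization = "sum")),
               "sum-scaled")
})

test_that("build_rank_matrix validates its ensemble", {
  one <- list(model_importance("m1", c(A = 1, B = 2)))
  expect_error(build_rank_matrix(one, wisfc_config()), ">= 2 models")
  dup <- c(one, one)
  expect_error(build_rank_matrix(dup, wisfc_config()), "duplicate model_id")
})

test_that("build_rank_matrix is invariant to model input order", {
  outs <- random_outputs(4, 6, seed = 9)
  m1 <- build_rank_matrix(outs, wisfc_config())
  m2 <- build_rank_matrix(rev(outs), wisfc_config())
  expect_equal(m2$entries[, m1$models], m1$entries)
})

test_that("softmax weights follow the closed form and sum to one", {
  expect_equal(softmax_weights(c(0.8, 0.8, 0.8))$weights, rep(1 / 3, 3))
  expect_equal(softmax_weights(c(0, log(2)))$weights, c(1 / 3, 2 / 3),
               tolerance = 1e-12)
  expect_equal(equal_weights(paste0("m", 1:5))$weights, rep(0.2, 5))
})

test_that("softmax weights are shift-invariant and order-preserving", {
  set.seed(7)
  for (i in 1:20) {
    perf <- runif(5)
    w <- softmax_weights(perf)$weights
    expect_gt(min(w), 0)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(softmax_weights(perf + runif(1, -10, 10))$weights, w,
                 tolerance = 1e-9)
    expect_identical(order(w), order(perf))
  }
  expect_error(softmax_weights(c(0.5, NA)), "non-finite")
})

test_that("temperature flattens or sharpens softmax weights", {
  perf <- c(0.6, 0.9)
  sharp <- softmax_weights(perf, temperature = 0.1)$weights
  flat <- softmax_weights(perf, temperature = 10)$weights
  plain <- softmax_weights(perf)$weights
  expect_gt(sharp[2], plain[2])
  expect_lt(flat[2], plain[2])
  expect_equal(plain[2] / plain[1], exp(0.9) / exp(0.6), tolerance = 1e-12)
})
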