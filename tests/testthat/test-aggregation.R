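bp_chol_matrix <- function() {
  ranks <- cbind(c(1, 1), c(2, 8), c(4, 2), c(1, 15), c(3, 1))
  rownames(ranks) <- c("Blood Pressure", "Cholesterol")
  build_rank_matrix(preranked_outputs(ranks), wisfc_config())
}

test_that("equal-weight WIS reproduces the two-feature rank vectors", {
  m <- bp_chol_matrix()
  wis <- weighted_importance_score(m, equal_weights(m$models))
  expect_equal(unname(wis["Blood Pressure"]), 2.2, tolerance = 1e-12)
  expect_equal(unname(wis["Cholesterol"]), 5.4, tolerance = 1e-12)
})

test_that("a degenerate weight vector returns that model's column", {
  ranks <- cbind(c(A = 1, B = 2), c(3, 1))
  rownames(ranks) <- c("A", "B")
  m <- build_rank_matrix(preranked_outputs(ranks), wisfc_config())
  w <- structure(list(model_ids = c("m1", "m2"), weights = c(1, 0)),
                 class = "weight_vector")
  wis <- weighted_importance_score(m, w)
  expect_equal(unname(unclass(wis)), c(1, 2), ignore_attr = TRUE)
})

test_that("weight/model misalignment is an error", {
  m <- bp_chol_matrix()
  expect_error(weighted_importance_score(m, equal_weights(c("x", "y"))),
               "do not match")
})

test_that("equal-weight WIS matches the brute-force column-mean oracle", {
  set.seed(101)
  for (i in 1:50) {
    p <- sample(2:8, 1); n_models <- sample(2:6, 1)
    outs <- random_outputs(n_models, p, seed = 1000 + i)
    m <- build_rank_matrix(outs, wisfc_config())
    wis <- weighted_importance_score(m, equal_weights(m$models))
    oracle <- apply(m$entries, 1, mean)  # brute force over columns
    expect_equal(unclass(wis), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("WIS renormalizes weights over reporting models under exclude fill", {
  outs <- list(model_importance("m1", c(A = 3, B = 2, C = 1)),
               model_importance("m2", c(A = 3, B = 2)))
  m <- build_rank_matrix(outs, wisfc_config(fill = "exclude"))
  wis <- weighted_importance_score(m, equal_weights(m$models))
  expect_equal(unname(unclass(wis)["C"]), 3)  # only m1 reports C
})

test_that("frequency count matches the printed worked-example values", {
  m <- bp_chol_matrix()
  fc <- frequency_count(m, k = 10)
  expect_equal(fc$fc_fraction[fc$feature == "Blood Pressure"], 1.0)
  expect_equal(fc$fc_fraction[fc$feature == "Cholesterol"], 0.8)
  fc3 <- frequency_count(m, k = 3)
  expect_equal(fc3$fc_fraction[fc3$feature == "Cholesterol"], 0.6)
})

test_that("frequency count is monotone in k and saturates at the pool size", {
  outs <- random_outputs(5, 8, seed = 77)
  m <- build_rank_matrix(outs, wisfc_config())
  prev <- rep(0L, 8)
  for (k in 1:8) {
    fc <- frequency_count(m, k)$fc_count
    expect_true(all(fc >= prev))
    prev <- fc
  }
  expect_equal(frequency_count(m, 8)$fc_count, rep(5L, 8))
  expect_equal(frequency_count(m, 100)$fc_count, rep(5L, 8))
})

test_that("frequency count refuses a share-oriented matrix", {
  outs <- random_outputs(3, 4, seed = 5)
  m <- build_rank_matrix(outs, wisfc_config(normalization = "sum"))
  expect_error(frequency_count(m, 3), "rank")
})

test_that("invert_wis is the order-reversing affine map on [1, p]", {
  expect_equal(unclass(invert_wis(1, p = 20)), 20, ignore_attr = TRUE)
  expect_equal(unclass(invert_wis(20, p = 20)), 1, ignore_attr = TRUE)
  expect_equal(unclass(invert_wis(2.2, p = 20)), 18.8, ignore_attr = TRUE)
  expect_error(invert_wis(0.5, p = 20), "outside")
  expect_error(invert_wis(21, p = 20), "outside")
  set.seed(11)
  for (i in 1:20) {
    w <- runif(10, 1, 15)
    inv <- unclass(invert_wis(w, p = 15))
    expect_identical(order(inv), order(-w))  # brute-force order reversal
  }
})

test_that("composite score is the FC-discounted product with identities", {
  expect_equal(composite_score(0.5, 5, 5), 0.5)
  expect_equal(composite_score(0.4, 0, 5), 0)
  expect_equal(composite_score(0.4, 2, 5), 0.16)
})

test_that("composite score refuses rank-oriented WIS", {
  m <- bp_chol_matrix()
  wis <- weighted_importance_score(m, equal_weights(m$models))
  expect_error(composite_score(wis, c(5, 4), 5), "invert_wis")
  inverted <- invert_wis(wis, p = 15)
  expect_silent(composite_score(inverted, c(5, 4), 5))
})

test_that("joint selection gates on both consistency and strength", {
  # boundary: 4 features, top-quartile cut selects exactly the best WIS
  wis <- c(a = 1, b = 2, c = 3, d = 4)
  sel <- joint_select(wis, rep(1, 4), orientation = "RANK_LOW_BEST")
  expect_identical(unname(sel), c(TRUE, FALSE, FALSE, FALSE))

  # best WIS but failing the FC gate is never selected
  sel2 <- joint_select(wis, c(0.2, 1, 1, 1), orientation = "RANK_LOW_BEST")
  expect_false(sel2[["a"]])

  # dominating both criteria
  wis20 <- stats::setNames(1:20, letters[1:20])
  fc20 <- c(0.8, rep(1, 19))
  expect_true(joint_select(wis20, fc20, orientation = "RANK_LOW_BEST")[[1]])

  expect_error(joint_select(numeric(0), numeric(0),
                            orientation = "RANK_LOW_BEST"), "empty")
})

test_that("final ranking sorts by WIS, then FC, then feature name", {
  r <- rank_features(c(A = 2.2, B = 5.4), c(1.0, 0.8),
                     orientation = "RANK_LOW_BEST")
  expect_equal(r, c(1L, 2L))
  # FC tie-break
  r2 <- rank_features(c(A = 3, B = 3), c(0.6, 0.8),
                      orientation = "RANK_LOW_BEST")
  expect_equal(r2, c(2L, 1L))
  # lexicographic final tie-break
  r3 <- rank_features(c(B = 3, A = 3), c(0.8, 0.8),
                      orientation = "RANK_LOW_BEST")
  expect_equal(r3, c(2L, 1L))
})

test_that("final ranking is a reproducible total order", {
  set.seed(21)
  for (i in 1:10) {
    p <- sample(3:12, 1)
    wis <- stats::setNames(sample(1:4, p, replace = TRUE), paste0("f", 1:p))
    fc <- sample(c(0.2, 0.6, 1), p, replace = TRUE)
    r <- rank_features(wis, fc, orientation = "RANK_LOW_BEST")
    expect_identical(sort(r), seq_len(p))
    expect_identical(rank_features(wis, fc, orientation = "RANK_LOW_BEST"), r)
  }
})

test_that("interpretation categories cross strength with consistency", {
  wis <- stats::setNames(1:20, sprintf("f%02d", 1:20))
  fc <- rep(0.2, 20)
  fc[1] <- 1.0   # strong + consistent
  fc[2] <- 0.2   # strong + model-specific
  fc[10] <- 0.9  # moderate + consistent
  cat20 <- categorize(wis, fc, orientation = "RANK_LOW_BEST")
  expect_equal(as.character(cat20[1]), "ROBUST")
  expect_equal(as.character(cat20[2]), "MODEL_SPECIFIC")
  expect_equal(as.character(cat20[10]), "CONSISTENT_MODERATE")
  expect_equal(as.character(cat20[20]), "LOW_SIGNAL")
})

test_that("a unanimously top-ranked feature attains minimal WIS and full FC", {
  set.seed(31)
  outs <- lapply(1:4, function(j) {
    v <- c(star = 100, stats::setNames(runif(5, 0, 50), paste0("f", 1:5)))
    model_importance(paste0("m", j), v)
  })
  res <- wisfc(outs, wisfc_config(k = 1))
  star <- res[res$feature == "star", ]
  expect_equal(star$wis, 1)
  expect_equal(star$fc_count, 4L)
  expect_equal(star$final_rank, 1L)
})

test_that("aggregation is invariant to model and feature order", {
  outs <- random_outputs(5, 7, seed = 55)
  res1 <- wisfc(outs, wisfc_config(k = 3))
  shuffled <- lapply(rev(outs), function(o)
    model_importance(o$model_id, sample(o$values), o$metric, o$performance))
  res2 <- wisfc(shuffled, wisfc_config(k = 3))
  expect_equal(as.data.frame(res2), as.data.frame(res1), ignore_attr = TRUE)
})

test_that("the full pipeline ranks the worked example correctly", {
  res <- wisfc(worked_example_matrix())
  expect_identical(res$feature[res$final_rank == 1], "Blood Pressure")
  expect_equal(res$wis, c(2.2, 5.4))
  expect_equal(res$fc_fraction, c(1.0, 0.8))
  # composite uses the inverted (higher-is-better) scale over the 20-pool
  expect_equal(res$composite, c((20 + 1 - 2.2) * 1, (20 + 1 - 5.4) * 0.8))
})

test_that("softmax weighting shifts WIS toward the stronger model", {
  outs <- list(
    model_importance("weak",   c(A = 1, B = 10), performance = 0.5),
    model_importance("strong", c(A = 10, B = 1), performance = 5))
  res_eq <- wisfc(outs, wisfc_config(k = 1, weighting = "equal"))
  res_sm <- wisfc(outs, wisfc_config(k = 1, weighting = "softmax"))
  expect_equal(res_eq$wis, c(1.5, 1.5))
  expect_identical(res_sm$feature[res_sm$final_rank == 1], "A")
  outs_noperf <- list(model_importance("a", c(A = 1, B = 2)),
                      model_importance("b", c(A = 2, B = 1)))
  expect_error(wisfc(outs_noperf, wisfc_config(weighting = "softmax")),
               "performance")
})

test_that("fc_sweep reports FC across multiple thresholds", {
  m <- bp_chol_matrix()
  sw <- fc_sweep(m, ks = c(3, 10))
  expect_named(sw, c("feature", "fc_fraction_k3", "fc_fraction_k10"))
  expect_equal(sw$fc_fraction_k10[sw$feature == "Cholesterol"], 0.8)
  expect_equal(sw$fc_fraction_k3[sw$feature == "Cholesterol"], 0.6)
})
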