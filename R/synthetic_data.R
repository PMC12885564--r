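# Synthetic tabular cohorts with known ground-truth feature relevance: the
# testable stand-in for small clinical datasets whose registry data cannot
# be redistributed.

#' Generate a synthetic clinical-style cohort
#'
#' Draws an n x p Gaussian feature matrix (standard normal margins), plants
#' `s` truly informative features with effect sizes spaced across
#' `beta_range` (strongest first), and generates the outcome from a linear
#' (continuous) or logistic (binary) model. Optional equicorrelated feature
#' blocks emulate the redundant predictor groups common in clinical tables:
#' within a block of `block_size` consecutive features, every pair has
#' correlation `rho` (single-factor construction, margins remain N(0, 1)).
#'
#' Defaults mirror a small clinical cohort: a few hundred patients, 20
#' candidate predictors, 5 informative.
#'
#' @param n Rows (>= 10), default 300.
#' @param p Features, default 20. Named `f01..f<p>`.
#' @param s Number of informative features (`<= p`), default 5; these are
#'   features `f01..f0s`, with coefficients `seq(beta_range[2],
#'   beta_range[1], length.out = s)`.
#' @param beta_range Length-2 numeric: weakest and strongest effect size on
#'   the linear predictor scale (per SD of the feature), default
#'   `c(0.5, 1.5)`.
#' @param rho Within-block correlation in `[0, 0.95]`, default 0 (independent
#'   features).
#' @param block_size Features per correlation block when `rho > 0`, default 4.
#' @param outcome `"binary"` (Bernoulli with logistic link, intercept 0) or
#'   `"continuous"` (unit Gaussian noise).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return Object of class `synthetic_cohort`: list with `X` (matrix), `y`,
#'   `truth` (data frame: feature, beta, relevant), `correlation_blocks`,
#'   `outcome`, `seed`. Use [as.data.frame()] to get a modelling table with
#'   outcome column `y`.
#' @export
generate_cohort <- function(n = 300L, p = 20L, s = 5L,
                            beta_range = c(0.5, 1.5), rho = 0,
                            block_size = 4L,
                            outcome = c("binary", "continuous"),
                            seed = 1L) {
  outcome <- match.arg(outcome)
  stopifnot(n >= 10L, p >= 2L, s >= 0L, s <= p,
            length(beta_range) == 2L, all(beta_range >= 0),
            rho >= 0, rho <= 0.95, block_size >= 2L)
  set.seed(seed)

  features <- sprintf("f%02d", seq_len(p))
  blocks <- NULL
  if (rho > 0) {
    blocks <- split(seq_len(p), ceiling(seq_len(p) / block_size))
    X <- matrix(NA_real_, n, p)
    for (b in blocks) {
      z <- stats::rnorm(n)
      for (j in b)
        X[, j] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
    }
  } else {
    X <- matrix(stats::rnorm(n * p), n, p)
  }
  colnames(X) <- features

  beta <- numeric(p)
  if (s > 0)
    beta[seq_len(s)] <- seq(max(beta_range), min(beta_range), length.out = s)
  eta <- as.numeric(X %*% beta)
  y <- if (outcome == "binary") stats::rbinom(n, 1L, stats::plogis(eta))
       else eta + stats::rnorm(n)

  structure(
    list(X = X, y = y,
         truth = data.frame(feature = features, beta = beta,
                            relevant = beta != 0, stringsAsFactors = FALSE),
         correlation_blocks = blocks, rho = rho,
         outcome = outcome, seed = as.integer(seed)),
    class = "synthetic_cohort")
}

#' @export
as.data.frame.synthetic_cohort <- function(x, ...) {
  data.frame(x$X, y = x$y, check.names = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> n = %d, p = %d (%d informative), %s outcome, seed %d\n",
    nrow(x$X), ncol(x$X), sum(x$truth$relevant), x$outcome, x$seed))
  invisible(x)
}

#' Simulate disagreeing model rankings around a shared ground truth
#'
#' Emulates the explainer-disagreement phenomenon directly, without fitting
#' any model: each of `N` synthetic "models" ranks `p` features by a latent
#' score `p..1` (following `truth_order`) perturbed with Gaussian noise of
#' standard deviation `noise_level`. At `noise_level = 0` all rankings equal
#' the truth order; as the noise grows the rankings approach independent
#' uniform permutations.
#'
#' @param p Number of features.
#' @param N Number of synthetic models (>= 2 for downstream aggregation).
#' @param noise_level Non-negative perturbation SD on the latent score scale
#'   (the gap between adjacent true ranks is 1).
#' @param seed Integer seed.
#' @param truth_order Integer permutation of `1..p`: position `i` names the
#'   index of the i-th most important feature. Default `1:p`.
#' @param features Feature names, default `f01..f<p>`.
#' @return List of `N` [model_importance()] objects (metric
#'   `"synthetic_score"`), each assigning positive scores so that
#'   [rank_transform()] recovers the perturbed order.
#' @export
disagreement_rankings <- function(p, N, noise_level = 1, seed = 1L,
                                  truth_order = seq_len(p),
                                  features = sprintf("f%02d", seq_len(p))) {
  stopifnot(p >= 2L, N >= 1L, noise_level >= 0,
            length(truth_order) == p, setequal(truth_order, seq_len(p)),
            length(features) == p)
  true_score <- numeric(p)
  true_score[truth_order] <- p:1
  lapply(seq_len(N), function(j) {
    set.seed(seed + 7919L * j)
    latent <- true_score + noise_level * stats::rnorm(p)
    # convert to positive scores preserving the perturbed order
    score <- p + 1 - rank(-latent, ties.method = "first")
    model_importance(paste0("m", j),
                     stats::setNames(as.numeric(score), features),
                     metric = "synthetic_score")
  })
}

#' Worked two-feature example: pre-ranked matrix
#'
#' The canonical illustration of why strength and consistency are separate
#' axes: across five models (a pool of 20 candidate predictors), Blood
#' Pressure holds ranks `[1, 2, 4, 1, 3]` — never below fourth place — while
#' Cholesterol holds `[1, 8, 2, 15, 1]`, twice first yet once near the
#' bottom. Equal-weight WIS is 2.2 vs 5.4, and with `k = 10` FC is 5/5 vs
#' 4/5.
#'
#' @return A `rank_matrix` (RANK_LOW_BEST) with the two feature rows and five
#'   model columns, `pool_size = 20`.
#' @export
worked_example_matrix <- function() {
  outs <- read_importance_table(
    system.file("extdata", "worked_example_ranks.csv", package = "wisfc",
                mustWork = TRUE))
  m <- build_rank_matrix(outs, wisfc_config())
  m$pool_size <- 20L
  m
}

#' Churn walkthrough fixture
#'
#' A small cross-domain scenario: three models (logistic regression, decision
#' tree, gradient boosting) rank six customer-churn predictors. The models
#' agree that tenure dominates but disagree on the supporting cast; gradient
#' boosting alone promotes age. Shipped as a plain-CSV importance table.
#'
#' @return List of three [model_importance()] objects over six features.
#' @export
churn_example <- function() {
  read_importance_table(
    system.file("extdata", "churn_importance.csv", package = "wisfc",
                mustWork = TRUE))
}

#' Planted-feature recovery experiment
#'
#' Generates a fresh synthetic cohort per seed, runs the full pipeline
#' (model harness then consensus aggregation with equal weights), and counts
#' how many of the `s` planted informative features appear in the consensus
#' top-`k_top` versus each single model's top-`k_top` (by that model's own
#' importance ranking). The consensus is expected to recover at least as many
#' planted features on average as the weakest single model — typically more.
#'
#' @param n_seeds Number of independent cohorts, default 20.
#' @param n,p,s,beta_range,rho,outcome Passed to [generate_cohort()].
#' @param k_top Size of the inspected top set, default 5 (= `s`).
#' @param config Aggregation configuration, default [wisfc_config()].
#' @param folds,repeats Harness cross-validation geometry; default 3 x 1
#'   keeps the repeated-experiment runtime modest.
#' @param seed Base seed; cohort `i` uses `seed + 97 * i`.
#' @return Data frame of class `recovery_result`: one row per seed with the
#'   planted-feature hit count of the consensus (`wisfc`) and of every single
#'   model. Attribute `summary` holds the per-method means.
#' @export
recovery_experiment <- function(n_seeds = 20L, n = 300L, p = 20L, s = 5L,
                                beta_range = c(0.5, 1.5), rho = 0,
                                outcome = "binary", k_top = 5L,
                                config = wisfc_config(),
                                folds = 3L, repeats = 1L, seed = 1L) {
  stopifnot(n_seeds >= 1L, k_top >= 1L)
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cohort <- generate_cohort(n = n, p = p, s = s, beta_range = beta_range,
                              rho = rho, outcome = outcome,
                              seed = seed + 97L * i)
    task <- if (outcome == "binary") "CLASSIFICATION" else "REGRESSION"
    hr <- run_harness(as.data.frame(cohort), "y",
                      specs = default_model_suite(task, seed = seed + 97L * i),
                      folds = folds, repeats = repeats, seed = seed + 97L * i)
    planted <- cohort$truth$feature[cohort$truth$relevant]

    res <- wisfc(hr$importances, config)
    hits <- list(wisfc = length(intersect(
      res$feature[res$final_rank <= k_top], planted)))
    for (imp in hr$importances) {
      r <- rank_transform(imp)
      hits[[imp$model_id]] <-
        length(intersect(names(sort(r))[seq_len(k_top)], planted))
    }
    rows[[i]] <- data.frame(seed = seed + 97L * i, as.data.frame(hits))
  }
  out <- do.call(rbind, rows)
  structure(out, summary = colMeans(out[-1L]),
            class = c("recovery_result", "data.frame"))
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> %d seeds; mean planted features in top set:\n",
              nrow(x)))
  print(round(attr(x, "summary"), 2))
  invisible(x)
}
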