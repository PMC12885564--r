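# Domain types and normalization of heterogeneous per-model importance
# outputs onto a comparable scale, plus model-weight construction.

#' Per-model feature-importance output
#'
#' Container for one model's raw importance scores. Signed importance metrics
#' (e.g. linear regression coefficients) are converted to magnitudes on
#' construction: cross-model aggregation compares strength of association,
#' not direction, and sign tracking is deliberately out of scope.
#'
#' @param model_id Single string identifying the model.
#' @param values Named numeric vector mapping feature name to raw importance.
#'   Must be non-empty with finite values; unique names required. Negative
#'   values are replaced by their absolute value.
#' @param metric String naming the importance measure, e.g.
#'   `"abs_coefficient"`, `"impurity"`, `"permutation"`, `"mean_abs_shap"`.
#'   The special value `"rank"` marks pre-ranked input: values are importance
#'   ranks (1 = most important) and are used verbatim by
#'   [build_rank_matrix()] instead of being re-ranked.
#' @param performance Optional scalar: a higher-is-better validation score
#'   (accuracy, AUC, R-squared) measured on held-out data. Lower-is-better
#'   metrics (error rates) must be negated by the caller; the constructor
#'   cannot detect orientation. Used by [softmax_weights()].
#'
#' @return An object of class `model_importance`.
#' @examples
#' model_importance("logit", c(age = 1.4, bmi = 0.3), "abs_coefficient", 0.81)
#' @export
model_importance <- function(model_id, values, metric = "unknown",
                             performance = NA_real_) {
  stopifnot(is.character(model_id), length(model_id) == 1L, nzchar(model_id),
            is.character(metric), length(metric) == 1L)
  if (!is.numeric(values) || length(values) == 0L)
    stop("`values` must be a non-empty named numeric vector", call. = FALSE)
  nm <- names(values)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("all importance values must be named by feature", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate feature names in importance values: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  bad <- nm[!is.finite(values)]
  if (length(bad))
    stop("non-finite importance for feature(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (identical(metric, "rank") && any(values < 1))
    stop("pre-ranked input requires ranks >= 1", call. = FALSE)
  if (!is.na(performance) && !is.finite(performance))
    stop("`performance` must be finite (or NA when absent)", call. = FALSE)
  structure(
    list(model_id = model_id, values = abs(values), metric = metric,
         performance = as.numeric(performance)),
    class = "model_importance"
  )
}

#' @export
print.model_importance <- function(x, ...) {
  cat(sprintf("<model_importance> %s (%s), %d features%s\n",
              x$model_id, x$metric, length(x$values),
              if (is.na(x$performance)) ""
              else sprintf(", performance = %.4g", x$performance)))
  invisible(x)
}

#' Aggregation configuration
#'
#' Collects the tunable parameters of the consensus-ranking pipeline.
#'
#' @param k Positive integer: rank threshold for the frequency count (a
#'   feature "appears" in a model when its rank is `<= k`). Default 10.
#' @param weighting `"equal"` (every model weight 1/N) or `"softmax"`
#'   (weights proportional to `exp(performance / temperature)`).
#' @param normalization `"rank"` (ranks, 1 = most important, lower WIS is
#'   better) or `"sum"` (importances scaled to per-model shares summing to 1,
#'   higher WIS is better).
#' @param fc_threshold Fraction of models in `[0, 1]` a feature must appear
#'   in (top-k) to pass the consistency gate of joint selection. Default 0.5.
#' @param wis_quantile Fraction in `(0, 1]`: the best-WIS quantile a feature
#'   must reach to pass the strength gate. Default 0.25 (top quartile).
#' @param softmax_temperature Positive real; 1 gives the plain softmax over
#'   performances. Larger values flatten the weights, smaller sharpen them.
#' @param fill How to handle a (feature, model) cell where the model never
#'   reported that feature: `"worst"` assigns the worst possible rank (the
#'   pool size) or share 0 — non-appearance counts as evidence against the
#'   feature; `"exclude"` leaves the cell missing and renormalizes model
#'   weights per feature over the models that did report it.
#'
#' @return A list of class `wisfc_config`.
#' @export
wisfc_config <- function(k = 10L,
                         weighting = c("equal", "softmax"),
                         normalization = c("rank", "sum"),
                         fc_threshold = 0.5,
                         wis_quantile = 0.25,
                         softmax_temperature = 1,
                         fill = c("worst", "exclude")) {
  weighting <- match.arg(weighting)
  normalization <- match.arg(normalization)
  fill <- match.arg(fill)
  k <- as.integer(k)
  stopifnot(length(k) == 1L, !is.na(k), k >= 1L,
            is.numeric(fc_threshold), fc_threshold >= 0, fc_threshold <= 1,
            is.numeric(wis_quantile), wis_quantile > 0, wis_quantile <= 1,
            is.numeric(softmax_temperature), softmax_temperature > 0)
  structure(
    list(k = k, weighting = weighting, normalization = normalization,
         fc_threshold = fc_threshold, wis_quantile = wis_quantile,
         softmax_temperature = softmax_temperature, fill = fill),
    class = "wisfc_config"
  )
}

#' Rank-transform one model's raw importances
#'
#' Converts raw importance values to ranks: 1 = most important. Ties receive
#' the average of the ranks they span, so the result never depends on input
#' order. Scale-invariant: multiplying all importances by a positive constant
#' leaves the ranks unchanged.
#'
#' @param raw A [model_importance()] object.
#' @return Named numeric vector of ranks over `raw`'s features
#'   (orientation: lower is better).
#' @examples
#' rank_transform(model_importance("m", c(A = 0.5, B = 0.3, C = 0.2)))
#' @export
rank_transform <- function(raw) {
  stopifnot(inherits(raw, "model_importance"))
  v <- raw$values
  bad <- names(v)[!is.finite(v)]
  if (length(bad))
    stop("non-finite importance for feature(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  rank(-v, ties.method = "average")
}

#' Scale one model's importances to relative shares
#'
#' Divides each importance by the model's total so the values become a
#' relative importance share summing to 1 (orientation: higher is better).
#' Idempotent and order-preserving.
#'
#' @param raw A [model_importance()] object with at least one strictly
#'   positive value.
#' @return Named numeric vector of shares summing to 1.
#' @export
sum_scale <- function(raw) {
  stopifnot(inherits(raw, "model_importance"))
  v <- raw$values
  total <- sum(v)
  if (total <= 0)
    stop("all importances are zero for model '", raw$model_id,
         "': an uninformative model cannot be sum-scaled", call. = FALSE)
  v / total
}

#' Assemble per-model importances into a normalized feature x model matrix
#'
#' Each model's column is normalized independently (rank transform or sum
#' scaling, per `config$normalization`) so models with different importance
#' scales never contaminate each other. Features are the union of all
#' reported feature names; cells for features a model never reported are
#' filled per `config$fill`. Models whose `metric` is `"rank"` are taken as
#' pre-ranked and their values are preserved verbatim (ranks may then exceed
#' the number of listed features, e.g. when the list is a slice of a larger
#' candidate pool; the matrix records the implied pool size).
#'
#' @param outputs List of at least two [model_importance()] objects with
#'   unique model ids.
#' @param config A [wisfc_config()].
#' @return An object of class `rank_matrix`: list with `entries` (feature x
#'   model numeric matrix), `features`, `models`, `orientation`
#'   (`"RANK_LOW_BEST"` or `"SCORE_HIGH_BEST"`), `pool_size`, and
#'   `fill_policy_applied` (data frame of filled cells).
#' @export
build_rank_matrix <- function(outputs, config = wisfc_config()) {
  stopifnot(is.list(outputs), inherits(config, "wisfc_config"))
  if (length(outputs) < 2L)
    stop("aggregation requires >= 2 models; got ", length(outputs),
         call. = FALSE)
  ok <- vapply(outputs, inherits, logical(1), "model_importance")
  if (!all(ok))
    stop("`outputs` must be a list of model_importance objects", call. = FALSE)
  ids <- vapply(outputs, `[[`, character(1), "model_id")
  if (anyDuplicated(ids))
    stop("duplicate model_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  features <- sort(unique(unlist(lapply(outputs, function(o) names(o$values)))))
  p <- length(features)
  pre_ranked <- vapply(outputs, function(o) identical(o$metric, "rank"),
                       logical(1))
  if (config$normalization == "sum" && any(pre_ranked))
    stop("pre-ranked inputs (metric = \"rank\") cannot be sum-scaled; ",
         "use normalization = \"rank\"", call. = FALSE)

  cols <- vector("list", length(outputs))
  for (j in seq_along(outputs)) {
    cols[[j]] <- if (pre_ranked[j]) outputs[[j]]$values
      else if (config$normalization == "rank") rank_transform(outputs[[j]])
      else sum_scale(outputs[[j]])
  }
  # a pre-ranked slice of a wider candidate pool implies pool size >= max rank
  pool_size <- max(p, if (any(pre_ranked))
    ceiling(max(unlist(cols[pre_ranked]))) else 0L)

  entries <- matrix(NA_real_, nrow = p, ncol = length(outputs),
                    dimnames = list(features, ids))
  for (j in seq_along(cols)) entries[names(cols[[j]]), j] <- cols[[j]]

  filled <- which(is.na(entries), arr.ind = TRUE)
  if (config$fill == "worst" && nrow(filled)) {
    entries[is.na(entries)] <-
      if (config$normalization == "rank") pool_size else 0
  }
  fill_log <- data.frame(
    feature = if (nrow(filled)) features[filled[, 1L]] else character(0),
    model   = if (nrow(filled)) ids[filled[, 2L]] else character(0),
    policy  = rep(config$fill, nrow(filled)),
    stringsAsFactors = FALSE
  )

  structure(
    list(entries = entries, features = features, models = ids,
         orientation = if (config$normalization == "rank") "RANK_LOW_BEST"
                       else "SCORE_HIGH_BEST",
         pool_size = pool_size,
         fill_policy_applied = fill_log),
    class = "rank_matrix"
  )
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> %d features x %d models, %s%s\n",
              length(x$features), length(x$models), x$orientation,
              if (nrow(x$fill_policy_applied))
                sprintf(", %d cells filled (%s)",
                        nrow(x$fill_policy_applied),
                        x$fill_policy_applied$policy[1L]) else ""))
  print(utils::head(x$entries, 10L))
  if (length(x$features) > 10L) cat("...\n")
  invisible(x)
}

#' Softmax model weights from validation performance
#'
#' Computes `w_j = exp(perf_j / T) / sum_k exp(perf_k / T)`. At temperature
#' `T = 1` this is the plain softmax over performances. Weights are positive,
#' sum to 1, invariant to adding a constant to all performances, and strictly
#' order-preserving.
#'
#' Performances must be higher-is-better scores measured on held-out data
#' (validation folds), never the training set: softmax weighting of training
#' scores systematically overweights the most overfit model.
#'
#' @param performances Numeric vector of finite validation scores on a common
#'   scale.
#' @param temperature Positive scalar; default 1.
#' @param model_ids Optional character vector of ids (defaults to names of
#'   `performances` or `m1..mN`).
#' @return Object of class `weight_vector`: list with `model_ids` and
#'   `weights` (summing to 1).
#' @examples
#' softmax_weights(c(logit = 0.78, rf = 0.84, svm = 0.80))
#' @export
softmax_weights <- function(performances, temperature = 1, model_ids = NULL) {
  if (!is.numeric(performances) || length(performances) == 0L)
    stop("`performances` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(performances)))
    stop("non-finite performance value(s) at position(s): ",
         paste(which(!is.finite(performances)), collapse = ", "),
         call. = FALSE)
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  if (is.null(model_ids))
    model_ids <- names(performances) %||%
      paste0("m", seq_along(performances))
  stopifnot(length(model_ids) == length(performances))
  # subtract the max before exponentiating: numerically safe and makes the
  # documented shift-invariance exact
  z <- (performances - max(performances)) / temperature
  w <- exp(z) / sum(exp(z))
  structure(list(model_ids = model_ids, weights = unname(w)),
            class = "weight_vector")
}

#' Equal model weights
#'
#' @param model_ids Character vector of model ids.
#' @return A `weight_vector` with every weight `1/N`.
#' @export
equal_weights <- function(model_ids) {
  stopifnot(is.character(model_ids), length(model_ids) >= 1L)
  structure(list(model_ids = model_ids,
                 weights = rep(1 / length(model_ids), length(model_ids))),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector>\n")
  print(stats::setNames(round(x$weights, 4), x$model_ids))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
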