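# WIS, FC, composite score, selection rules, final ranking and the
# interpretation categories.

orientation_of <- function(x, default = NULL) {
  attr(x, "wisfc_orientation") %||% default
}

with_orientation <- function(x, orientation) {
  attr(x, "wisfc_orientation") <- orientation
  x
}

#' Weighted importance score
#'
#' Per-feature weighted sum of normalized importances across models:
#' `WIS(f) = sum_j w_j * R_j(f)`. With equal weights this is the arithmetic
#' mean of the feature's normalized importances — under rank normalization,
#' its mean rank across models. The result carries the matrix orientation
#' forward: lower is better under `RANK_LOW_BEST`, higher is better under
#' `SCORE_HIGH_BEST`.
#'
#' Cells left missing by the `"exclude"` fill policy are handled by
#' renormalizing the weights per feature over the models that reported it.
#'
#' @param matrix A [build_rank_matrix()] result.
#' @param weights A `weight_vector` aligned with `matrix$models` (any order;
#'   matched by id).
#' @return Named numeric vector of WIS values with a `wisfc_orientation`
#'   attribute.
#' @export
weighted_importance_score <- function(matrix, weights) {
  stopifnot(inherits(matrix, "rank_matrix"), inherits(weights, "weight_vector"))
  if (!setequal(weights$model_ids, matrix$models) ||
      length(weights$model_ids) != length(matrix$models))
    stop("weight vector model ids do not match the matrix models", call. = FALSE)
  w <- weights$weights[match(matrix$models, weights$model_ids)]
  e <- matrix$entries
  if (anyNA(e)) {
    obs <- !is.na(e)
    denom <- as.numeric(obs %*% w)
    if (any(denom == 0))
      stop("feature(s) reported by no model with positive weight: ",
           paste(matrix$features[denom == 0], collapse = ", "), call. = FALSE)
    e0 <- e; e0[!obs] <- 0
    wis <- as.numeric(e0 %*% w) / denom
  } else {
    wis <- as.numeric(e %*% w)
  }
  names(wis) <- matrix$features
  with_orientation(wis, matrix$orientation)
}

#' Frequency count over top-k lists
#'
#' For each feature, counts in how many models it appears within the top-k of
#' that model's importance ranking (rank `<= k`), and expresses the count as
#' a fraction and percentage of the ensemble size N. Monotone non-decreasing
#' in `k`; equals N for every feature once `k` reaches the candidate pool
#' size. One model, one vote: model weights never enter FC.
#'
#' @param matrix A `rank_matrix` in `RANK_LOW_BEST` orientation.
#' @param k Positive integer rank threshold.
#' @return Data frame with columns `feature`, `fc_count`, `fc_fraction`,
#'   `fc_percent`.
#' @export
frequency_count <- function(matrix, k = 10L) {
  stopifnot(inherits(matrix, "rank_matrix"))
  k <- as.integer(k)
  stopifnot(length(k) == 1L, !is.na(k), k >= 1L)
  if (matrix$orientation != "RANK_LOW_BEST")
    stop("frequency_count needs per-model ranks: rebuild the matrix with ",
         "normalization = \"rank\"", call. = FALSE)
  n_models <- length(matrix$models)
  fc <- rowSums(matrix$entries <= k, na.rm = TRUE)
  data.frame(feature = matrix$features,
             fc_count = as.integer(fc),
             fc_fraction = fc / n_models,
             fc_percent = 100 * fc / n_models,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Frequency counts across a sweep of k values
#'
#' Robust features keep a high FC across a range of reasonable `k`; a feature
#' whose FC collapses when `k` shrinks was hovering near the cutoff.
#'
#' @param matrix A `rank_matrix` in `RANK_LOW_BEST` orientation.
#' @param ks Integer vector of thresholds (default `c(3, 5, 10, 15)`).
#' @return Data frame: `feature` plus one `fc_fraction_k<k>` column per `k`.
#' @export
fc_sweep <- function(matrix, ks = c(3L, 5L, 10L, 15L)) {
  stopifnot(length(ks) >= 1L)
  ks <- sort(unique(as.integer(ks)))
  out <- data.frame(feature = matrix$features, stringsAsFactors = FALSE)
  for (k in ks)
    out[[sprintf("fc_fraction_k%d", k)]] <- frequency_count(matrix, k)$fc_fraction
  out
}

#' Invert a rank-based WIS to a higher-is-better score
#'
#' Applies the order-reversing affine map `p + 1 - wis`, sending the best
#' possible mean rank 1 to `p` and the worst possible `p` to 1.
#'
#' @param wis_rank_based Numeric vector of rank-oriented WIS values, each in
#'   `[1, p]`.
#' @param p Candidate pool size (total feature count).
#' @return Numeric vector oriented higher-is-better (attribute
#'   `wisfc_orientation = "SCORE_HIGH_BEST"`).
#' @export
invert_wis <- function(wis_rank_based, p) {
  stopifnot(is.numeric(wis_rank_based), length(wis_rank_based) >= 1L,
            is.numeric(p), length(p) == 1L, p >= 1)
  ori <- orientation_of(wis_rank_based)
  if (!is.null(ori) && ori != "RANK_LOW_BEST")
    stop("input is already oriented higher-is-better", call. = FALSE)
  bad <- wis_rank_based < 1 | wis_rank_based > p
  if (any(bad))
    stop("WIS value(s) outside [1, p]: ",
         paste(format(wis_rank_based[bad]), collapse = ", "), call. = FALSE)
  with_orientation(p + 1 - unclass(wis_rank_based), "SCORE_HIGH_BEST")
}

#' Composite consensus score
#'
#' `C(f) = WIS(f) * FC(f) / N`, discounting a feature's strength by the
#' fraction of models that corroborate it. Requires WIS on a higher-is-better
#' scale — the product only penalizes inconsistency in that orientation — so
#' rank-based WIS must be inverted first via [invert_wis()]; passing a
#' rank-oriented vector is an error rather than a silent sign flip.
#'
#' @param wis_high_best Numeric vector of higher-is-better WIS values.
#' @param fc_count Integer vector of per-feature model counts in `[0, N]`.
#' @param n_models Ensemble size N.
#' @return Numeric vector: `wis * fc_count / n_models`.
#' @export
composite_score <- function(wis_high_best, fc_count, n_models) {
  stopifnot(is.numeric(wis_high_best), is.numeric(fc_count),
            length(fc_count) == length(wis_high_best),
            length(n_models) == 1L, n_models >= 1)
  if (identical(orientation_of(wis_high_best), "RANK_LOW_BEST"))
    stop("composite_score needs higher-is-better WIS; apply invert_wis() ",
         "to rank-based scores first", call. = FALSE)
  if (any(fc_count < 0 | fc_count > n_models))
    stop("fc_count must lie in [0, n_models]", call. = FALSE)
  unclass(wis_high_best) * fc_count / n_models
}

# value at the best-side q-quantile boundary (nearest rank, inclusive):
# features at-or-better than this value form the "top q" set
wis_quantile_cut <- function(wis, q, orientation) {
  stopifnot(q > 0, q <= 1)
  idx <- ceiling(q * length(wis))
  sorted <- sort(unclass(wis), decreasing = (orientation == "SCORE_HIGH_BEST"))
  sorted[idx]
}

wis_at_or_better <- function(wis, cut, orientation) {
  if (orientation == "RANK_LOW_BEST") unclass(wis) <= cut
  else unclass(wis) >= cut
}

#' Joint selection of robust features
#'
#' Flags a feature as robust when it passes both gates: consistency
#' (`fc_fraction >= fc_threshold`, e.g. reported by at least half the models)
#' and strength (WIS at or better than the `wis_quantile` best quantile of
#' all candidate features, e.g. top quartile). The quantile boundary is
#' computed by nearest rank and is inclusive, so exact ties at the cut are
#' selected.
#'
#' @param wis Named numeric WIS vector (orientation taken from its
#'   `wisfc_orientation` attribute, or given explicitly).
#' @param fc_fraction Numeric vector aligned with `wis`.
#' @param fc_threshold Consistency gate in `[0, 1]`; default 0.5.
#' @param wis_quantile Strength gate in `(0, 1]`; default 0.25.
#' @param orientation `"RANK_LOW_BEST"` or `"SCORE_HIGH_BEST"`; overrides the
#'   attribute when given.
#' @return Logical vector of selection flags.
#' @export
joint_select <- function(wis, fc_fraction, fc_threshold = 0.5,
                         wis_quantile = 0.25, orientation = NULL) {
  if (length(wis) == 0L) stop("empty feature set", call. = FALSE)
  stopifnot(length(fc_fraction) == length(wis),
            fc_threshold >= 0, fc_threshold <= 1,
            wis_quantile > 0, wis_quantile <= 1)
  orientation <- orientation %||% orientation_of(wis) %||%
    stop("WIS orientation unknown: pass `orientation`", call. = FALSE)
  cut <- wis_quantile_cut(wis, wis_quantile, orientation)
  fc_fraction >= fc_threshold & wis_at_or_better(wis, cut, orientation)
}

#' Final consensus ranking
#'
#' Sorts features primarily by WIS (best first per orientation), breaking WIS
#' ties by higher FC, and remaining exact ties lexicographically by feature
#' name so the ranking is a reproducible total order.
#'
#' @inheritParams joint_select
#' @param features Character vector of feature names (defaults to
#'   `names(wis)`).
#' @return Integer vector of final ranks (a permutation of `1..p`) aligned
#'   with the input order.
#' @export
rank_features <- function(wis, fc_fraction, orientation = NULL,
                          features = names(wis)) {
  if (length(wis) == 0L) stop("empty feature set", call. = FALSE)
  stopifnot(length(fc_fraction) == length(wis),
            !is.null(features), length(features) == length(wis))
  orientation <- orientation %||% orientation_of(wis) %||%
    stop("WIS orientation unknown: pass `orientation`", call. = FALSE)
  key <- if (orientation == "RANK_LOW_BEST") unclass(wis) else -unclass(wis)
  ord <- order(key, -fc_fraction, features)
  ranks <- integer(length(wis))
  ranks[ord] <- seq_along(ord)
  ranks
}

#' Interpretation categories from the WIS x FC cross
#'
#' Crosses WIS strength (at or better than the `wis_quantile` best quantile)
#' with FC consistency (`fc_fraction >= fc_split`):
#' * strong WIS, high FC — `ROBUST`: report with confidence;
#' * strong WIS, low FC — `MODEL_SPECIFIC`: one model class drives the
#'   signal, investigate before trusting;
#' * moderate WIS, high FC — `CONSISTENT_MODERATE`: never a top feature but
#'   corroborated everywhere, a candidate for follow-up;
#' * neither — `LOW_SIGNAL`.
#'
#' @inheritParams joint_select
#' @param fc_split FC fraction separating high from low consistency
#'   (default 0.5).
#' @return Factor with levels `ROBUST`, `MODEL_SPECIFIC`,
#'   `CONSISTENT_MODERATE`, `LOW_SIGNAL`.
#' @export
categorize <- function(wis, fc_fraction, wis_quantile = 0.25, fc_split = 0.5,
                       orientation = NULL) {
  if (length(wis) == 0L) stop("empty feature set", call. = FALSE)
  orientation <- orientation %||% orientation_of(wis) %||%
    stop("WIS orientation unknown: pass `orientation`", call. = FALSE)
  cut <- wis_quantile_cut(wis, wis_quantile, orientation)
  strong <- wis_at_or_better(wis, cut, orientation)
  high_fc <- fc_fraction >= fc_split
  out <- ifelse(strong & high_fc, "ROBUST",
         ifelse(strong & !high_fc, "MODEL_SPECIFIC",
         ifelse(high_fc, "CONSISTENT_MODERATE", "LOW_SIGNAL")))
  factor(out, levels = c("ROBUST", "MODEL_SPECIFIC", "CONSISTENT_MODERATE",
                         "LOW_SIGNAL"))
}

#' Consensus feature ranking across a model ensemble
#'
#' End-to-end aggregation: normalizes every model's importances onto a common
#' scale, computes the weighted importance score (WIS) and the top-k
#' frequency count (FC), derives the composite score, the joint-criteria
#' selection flags, the interpretation category and the final rank.
#'
#' With rank normalization (the default) WIS is a weighted mean rank, and the
#' composite score is computed from its higher-is-better inversion
#' `p + 1 - WIS` so that low-frequency features are penalized, never
#' rewarded.
#'
#' @param outputs List of [model_importance()] objects (>= 2, unique ids), or
#'   a pre-built `rank_matrix`.
#' @param config A [wisfc_config()].
#' @param weights Optional `weight_vector`; when `NULL`, built per
#'   `config$weighting` (softmax weighting requires every model to carry a
#'   `performance` value and is unavailable when `outputs` is a bare matrix).
#' @return A data frame of class `wisfc_result`, one row per feature, sorted
#'   by `final_rank`, with columns `feature`, `wis`, `fc_count`,
#'   `fc_fraction`, `fc_percent`, `composite`, `category`, `selected`,
#'   `final_rank`. Attributes: `config`, `weights`, `orientation`,
#'   `n_models`, `pool_size`.
#' @examples
#' outs <- list(
#'   model_importance("logit", c(age = 2.0, bmi = 1.2, smoker = 0.1)),
#'   model_importance("rf",    c(age = 30,  bmi = 5,   smoker = 9)),
#'   model_importance("gbm",   c(age = 0.5, bmi = 0.4, smoker = 0.02)))
#' wisfc(outs, wisfc_config(k = 2))
#' @export
wisfc <- function(outputs, config = wisfc_config(), weights = NULL) {
  stopifnot(inherits(config, "wisfc_config"))

  if (inherits(outputs, "rank_matrix")) {
    rank_mat <- outputs
    if (rank_mat$orientation != "RANK_LOW_BEST")
      stop("a pre-built matrix must be in RANK_LOW_BEST orientation",
           call. = FALSE)
    score_mat <- NULL
    performances <- NULL
  } else {
    rank_cfg <- config
    rank_cfg$normalization <- "rank"
    rank_mat <- build_rank_matrix(outputs, rank_cfg)
    score_mat <- if (config$normalization == "sum")
      build_rank_matrix(outputs, config) else NULL
    performances <- vapply(outputs, `[[`, numeric(1), "performance")
    names(performances) <- rank_mat$models
  }

  if (is.null(weights)) {
    weights <- if (config$weighting == "equal") {
      equal_weights(rank_mat$models)
    } else {
      if (is.null(performances) || anyNA(performances))
        stop("softmax weighting requires a validation performance for every ",
             "model", call. = FALSE)
      softmax_weights(performances, temperature = config$softmax_temperature,
                      model_ids = names(performances))
    }
  }

  wis_mat <- score_mat %||% rank_mat
  wis <- weighted_importance_score(wis_mat, weights)
  fc <- frequency_count(rank_mat, config$k)
  stopifnot(identical(fc$feature, names(wis)))

  wis_high <- if (wis_mat$orientation == "RANK_LOW_BEST")
    invert_wis(wis, rank_mat$pool_size) else wis
  composite <- composite_score(wis_high, fc$fc_count, length(rank_mat$models))

  selected <- joint_select(wis, fc$fc_fraction,
                           fc_threshold = config$fc_threshold,
                           wis_quantile = config$wis_quantile)
  category <- categorize(wis, fc$fc_fraction,
                         wis_quantile = config$wis_quantile,
                         fc_split = config$fc_threshold)
  final_rank <- rank_features(wis, fc$fc_fraction)

  res <- data.frame(feature = fc$feature,
                    wis = unclass(unname(wis)),
                    fc_count = fc$fc_count,
                    fc_fraction = fc$fc_fraction,
                    fc_percent = fc$fc_percent,
                    composite = composite,
                    category = category,
                    selected = selected,
                    final_rank = final_rank,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$final_rank), , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            config = config,
            weights = weights,
            orientation = wis_mat$orientation,
            n_models = length(rank_mat$models),
            pool_size = rank_mat$pool_size,
            class = c("wisfc_result", "data.frame"))
}

#' @export
`[.wisfc_result` <- function(x, ...) {
  # a subset is no longer the full consensus table; return a plain data frame
  out <- NextMethod()
  if (is.data.frame(out)) {
    class(out) <- "data.frame"
    attr(out, "config") <- NULL
    attr(out, "weights") <- NULL
  }
  out
}

#' @export
print.wisfc_result <- function(x, digits = 3, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Consensus feature ranking over %d models (k = %d, %s weights, %s WIS)\n",
    attr(x, "n_models"), cfg$k, cfg$weighting,
    if (attr(x, "orientation") == "RANK_LOW_BEST") "rank-based (lower better)"
    else "share-based (higher better)"))
  df <- as.data.frame(x)
  df$wis <- round(df$wis, digits)
  df$composite <- round(df$composite, digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Scatter of consensus strength vs consistency
#'
#' Plots WIS (x, oriented so right = stronger) against FC fraction (y) with
#' the joint-selection gates drawn as reference lines.
#'
#' @param x A `wisfc_result`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.wisfc_result <- function(x, ...) {
  cfg <- attr(x, "config")
  low_best <- attr(x, "orientation") == "RANK_LOW_BEST"
  wis <- if (low_best) -x$wis else x$wis
  graphics::plot(wis, x$fc_fraction,
                 xlab = if (low_best) "WIS (negated mean rank)" else "WIS (share)",
                 ylab = "FC fraction", ylim = c(0, 1),
                 pch = ifelse(x$selected, 19, 1), ...)
  graphics::abline(h = cfg$fc_threshold, lty = 2, col = "grey50")
  graphics::text(wis, x$fc_fraction, labels = x$feature, pos = 3, cex = 0.7)
  invisible(x)
}
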