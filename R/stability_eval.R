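# Quantify how stable top-k feature sets are across data resamples, for the
# consensus ranking versus each single model.

#' Mean pairwise Jaccard similarity of feature sets
#'
#' `|A intersect B| / |A union B|` averaged over all unordered pairs.
#' Identical sets give 1, disjoint sets 0.
#'
#' @param sets List of >= 2 non-empty character vectors.
#' @return Scalar in `[0, 1]`.
#' @examples
#' topk_jaccard(list(c("A", "B"), c("B", "C")))  # 1/3
#' @export
topk_jaccard <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (any(lengths(sets) == 0L))
    stop("empty feature set in input", call. = FALSE)
  sets <- lapply(sets, unique)
  pairs <- utils::combn(length(sets), 2L)
  mean(apply(pairs, 2L, function(ij) {
    a <- sets[[ij[1L]]]; b <- sets[[ij[2L]]]
    length(intersect(a, b)) / length(union(a, b))
  }))
}

top_k_set <- function(ranks, k) names(sort(ranks))[seq_len(min(k, length(ranks)))]

#' Bootstrap stability of top-k feature sets
#'
#' For each of `B` seeded bootstrap resamples of the rows, runs the model
#' harness and records the top-`k` feature set of every single model (by its
#' own importance ranking) and of the consensus ranking. Stability per method
#' is the mean pairwise Jaccard similarity of its `B` top-`k` sets; every
#' method is evaluated on the identical sequence of resamples, so the
#' comparison is paired. Aggregating diverse models is expected to yield
#' top-`k` sets at least as stable as any single model's.
#'
#' @param data Data frame (outcome column plus numeric features).
#' @param outcome Outcome column name.
#' @param specs Model specs; default [default_model_suite()] for the
#'   outcome's task.
#' @param B Number of bootstrap resamples (>= 2), default 20.
#' @param k Top-set size, default 5.
#' @param config Aggregation configuration, default [wisfc_config()].
#' @param folds,repeats Harness cross-validation geometry, default 3 x 1.
#' @param seed Base seed.
#' @param resample_seeds Optional integer vector of length `B` overriding the
#'   per-resample seeds (`seed + 1..B` by default).
#' @return Data frame of class `stability_report` with columns `method` and
#'   `mean_jaccard`, consensus row first. Attributes: `B`, `k`,
#'   `scheme = "bootstrap"`, `seed`, `top_sets`.
#' @export
stability_experiment <- function(data, outcome, specs = NULL, B = 20L,
                                 k = 5L, config = wisfc_config(),
                                 folds = 3L, repeats = 1L, seed = 1L,
                                 resample_seeds = NULL) {
  stopifnot(is.data.frame(data), B >= 2L, k >= 1L)
  resample_seeds <- resample_seeds %||% (seed + seq_len(B))
  stopifnot(length(resample_seeds) == B)
  n <- nrow(data)

  top_sets <- list()
  for (b in seq_len(B)) {
    set.seed(resample_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    hr <- tryCatch(
      run_harness(data[idx, , drop = FALSE], outcome, specs = specs,
                  folds = folds, repeats = repeats, seed = resample_seeds[b]),
      error = function(e)
        stop("harness failed on resample ", b, ": ", conditionMessage(e),
             call. = FALSE))
    res <- wisfc(hr$importances, config)
    top_sets[["wisfc"]][[b]] <- res$feature[res$final_rank <= k]
    for (imp in hr$importances)
      top_sets[[imp$model_id]][[b]] <- top_k_set(rank_transform(imp), k)
  }

  report <- data.frame(
    method = names(top_sets),
    mean_jaccard = vapply(top_sets, topk_jaccard, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(report, B = B, k = k, scheme = "bootstrap", seed = seed,
            top_sets = top_sets,
            class = c("stability_report", "data.frame"))
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "Top-%d set stability over %d bootstrap resamples (mean pairwise Jaccard)\n",
    attr(x, "k"), attr(x, "B")))
  df <- as.data.frame(x)
  df$mean_jaccard <- round(df$mean_jaccard, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
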