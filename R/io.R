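# File formats: the long-format importance-table interchange CSV, matrix
# dumps, and the ranking report (CSV + JSON with config echo).

REQUIRED_COLUMNS <- c("model_id", "feature", "importance", "metric",
                      "performance")

#' Read a long-format importance table
#'
#' Expected CSV header: `model_id,feature,importance,metric,performance`
#' (UTF-8, `.` decimal separator). One row per (model, feature); `metric` and
#' `performance` must be constant within a model and `performance` may be
#' empty. Extra columns are ignored.
#'
#' @param path Path to the CSV file.
#' @return List of [model_importance()] objects, one per distinct `model_id`
#'   in order of first appearance.
#' @export
read_importance_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("importance table is empty", call. = FALSE)

  dup <- duplicated(df[c("model_id", "feature")])
  if (any(dup))
    stop("duplicate (model_id, feature) row(s) at line(s): ",
         paste(which(dup) + 1L, collapse = ", "),  # +1 for the header line
         call. = FALSE)
  imp_num <- suppressWarnings(as.numeric(df$importance))
  bad <- which(is.na(imp_num))
  if (length(bad))
    stop("non-numeric importance at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  df$importance <- imp_num
  df$performance <- suppressWarnings(as.numeric(df$performance))

  lapply(split(df, factor(df$model_id, levels = unique(df$model_id))),
         function(g) {
    if (length(unique(g$metric)) != 1L)
      stop("model '", g$model_id[1L], "' mixes importance metrics",
           call. = FALSE)
    perf <- unique(g$performance)
    if (length(perf) != 1L)
      stop("model '", g$model_id[1L], "' has inconsistent performance values",
           call. = FALSE)
    model_importance(g$model_id[1L],
                     stats::setNames(g$importance, g$feature),
                     metric = g$metric[1L], performance = perf)
  })
}

#' Write a long-format importance table
#'
#' Inverse of [read_importance_table()]: round-trips content exactly (up to
#' row order and numeric formatting).
#'
#' @param outputs List of [model_importance()] objects (or a
#'   `harness_result`).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_importance_table <- function(outputs, path) {
  if (inherits(outputs, "harness_result")) outputs <- outputs$importances
  rows <- lapply(outputs, function(o)
    data.frame(model_id = o$model_id, feature = names(o$values),
               importance = unname(o$values), metric = o$metric,
               performance = o$performance, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Dump a normalized matrix as wide CSV plus JSON sidecar
#'
#' Rows are features, columns model ids; the sidecar records orientation,
#' pool size and the applied fill policy.
#'
#' @param matrix A `rank_matrix`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return Invisibly, `path`.
#' @export
write_rank_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "rank_matrix"))
  df <- data.frame(feature = matrix$features, matrix$entries,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  meta <- list(orientation = matrix$orientation,
               pool_size = matrix$pool_size,
               models = matrix$models,
               filled_cells = matrix$fill_policy_applied)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

config_fingerprint <- function(config, seed = NULL) {
  payload <- jsonlite::toJSON(list(config = unclass(config), seed = seed),
                              auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(payload, tmp)
  unname(tools::md5sum(tmp))
}

#' Write the consensus ranking report
#'
#' Emits `ranking.csv` (one row per feature: wis, fc, composite, category,
#' final rank, selection flag), `ranking.json` (the same records plus the
#' full configuration echo, model weights, seed and a config fingerprint so
#' reruns are byte-comparable), and optionally `fc_sweep.csv` with FC across
#' several `k` values.
#'
#' @param result A [wisfc()] result.
#' @param dir Output directory (created if absent).
#' @param seed Seed to record in the report metadata.
#' @param sweep Optional data frame from [fc_sweep()].
#' @return Invisibly, the paths written.
#' @export
write_wisfc_report <- function(result, dir, seed = NULL, sweep = NULL) {
  stopifnot(inherits(result, "wisfc_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(result, "config")
  w <- attr(result, "weights")

  csv_path <- file.path(dir, "ranking.csv")
  df <- as.data.frame(result)
  df <- df[c("feature", "wis", "fc_count", "fc_fraction", "fc_percent",
             "composite", "category", "final_rank", "selected")]
  utils::write.csv(df, csv_path, row.names = FALSE, fileEncoding = "UTF-8")

  json_path <- file.path(dir, "ranking.json")
  jsonlite::write_json(
    list(config = unclass(cfg),
         seed = seed,
         config_fingerprint = config_fingerprint(cfg, seed),
         n_models = attr(result, "n_models"),
         orientation = attr(result, "orientation"),
         weights = stats::setNames(as.list(w$weights), w$model_ids),
         ranking = df),
    json_path, auto_unbox = TRUE, digits = NA)

  paths <- c(csv_path, json_path)
  if (!is.null(sweep)) {
    sweep_path <- file.path(dir, "fc_sweep.csv")
    utils::write.csv(sweep, sweep_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, sweep_path)
  }
  invisible(paths)
}
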