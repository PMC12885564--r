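# Brute-force ensemble driver: fit a diverse suite of standard model
# families on one tabular dataset under repeated cross-validation, extract
# per-model importances and held-out performance.

FAMILIES <- c("LINEAR", "DECISION_TREE", "RANDOM_FOREST",
              "GRADIENT_BOOSTING", "KERNEL_SVM")
TREE_FAMILIES <- c("DECISION_TREE", "RANDOM_FOREST", "GRADIENT_BOOSTING")
BACKENDS <- c("COEFFICIENT_MAGNITUDE", "IMPURITY", "PERMUTATION")

#' Specification of one ensemble member
#'
#' @param family One of `"LINEAR"` (logistic/linear regression),
#'   `"DECISION_TREE"` (rpart), `"RANDOM_FOREST"` (ranger),
#'   `"GRADIENT_BOOSTING"` (xgboost), `"KERNEL_SVM"` (e1071 radial SVM).
#' @param task `"CLASSIFICATION"` or `"REGRESSION"`.
#' @param importance_backend `"COEFFICIENT_MAGNITUDE"` (LINEAR only; absolute
#'   standardized coefficients), `"IMPURITY"` (tree families only; impurity /
#'   gain importance), or `"PERMUTATION"` (any family; model-agnostic).
#' @param hyperparameters Named list passed to the underlying fitter.
#' @param seed Integer seed governing this model's fitting randomness.
#' @param model_id Identifier used in the importance output; defaults to the
#'   lower-cased family name.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family, task = c("CLASSIFICATION", "REGRESSION"),
                       importance_backend = NULL, hyperparameters = list(),
                       seed = 1L, model_id = NULL) {
  family <- match.arg(family, FAMILIES)
  task <- match.arg(task)
  if (is.null(importance_backend))
    importance_backend <- switch(family,
      LINEAR = "COEFFICIENT_MAGNITUDE",
      KERNEL_SVM = "PERMUTATION",
      "IMPURITY")
  importance_backend <- match.arg(importance_backend, BACKENDS)
  if (importance_backend == "COEFFICIENT_MAGNITUDE" && family != "LINEAR")
    stop("COEFFICIENT_MAGNITUDE importance is only defined for LINEAR models",
         call. = FALSE)
  if (importance_backend == "IMPURITY" && !family %in% TREE_FAMILIES)
    stop("IMPURITY importance is only defined for tree-based families",
         call. = FALSE)
  structure(list(family = family, task = task,
                 importance_backend = importance_backend,
                 hyperparameters = hyperparameters,
                 seed = as.integer(seed),
                 model_id = model_id %||% tolower(family)),
            class = "model_spec")
}

#' The default diverse model suite
#'
#' A brute-force ensemble of five standard families spanning linear,
#' single-tree, bagged-tree, boosted-tree and kernel methods: logistic (or
#' linear) regression with coefficient-magnitude importance, a decision tree
#' and a random forest with impurity importance, gradient boosting with gain
#' importance, and a radial-kernel SVM explained by permutation importance
#' (the model-agnostic attribution used here for kernel methods).
#'
#' @param task `"CLASSIFICATION"` or `"REGRESSION"`.
#' @param seed Base integer seed; member `i` gets `seed + i`.
#' @return List of five [model_spec()] objects.
#' @export
default_model_suite <- function(task = c("CLASSIFICATION", "REGRESSION"),
                                seed = 1L) {
  task <- match.arg(task)
  fams <- FAMILIES
  lapply(seq_along(fams), function(i)
    model_spec(fams[i], task = task, seed = seed + i))
}

#' Permutation importance of a fitted model
#'
#' For each feature, the drop in a higher-is-better metric when that
#' feature's column is randomly permuted, averaged over `n_repeats` seeded
#' permutations. The baseline metric is computed once on the unpermuted data.
#' A feature the model ignores scores approximately zero.
#'
#' @param predict_fun Function `(X) -> predictions` for the fitted model.
#' @param X Data frame or matrix of features.
#' @param y True outcomes.
#' @param metric_fun Function `(truth, predicted) -> scalar`, higher is
#'   better (e.g. accuracy or R-squared).
#' @param n_repeats Number of permutations per feature (>= 1), default 5.
#' @param seed Integer seed for the permutation stream.
#' @return Named numeric vector: mean metric drop per feature.
#' @export
permutation_importance <- function(predict_fun, X, y, metric_fun,
                                   n_repeats = 5L, seed = 1L) {
  stopifnot(is.function(predict_fun), is.function(metric_fun),
            n_repeats >= 1L)
  X <- as.data.frame(X)
  baseline <- metric_fun(y, predict_fun(X))
  if (!is.finite(baseline))
    stop("performance metric is undefined on this data (baseline is not ",
         "finite)", call. = FALSE)
  set.seed(seed)
  drops <- vapply(seq_along(X), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[[j]] <- X[[j]][sample.int(nrow(X))]
      baseline - metric_fun(y, predict_fun(Xp))
    }, numeric(1)))
  }, numeric(1))
  stats::setNames(drops, names(X))
}

accuracy <- function(truth, pred) mean(as.character(pred) == as.character(truth))
r_squared <- function(truth, pred) {
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((truth - pred)^2) / sst
}

# fit one spec on (X, y); returns list(predict = function(X), fit = object)
fit_model <- function(spec, X, y, seed) {
  set.seed(seed)
  hp <- spec$hyperparameters
  cls <- spec$task == "CLASSIFICATION"
  df <- data.frame(X, .y = y, check.names = FALSE)

  switch(spec$family,
    LINEAR = {
      # standardized design so coefficient magnitudes are comparable
      mu <- vapply(X, mean, numeric(1))
      sdev <- vapply(X, stats::sd, numeric(1))
      sdev[sdev == 0] <- 1
      Xs <- as.data.frame(scale(X, center = mu, scale = sdev))
      dfs <- data.frame(Xs, .y = y, check.names = FALSE)
      fit <- if (cls)
        suppressWarnings(stats::glm(.y ~ ., data = dfs, family = stats::binomial()))
      else stats::lm(.y ~ ., data = dfs)
      predict_fun <- function(newX) {
        newXs <- as.data.frame(scale(newX, center = mu, scale = sdev))
        if (cls) {
          pr <- stats::predict(fit, newdata = newXs, type = "response")
          factor(levels(y)[(pr > 0.5) + 1L], levels = levels(y))
        } else stats::predict(fit, newdata = newXs)
      }
      list(predict = predict_fun, fit = fit)
    },
    DECISION_TREE = {
      fit <- rpart::rpart(.y ~ ., data = df,
                          method = if (cls) "class" else "anova",
                          control = do.call(rpart::rpart.control,
                                            hp %||% list()))
      predict_fun <- function(newX)
        if (cls) stats::predict(fit, newdata = as.data.frame(newX),
                                type = "class")
        else stats::predict(fit, newdata = as.data.frame(newX))
      list(predict = predict_fun, fit = fit)
    },
    RANDOM_FOREST = {
      fit <- ranger::ranger(
        x = X, y = y,
        num.trees = hp$num.trees %||% 300L,
        importance = "impurity",
        seed = seed, num.threads = 1L, verbose = FALSE)
      predict_fun <- function(newX)
        stats::predict(fit, data = as.data.frame(newX),
                       num.threads = 1L)$predictions
      list(predict = predict_fun, fit = fit)
    },
    GRADIENT_BOOSTING = {
      fit <- xgboost::xgboost(
        as.matrix(X), y,
        nrounds = hp$nrounds %||% 60L,
        max_depth = hp$max_depth %||% 3L,
        learning_rate = hp$learning_rate %||% 0.3,
        nthreads = 1L, seed = seed %% .Machine$integer.max, verbosity = 0L)
      predict_fun <- function(newX) {
        pr <- stats::predict(fit, as.matrix(newX))
        if (cls) factor(levels(y)[(pr > 0.5) + 1L], levels = levels(y))
        else pr
      }
      list(predict = predict_fun, fit = fit)
    },
    KERNEL_SVM = {
      fit <- e1071::svm(x = as.matrix(X), y = y, kernel = "radial",
                        cost = hp$cost %||% 1)
      predict_fun <- function(newX)
        stats::predict(fit, newdata = as.matrix(newX))
      list(predict = predict_fun, fit = fit)
    }
  )
}

# importance of a full-data fit, covering every feature (unreported -> 0)
extract_importance <- function(spec, fitted, X, y, metric_fun, seed) {
  full <- stats::setNames(numeric(ncol(X)), names(X))
  raw <- switch(spec$importance_backend,
    COEFFICIENT_MAGNITUDE = {
      co <- stats::coef(fitted$fit)
      abs(co[setdiff(names(co), "(Intercept)")])
    },
    IMPURITY = switch(spec$family,
      DECISION_TREE = fitted$fit$variable.importance %||% numeric(0),
      RANDOM_FOREST = ranger::importance(fitted$fit),
      GRADIENT_BOOSTING = {
        imp <- xgboost::xgb.importance(model = fitted$fit)
        stats::setNames(imp$Gain, imp$Feature)
      }),
    PERMUTATION = permutation_importance(fitted$predict, X, y, metric_fun,
                                         n_repeats = 5L, seed = seed)
  )
  if (length(raw)) {
    raw <- raw[names(raw) %in% names(full)]
    full[names(raw)] <- pmax(raw, 0)
  }
  full
}

metric_for_task <- function(task, metric = NULL) {
  metric <- metric %||% if (task == "CLASSIFICATION") "accuracy" else "r_squared"
  fun <- switch(metric, accuracy = accuracy, r_squared = r_squared,
                stop("unknown metric: ", metric, call. = FALSE))
  list(name = metric, fun = fun)
}

# stratified (classification) or plain fold assignment
make_folds <- function(y, folds, cls) {
  assign <- integer(length(y))
  if (cls) {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  } else assign[] <- sample(rep_len(seq_len(folds), length(y)))
  assign
}

#' Run the brute-force model harness
#'
#' Fits every model spec on one tabular dataset. Held-out performance is the
#' mean metric over the folds of repeated cross-validation (never the
#' training rows — this is what makes the scores safe to feed into
#' [softmax_weights()]); the reported importances come from a refit on the
#' full dataset. All randomness flows from `seed` and the per-spec seeds, so
#' a fixed (data, specs, seed) triple reproduces identical output.
#'
#' @param data Data frame with the outcome column and numeric features, no
#'   missing values (impute upstream). Categorical features must be
#'   pre-encoded numerically.
#' @param outcome Name of the outcome column. For classification it is
#'   coerced to a factor and must have >= 2 classes.
#' @param specs List of [model_spec()] objects with a common task; default
#'   [default_model_suite()] for the outcome's task.
#' @param folds,repeats Cross-validation geometry (default 5 x 2).
#' @param seed Integer seed for fold assignment.
#' @param metric Performance metric name: `"accuracy"` (classification
#'   default) or `"r_squared"` (regression default).
#' @return A list of class `harness_result`: `importances` (list of
#'   [model_importance()], one per spec, `performance` filled), and
#'   `cv_config` (folds, repeats, seed, metric).
#' @export
run_harness <- function(data, outcome, specs = NULL, folds = 5L,
                        repeats = 2L, seed = 1L, metric = NULL) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            folds >= 2L, repeats >= 1L)
  X <- data[setdiff(names(data), outcome)]
  if (ncol(X) < 2L) stop("need >= 2 features", call. = FALSE)
  if (anyNA(data)) stop("data contains missing values; impute upstream",
                        call. = FALSE)
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("all features must be numeric (pre-encode categorical features)",
         call. = FALSE)
  y <- data[[outcome]]

  if (is.null(specs)) {
    task <- if (is.factor(y) || length(unique(y)) == 2L) "CLASSIFICATION"
            else "REGRESSION"
    specs <- default_model_suite(task, seed = seed)
  }
  tasks <- unique(vapply(specs, `[[`, character(1), "task"))
  if (length(tasks) != 1L)
    stop("all specs must share one task", call. = FALSE)
  cls <- tasks == "CLASSIFICATION"
  if (cls) {
    y <- factor(y)
    if (nlevels(y) < 2L)
      stop("degenerate outcome: a single class cannot be classified",
           call. = FALSE)
  } else y <- as.numeric(y)

  ids <- vapply(specs, `[[`, character(1), "model_id")
  ids <- make.unique(ids, sep = "_")
  m <- metric_for_task(tasks, metric)

  # held-out performance under repeated CV, identical folds for every spec
  perf <- matrix(NA_real_, nrow = length(specs), ncol = repeats * folds)
  col <- 0L
  for (r in seq_len(repeats)) {
    set.seed(seed + 1000L * r)
    assign <- make_folds(y, folds, cls)
    for (f in seq_len(folds)) {
      col <- col + 1L
      test <- assign == f
      for (s in seq_along(specs)) {
        fitted <- fit_model(specs[[s]], X[!test, , drop = FALSE], y[!test],
                            seed = specs[[s]]$seed + 13L * col)
        perf[s, col] <- m$fun(y[test], fitted$predict(X[test, , drop = FALSE]))
      }
    }
  }

  importances <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    fitted <- fit_model(specs[[s]], X, y, seed = specs[[s]]$seed)
    vals <- extract_importance(specs[[s]], fitted, X, y, m$fun,
                               seed = specs[[s]]$seed)
    importances[[s]] <- model_importance(
      model_id = ids[s], values = vals,
      metric = switch(specs[[s]]$importance_backend,
                      COEFFICIENT_MAGNITUDE = "abs_coefficient",
                      IMPURITY = "impurity",
                      PERMUTATION = "permutation"),
      performance = mean(perf[s, ]))
  }
  structure(list(importances = importances,
                 cv_config = list(folds = folds, repeats = repeats,
                                  seed = seed, metric = m$name)),
            class = "harness_result")
}

#' @export
print.harness_result <- function(x, ...) {
  cat(sprintf("<harness_result> %d models, %d-fold x %d CV (%s)\n",
              length(x$importances), x$cv_config$folds, x$cv_config$repeats,
              x$cv_config$metric))
  for (imp in x$importances)
    cat(sprintf("  %-20s %s = %.4f\n", imp$model_id, x$cv_config$metric,
                imp$performance))
  invisible(x)
}
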