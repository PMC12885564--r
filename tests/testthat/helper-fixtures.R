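# Small fixtures built in code.

# a list of model_importance objects with random positive importances over a
# common feature set
random_outputs <- function(n_models, p, seed, performance = FALSE) {
  set.seed(seed)
  feats <- sprintf("f%02d", seq_len(p))
  lapply(seq_len(n_models), function(j)
    model_importance(paste0("m", j),
                     stats::setNames(stats::rexp(p) + 1e-9, feats),
                     metric = "synthetic",
                     performance = if (performance) stats::runif(1) else NA))
}

# pre-ranked inputs from an explicit feature x model rank matrix
preranked_outputs <- function(rank_mat) {
  lapply(seq_len(ncol(rank_mat)), function(j)
    model_importance(paste0("m", j), rank_mat[, j], metric = "rank"))
}

# a tiny regression table where y is an exact copy of x1
copy_outcome_data <- function(n = 120, p = 5, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  data.frame(X, y = X[, 1])
}
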