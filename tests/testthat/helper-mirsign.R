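# Shared fixtures, all generated in code.

# Small two-class dataset with a strongly separating feature f1 and noise.
tiny_two_class <- function(n_per_class = 20, n_noise = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * (1 + n_noise)), n,
              dimnames = list(sprintf("s%02d", 1:n),
                              c("f1", sprintf("noise%d", seq_len(n_noise)))))
  y <- rep(c("A", "B"), each = n_per_class)
  X[y == "B", "f1"] <- X[y == "B", "f1"] + 10
  list(X = X, y = y)
}

# A precomputed-importance classifier stub: importance and predictions are
# fixed, so ensemble plumbing can be exercised without real model fits.
stub_classifier <- function(importance, levels = c("A", "B")) {
  structure(list(typology = "precomputed", importance = importance,
                 levels = levels,
                 predict_fun = function(newdata)
                   rep(levels[1L], nrow(newdata))),
            class = "mirsign_classifier")
}

# Stub fitter usable in run_ensemble_selection(fitters = ...): importance is
# a fixed deterministic function of the feature names.
stub_fitter <- function(X, y, params, seed) {
  p <- ncol(X)
  stub_classifier(stats::setNames(rev(seq_len(p)), colnames(X)),
                  levels = sort(unique(y)))
}
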