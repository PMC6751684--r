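baseline_result <- function(method, selected, scores = NULL, fit_count = NA_integer_,
                            extra = list()) {
  if (anyDuplicated(selected)) stop("selected features must be unique")
  structure(c(list(method = method, selected = as.character(selected),
                   scores = scores, fit_count = fit_count), extra),
            class = "baseline_result")
}

#' Univariate feature selection by ANOVA F
#'
#' Scores every feature with the one-way ANOVA F statistic across the
#' classes (between-group mean square over within-group mean square) and
#' keeps the k highest-scoring features. Constant features get F = 0 and
#' rank last.
#'
#' @param X Expression matrix, samples x features.
#' @param y Class labels (>= 2 classes, each with >= 2 samples).
#' @param k Number of features to select.
#' @return A `baseline_result` with per-feature F scores.
#' @export
ufs_select <- function(X, y, k) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  F <- anova_f_scores(X, y)
  sel <- rank_top_k(F, k)
  baseline_result("ufs", sel, scores = F[sel], fit_count = 0L)
}

#' @rdname ufs_select
#' @export
anova_f_scores <- function(X, y) {
  y <- factor(y)
  n <- nrow(X); g <- nlevels(y)
  counts <- tabulate(y, g)
  grand <- colMeans(X)
  group_means <- rowsum(X, y) / counts
  ss_between <- colSums(counts * sweep(group_means, 2L, grand)^2)
  ss_total <- colSums(sweep(X, 2L, grand)^2)
  ss_within <- ss_total - ss_between
  F <- (ss_between / (g - 1)) / (ss_within / (n - g))
  F[!is.finite(F) | ss_total == 0] <- 0
  stats::setNames(F, colnames(X))
}

#' Recursive feature elimination with a linear classifier
#'
#' Starting from all features, iteratively fits the base estimator (a
#' linear-kernel SVC by default), ranks the surviving features by summed
#' absolute coefficients, and removes exactly the single lowest-importance
#' feature, until k features remain. The estimator is therefore fitted
#' exactly n_features - k times.
#'
#' @param X Expression matrix.
#' @param y Class labels.
#' @param k Target number of features (< n_features).
#' @param base_estimator Classifier family used for scoring (a linear one).
#' @param seed Seed passed to each fit.
#' @param fit_fun Optional override `function(X, y, seed)` returning an
#'   object accepted by [classifier_importance()]; lets callers instrument
#'   or replace the estimator.
#' @return A `baseline_result`; `fit_count` records the internal fits and
#'   `elimination_order` the features in removal order.
#' @export
rfe_select <- function(X, y, k, base_estimator = "svc_linear", seed = 0L,
                      fit_fun = NULL) {
  if (k >= ncol(X)) stop("k must be < n_features")
  surviving <- colnames(X)
  eliminated <- character(0)
  fit_count <- 0L
  if (is.null(fit_fun))
    fit_fun <- function(Xs, ys, s) fit_classifier(base_estimator, Xs, ys, seed = s)
  std <- fit_standardization(X)
  Xs <- apply_standardization(std, X)
  while (length(surviving) > k) {
    model <- fit_fun(Xs[, surviving, drop = FALSE], y,
                     child_seed(seed, fit_count + 1L))
    fit_count <- fit_count + 1L
    imp <- classifier_importance(model, surviving)
    # drop the single worst feature; ties by name keep removal deterministic
    worst <- rev(rank_top_k(imp, length(surviving)))[1L]
    eliminated <- c(eliminated, worst)
    surviving <- setdiff(surviving, worst)
  }
  baseline_result("rfe", surviving, fit_count = fit_count,
                  extra = list(elimination_order = eliminated))
}

#' Penalized linear-model feature selection (LASSO / elastic net)
#'
#' Fits an L1 (lasso) or L1+L2 (elastic net, mixing 0.5) penalized linear
#' model with the regularization strength chosen by an internal 3-fold
#' cross-validation, ranks features by aggregated absolute coefficient
#' (summed over one-vs-rest class rows for multiclass labels), and keeps
#' the k highest. Zero-coefficient features rank below all nonzero ones in
#' name order; if fewer than k features have nonzero coefficients, the
#' selection is padded from them and flagged.
#'
#' @param X Expression matrix.
#' @param y Class labels.
#' @param k Number of features to select.
#' @param mode `"lasso"` or `"elastic_net"`.
#' @param seed Seed for the internal CV folds.
#' @return A `baseline_result` with the aggregated |coefficient| scores and
#'   a `padded` flag.
#' @export
penalized_select <- function(X, y, k, mode = c("lasso", "elastic_net"),
                             seed = 0L) {
  mode <- match.arg(mode)
  alpha <- if (mode == "lasso") 1 else 0.5
  y <- as.character(y)
  lev <- sort(unique(y))
  std <- fit_standardization(X)
  Xs <- apply_standardization(std, X)
  rng <- local_rng(seed)
  foldid <- as.integer(stratified_folds(y, 3L, seed = rng$spawn(1L))) + 1L
  fam <- if (length(lev) > 2L) "multinomial" else "binomial"
  cv <- glmnet::cv.glmnet(Xs, factor(y, levels = lev), family = fam,
                          alpha = alpha, nfolds = 3L, foldid = foldid,
                          standardize = FALSE)
  cf <- stats::coef(cv, s = "lambda.min")
  B <- if (is.list(cf)) t(sapply(cf, function(b) as.numeric(b)[-1L]))
       else rbind(as.numeric(cf)[-1L])
  score <- colSums(abs(B))
  names(score) <- colnames(X)
  nonzero <- names(score)[score > 0]
  if (!length(nonzero))
    warning("all coefficients are zero; falling back to name order")
  sel <- rank_top_k(score, k)
  padded <- min(k, ncol(X)) > length(nonzero)
  if (padded)
    warning(sprintf("only %d features have nonzero coefficients; padding to %d by name order",
                    length(nonzero), min(k, ncol(X))))
  baseline_result(mode, sel, scores = score[sel], fit_count = 1L,
                  extra = list(padded = padded, lambda = cv$lambda.min))
}

#' Subsampled linear-SVM ensemble elimination (EFS-CLA)
#'
#' Per iteration, fits `calls_per_step` linear support-vector classifiers on
#' random subsamples of the data, averages the absolute weight vectors over
#' the calls, and drops the lowest-scoring E% (floored, at least one) of the
#' surviving features. Iterations continue until at most k features survive;
#' if the last reduction undershoots k, the survivors are trimmed to exactly
#' k by removing the lowest averaged weights.
#'
#' @param X Expression matrix.
#' @param y Class labels.
#' @param k Target number of features.
#' @param E Percentage of surviving features removed per iteration
#'   (default 20).
#' @param calls_per_step Linear SVM fits per iteration (default 40).
#' @param subsample_fraction Fraction of samples drawn (without replacement)
#'   for each call (default 0.5).
#' @param seed Seed; the whole procedure is deterministic given it.
#' @return A `baseline_result`; `fit_count` counts every SVM call and
#'   `survivor_counts` records the per-iteration feature counts.
#' @export
efs_cla_select <- function(X, y, k, E = 20, calls_per_step = 40L,
                           subsample_fraction = 0.5, seed = 0L) {
  if (E <= 0 || E >= 100) stop("E must be in (0, 100)")
  y <- as.character(y)
  std <- fit_standardization(X)
  Xs <- apply_standardization(std, X)
  surviving <- colnames(X)
  survivor_counts <- length(surviving)
  fit_count <- 0L
  rng <- local_rng(seed)
  n <- nrow(X)
  m <- max(2L, floor(subsample_fraction * n))
  avg_w <- NULL
  while (length(surviving) > k) {
    w_sum <- stats::setNames(numeric(length(surviving)), surviving)
    calls <- 0L
    while (calls < calls_per_step) {
      idx <- rng$sample_int(n, m)
      if (length(unique(y[idx])) < 2L) next  # resample degenerate subsamples
      model <- tryCatch(
        fit_classifier("svc_linear", Xs[idx, surviving, drop = FALSE], y[idx],
                       seed = rng$spawn(1L)),
        error = function(e) e)
      calls <- calls + 1L
      fit_count <- fit_count + 1L
      if (inherits(model, "error")) {
        warning("SVM call failed and was skipped: ", conditionMessage(model))
        next
      }
      w_sum <- w_sum + classifier_importance(model, surviving)
    }
    avg_w <- w_sum / calls_per_step
    n_drop <- max(1L, floor(length(surviving) * E / 100))
    keep_n <- length(surviving) - n_drop
    if (keep_n < k) {                       # final trim: stop at exactly k
      surviving <- rank_top_k(avg_w, k)
      survivor_counts <- c(survivor_counts, length(surviving))
      break
    }
    surviving <- rank_top_k(avg_w, keep_n)
    survivor_counts <- c(survivor_counts, length(surviving))
  }
  baseline_result("efs_cla", surviving,
                  scores = if (!is.null(avg_w)) avg_w[surviving],
                  fit_count = fit_count,
                  extra = list(survivor_counts = survivor_counts))
}

#' Uniform random feature selection
#'
#' Baseline reference: k features sampled uniformly without replacement,
#' deterministic per seed.
#'
#' @param feature_names Feature universe.
#' @param k Number of features (<= n_features).
#' @param seed Seed.
#' @return A `baseline_result`.
#' @export
random_select <- function(feature_names, k, seed = 0L) {
  if (k > length(feature_names)) stop("k must be <= n_features")
  rng <- local_rng(seed)
  sel <- feature_names[rng$sample_int(length(feature_names), k)]
  baseline_result("random", sel, fit_count = 0L)
}

#' Number of features shared by two signatures
#'
#' @param a,b Feature-name vectors (or objects with a `feature`/`selected`
#'   component).
#' @return Integer size of the intersection.
#' @export
signature_overlap <- function(a, b) {
  length(intersect(signature_features(a), signature_features(b)))
}

signature_features <- function(x) {
  if (is.character(x)) x
  else if (!is.null(x$feature)) x$feature
  else if (!is.null(x$selected)) x$selected
  else stop("cannot extract feature names from object of class ",
            paste(class(x), collapse = "/"))
}

#' @exportS3Method base::print
print.baseline_result <- function(x, ...) {
  cat("<baseline_result>", x$method, "-", length(x$selected), "features,",
      x$fit_count, "classifier fits\n")
  invisible(x)
}
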