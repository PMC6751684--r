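#' Repeated stratified cross-validated accuracy
#'
#' Evaluates one classifier family on a feature subset by repeated
#' stratified k-fold cross-validation: per repeat, a fresh fold partition
#' is drawn; per fold, standardization is fitted on the training partition
#' only, the classifier is fitted on the standardized training data, and
#' plain accuracy (fraction of correct predictions) is measured on the
#' held-out fold. Per-class accuracy (recall) is aggregated over all
#' held-out predictions.
#'
#' @param X Expression matrix.
#' @param y Class labels.
#' @param family One of [classifier_families()].
#' @param feature_subset Character vector of features to use, or `NULL` for
#'   all features (identical to passing every feature).
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Number of repeats (default 10).
#' @param seed Master seed; per-repeat fold seeds derive from it.
#' @param params Hyperparameter overrides for the family.
#' @return Object of class `cv_report`: per repeat x fold accuracies, their
#'   mean/SD, a per-class accuracy table, and the evaluation metadata.
#' @export
repeated_cv_accuracy <- function(X, y, family, feature_subset = NULL,
                                 n_folds = 10L, n_repeats = 10L, seed = 0L,
                                 params = list()) {
  if (!family %in% classifier_families())
    stop("unknown family '", family, "'; supported: ",
         paste(classifier_families(), collapse = ", "))
  y <- as.character(y)
  if (is.null(feature_subset)) feature_subset <- colnames(X)
  missing <- setdiff(feature_subset, colnames(X))
  if (length(missing))
    stop("feature_subset not in X: ", paste(missing, collapse = ", "))
  Xs <- X[, feature_subset, drop = FALSE]
  folds_acc <- matrix(NA_real_, n_repeats, n_folds)
  pred_all <- truth_all <- character(0)
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(y, n_folds, seed = child_seed(seed, r))
    for (f in 0:(n_folds - 1L)) {
      tr <- fold != f
      std <- fit_standardization(Xs[tr, , drop = FALSE])
      model <- fit_classifier(family,
                              apply_standardization(std, Xs[tr, , drop = FALSE]),
                              y[tr], params = params,
                              seed = child_seed(seed, r * n_folds + f + 1L))
      pred <- predict(model, apply_standardization(std, Xs[!tr, , drop = FALSE]))
      folds_acc[r, f + 1L] <- mean(pred == y[!tr])
      pred_all <- c(pred_all, pred)
      truth_all <- c(truth_all, y[!tr])
    }
  }
  structure(list(family = family, feature_subset = feature_subset,
                 accuracies = folds_acc, mean = mean(folds_acc),
                 sd = stats::sd(as.numeric(folds_acc)),
                 per_class = per_class_accuracy(pred_all, truth_all,
                                                sort(unique(y))),
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed),
            class = "cv_report")
}

#' @exportS3Method base::print
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s on %d features: accuracy %.4f (sd %.4f), %dx%d-fold CV\n",
              x$family, length(x$feature_subset), x$mean, x$sd,
              x$n_repeats, x$n_folds))
  invisible(x)
}

#' Per-class accuracy (recall)
#'
#' For each class c, the fraction of samples whose true class is c that are
#' predicted as c. Classes with no truth samples are reported as `NA`. The
#' class-size-weighted mean of per-class accuracies equals global accuracy.
#'
#' @param predictions,truths Aligned label vectors.
#' @param classes Class set to report (defaults to classes in `truths`).
#' @return Data frame with columns `class`, `n`, `accuracy`.
#' @export
per_class_accuracy <- function(predictions, truths, classes = sort(unique(truths))) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must be aligned")
  out <- lapply(classes, function(cl) {
    idx <- truths == cl
    data.frame(class = cl, n = sum(idx),
               accuracy = if (any(idx)) mean(predictions[idx] == cl) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Derive binary labels from a predicate
#'
#' Builds a two-class task (e.g. tumor vs. normal tissue, or one molecular
#' subtype vs. the rest) from a label table. Both classes must be
#' non-empty; downstream stratified CV keeps the two-class proportions
#' inside every fold.
#'
#' @param labels Label data frame (see [label_table()]).
#' @param positive Predicate `function(labels)` returning a logical per
#'   sample, or the name of a column/value pair via `column` and `value`.
#' @param class_names Labels for the two classes (positive first).
#' @return Character vector of binary labels with attribute `counts`.
#' @export
build_binary_task <- function(labels, positive,
                              class_names = c("positive", "negative")) {
  flag <- if (is.function(positive)) positive(labels) else positive
  if (!is.logical(flag) || length(flag) != nrow(labels) || anyNA(flag))
    stop("predicate must assign TRUE/FALSE to every sample")
  if (all(flag) || !any(flag))
    stop("binary task is degenerate: one class is empty (",
         sum(flag), " positive of ", length(flag), ")")
  y <- ifelse(flag, class_names[1L], class_names[2L])
  structure(y, counts = stats::setNames(c(sum(flag), sum(!flag)), class_names))
}

#' Paired comparison of two cross-validation reports
#'
#' Compares the per-fold accuracy samples of two reports with a two-sided
#' paired t-test (same fold structure required) or a two-sample
#' Kolmogorov-Smirnov test. When all paired differences are equal the
#' t statistic is undefined; this degenerate case is reported with a flag
#' rather than an error (p = 1 when the common difference is 0).
#'
#' @param reportA,reportB `cv_report` objects (or numeric accuracy vectors).
#' @param test `"paired_t"` or `"ks"`.
#' @return List with `statistic`, `p_value`, `mean_difference` (A - B) and
#'   `degenerate_variance` flag.
#' @export
paired_comparison <- function(reportA, reportB, test = c("paired_t", "ks")) {
  test <- match.arg(test)
  a <- if (inherits(reportA, "cv_report")) as.numeric(reportA$accuracies) else as.numeric(reportA)
  b <- if (inherits(reportB, "cv_report")) as.numeric(reportB$accuracies) else as.numeric(reportB)
  if (test == "paired_t") {
    if (length(a) != length(b))
      stop("paired t-test needs aligned per-fold accuracies")
    d <- a - b
    if (stats::sd(d) == 0) {
      return(list(statistic = NA_real_,
                  p_value = if (mean(d) == 0) 1 else NA_real_,
                  mean_difference = mean(d), degenerate_variance = TRUE,
                  test = test))
    }
    ht <- stats::t.test(a, b, paired = TRUE)
  } else {
    ht <- suppressWarnings(stats::ks.test(a, b))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       mean_difference = mean(a) - mean(b), degenerate_variance = FALSE,
       test = test)
}

#' Train-on-one, test-on-another evaluation
#'
#' Cross-dataset mode used for external validation: the classifier (with
#' its standardization) is fitted on the full training matrix and evaluated
#' on a second matrix. The feature sets are intersected automatically and
#' the common-feature count is reported.
#'
#' @param X_train,y_train Training matrix and labels.
#' @param X_test,y_test Test matrix and labels.
#' @param family Classifier family.
#' @param feature_subset Optional signature restriction.
#' @param seed,params Passed to [fit_classifier()].
#' @return List with `accuracy`, `per_class`, `common_features` count and
#'   the features used.
#' @export
cross_dataset_accuracy <- function(X_train, y_train, X_test, y_test, family,
                                   feature_subset = NULL, seed = 0L,
                                   params = list()) {
  if (is.null(feature_subset)) feature_subset <- colnames(X_train)
  common <- intersect(intersect(feature_subset, colnames(X_train)),
                      colnames(X_test))
  if (!length(common)) stop("no common features between the datasets")
  message(length(common), " common feature(s) used for cross-dataset evaluation")
  std <- fit_standardization(X_train[, common, drop = FALSE])
  model <- fit_classifier(family,
                          apply_standardization(std, X_train[, common, drop = FALSE]),
                          y_train, params = params, seed = seed)
  pred <- predict(model, apply_standardization(std, X_test[, common, drop = FALSE]))
  list(accuracy = mean(pred == as.character(y_test)),
       per_class = per_class_accuracy(pred, as.character(y_test)),
       common_features = length(common), features = common)
}

#' Serialize a CV report
#'
#' Writes the aggregate report as JSON and the per-repeat, per-fold
#' accuracies as a flat TSV (columns `repeat`, `fold`, `accuracy`).
#'
#' @param report A `cv_report`.
#' @param json_path,tsv_path Output paths (`NULL` to skip either).
#' @export
write_cv_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(tsv_path)) {
    flat <- data.frame(rep = rep(seq_len(report$n_repeats), report$n_folds),
                       fold = rep(seq_len(report$n_folds),
                                  each = report$n_repeats),
                       accuracy = as.numeric(report$accuracies))
    flat <- flat[order(flat$rep, flat$fold), ]
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(family = report$family,
                              n_features = length(report$feature_subset),
                              mean_accuracy = report$mean,
                              sd_accuracy = report$sd,
                              per_class = report$per_class,
                              n_folds = report$n_folds,
                              n_repeats = report$n_repeats,
                              seed = report$seed),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
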