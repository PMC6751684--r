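#' Map mature-sequence expression onto stem-loop features
#'
#' Microarray platforms that measure only mature miRNA sequences (e.g.
#' hsa-miR-10b) must be reconciled with sequencing references indexed by
#' stem-loop precursors (hsa-mir-10b). Restricting each stem-loop to its
#' most common mature sequence reduces the relationship to a copy: every
#' stem-loop column takes the values of its designated mature column, and
#' several stem-loops sharing one mature sequence (the hsa-mir-135a-1 /
#' hsa-mir-135a-2 pattern, where distinct loci produce the same active
#' sequence) receive identical copies. Mature features without a mapping
#' are dropped with a logged count.
#'
#' @param X_mature Expression matrix with mature-sequence column names.
#' @param map Data frame with columns `mature`, `stemloop`.
#' @return Expression matrix over stem-loop names.
#' @export
aggregate_mature_to_stemloop <- function(X_mature, map) {
  if (!all(c("mature", "stemloop") %in% names(map)))
    stop("map needs `mature` and `stemloop` columns")
  present <- map[map$mature %in% colnames(X_mature), , drop = FALSE]
  if (!nrow(present))
    stop("no overlap between the mature-to-stem-loop map and the matrix features")
  dropped <- setdiff(colnames(X_mature), map$mature)
  if (length(dropped))
    message(length(dropped), " unmapped mature feature(s) dropped")
  dup <- present$stemloop[duplicated(present$stemloop)]
  if (length(dup))
    stop("stem-loop(s) mapped from multiple mature sequences: ",
         paste(unique(dup), collapse = ", "))
  out <- X_mature[, present$mature, drop = FALSE]
  colnames(out) <- present$stemloop
  expression_matrix(out)
}

#' Per-feature reference statistics
#'
#' Mean and SD of every feature on the reference (sequencing) matrix, used
#' to re-express external z-scores in the reference intensity space.
#' Uses the population SD convention, matching [standardize()].
#'
#' @param X_ref Reference expression matrix.
#' @return Data frame (class `reference_stats`) with columns `feature`,
#'   `mean`, `sd`.
#' @export
reference_stats <- function(X_ref) {
  mu <- colMeans(X_ref)
  sdev <- sqrt(colMeans(sweep(X_ref, 2L, mu)^2))
  structure(data.frame(feature = colnames(X_ref), mean = as.numeric(mu),
                       sd = as.numeric(sdev), stringsAsFactors = FALSE),
            class = c("reference_stats", "data.frame"))
}

#' Re-express external z-scores in the reference intensity space
#'
#' Implements the per-feature linear mapping X_i = (Z_i * sigma_i + mu_i) * a_i:
#' the external z-score is first unfolded with the reference mean and SD of
#' feature i, then rescaled by the platform-specific factor a_i. With a = 1
#' and Z the reference z-scores, this is the identity on the reference
#' matrix.
#'
#' @param Z Z-score matrix, samples x features.
#' @param stats A [reference_stats()] table aligned with `Z`'s features.
#' @param scale Per-feature positive scale a (named numeric, or a
#'   `platform_scale`); defaults to 1.
#' @return Expression matrix in reference space.
#' @export
zscore_to_reference <- function(Z, stats, scale = NULL) {
  a <- platform_scale_values(scale, colnames(Z))
  if (!identical(colnames(Z), stats$feature))
    stop("features of Z and the reference statistics are misaligned")
  X <- sweep(sweep(Z, 2L, stats$sd, "*"), 2L, stats$mean, "+")
  sweep(X, 2L, a, "*")
}

platform_scale_values <- function(scale, feature_names) {
  if (is.null(scale)) return(stats::setNames(rep(1, length(feature_names)),
                                             feature_names))
  a <- if (inherits(scale, "platform_scale")) scale$a else scale
  if (is.data.frame(a)) a <- stats::setNames(a$a, a$feature)
  if (!is.null(names(a))) {
    if (!all(feature_names %in% names(a)))
      stop("scale vector features are misaligned with the matrix")
    a <- a[feature_names]
  } else if (length(a) != length(feature_names)) {
    stop("scale vector length != number of features")
  }
  if (any(!is.finite(a)) || any(a <= 0))
    stop("platform scale values must be positive and finite")
  stats::setNames(as.numeric(a), feature_names)
}

#' Class-code RMSE of a reference classifier on mapped external data
#'
#' The calibration objective for the platform scale: map the external
#' z-scores into reference space with the candidate scale vector, apply the
#' reference standardization, predict with the reference-trained
#' classifier, and return the root-mean-squared difference between the
#' predicted and actual integer class codes (codes assigned by sorted class
#' order on the reference dataset). Zero iff every prediction is correct;
#' invariant to sample order.
#'
#' @param scale_vector Candidate per-feature scale a (positive).
#' @param Z_ext External z-score matrix.
#' @param y_ext True labels of the external samples (must be classes known
#'   to the reference model).
#' @param reference_model A `mirsign_classifier` trained on the reference
#'   dataset's standardized space.
#' @param stats Reference statistics ([reference_stats()]).
#' @param standardization The `standardization_model` fitted on the
#'   reference matrix (how the reference model's inputs were scaled).
#' @return Non-negative RMSE on integer class codes.
#' @export
rmse_objective <- function(scale_vector, Z_ext, y_ext, reference_model, stats,
                           standardization) {
  y_ext <- as.character(y_ext)
  lev <- reference_model$levels
  unseen <- setdiff(y_ext, lev)
  if (length(unseen))
    stop("class code(s) unseen by the reference model: ",
         paste(unique(unseen), collapse = ", "))
  X <- zscore_to_reference(Z_ext, stats, scale_vector)
  pred <- predict(reference_model, apply_standardization(standardization, X))
  code <- function(cls) match(cls, lev) - 1L
  sqrt(mean((code(pred) - code(y_ext))^2))
}

#' Fit the per-feature platform scale
#'
#' Calibrates the scale vector a of [zscore_to_reference()] by minimizing
#' [rmse_objective()] with a derivative-free (1+1) evolution strategy on
#' log(a): each step perturbs every coordinate with a log-normal mutation,
#' accepts the candidate only if the objective does not worsen, and adapts
#' the step size by the 1/5th success rule. The objective is piecewise
#' constant in a (it changes only when a prediction flips), so a
#' gradient-based optimizer is unsuitable; monotone acceptance guarantees
#' the returned scale never degrades the initial objective.
#'
#' @param Z_ext,y_ext External z-scores and labels.
#' @param reference_model,stats,standardization As in [rmse_objective()].
#' @param init Initial scale (default 1 per feature).
#' @param budget Maximum objective evaluations (default 5000).
#' @param sigma0 Initial mutation SD in log-space (default 0.3).
#' @param seed Seed; the search is deterministic given it.
#' @return Object of class `platform_scale`: data frame `a` (feature,
#'   a), and metadata `evaluations`, `initial_objective`,
#'   `final_objective`, `seed`.
#' @export
fit_platform_scale <- function(Z_ext, y_ext, reference_model, stats,
                               standardization, init = NULL, budget = 5000L,
                               sigma0 = 0.3, seed = 0L) {
  if (nrow(Z_ext) < 2L) stop("need at least 2 external samples")
  features <- colnames(Z_ext)
  p <- length(features)
  a <- if (is.null(init)) rep(1, p) else platform_scale_values(init, features)
  obj <- function(v) rmse_objective(stats::setNames(v, features), Z_ext, y_ext,
                                    reference_model, stats, standardization)
  f_init <- obj(a)
  # the walker may accept equal-objective moves (needed to traverse the
  # plateaus of the piecewise-constant objective), but only strictly
  # improving points are recorded as the result, so the returned scale
  # cannot drift along a plateau away from the initial guess
  cur <- a; f_cur <- f_init
  best <- a; f_best <- f_init
  evals <- 1L
  rng <- local_rng(seed)
  sigma <- sigma0
  success_window <- 0; trials <- 0
  improved <- FALSE
  while (evals < budget && f_best > 0) {
    cand <- cur * exp(sigma * rng$rnorm(p))
    f_cand <- obj(cand)
    evals <- evals + 1L
    trials <- trials + 1
    if (f_cand <= f_cur) {
      cur <- cand; f_cur <- f_cand
      success_window <- success_window + 1
      if (f_cand < f_best) {
        improved <- TRUE
        best <- cand; f_best <- f_cand
      }
    }
    if (trials >= 20) {                   # 1/5th success rule
      rate <- success_window / trials
      sigma <- sigma * exp((rate - 0.2))
      sigma <- min(max(sigma, 1e-3), 2)
      success_window <- 0; trials <- 0
    }
  }
  if (!improved && f_init > 0)
    warning("optimization budget exhausted without improving the objective; returning the initial scale")
  structure(list(a = data.frame(feature = features, a = as.numeric(best),
                                stringsAsFactors = FALSE),
                 evaluations = evals, initial_objective = f_init,
                 final_objective = f_best, sigma_final = sigma,
                 seed = seed),
            class = "platform_scale")
}

#' @exportS3Method base::print
print.platform_scale <- function(x, ...) {
  cat(sprintf("<platform_scale> %d features; objective %.4f -> %.4f (%d evaluations)\n",
              nrow(x$a), x$initial_objective, x$final_objective, x$evaluations))
  invisible(x)
}

#' Read/write platform-mapping tables
#'
#' Small TSV round-trips for the mature-to-stem-loop map (columns `mature`,
#' `stemloop`), reference statistics (`feature`, `mean`, `sd`) and a fitted
#' platform scale (`feature`, `a`).
#'
#' @param x Table to write.
#' @param path File path.
#' @name platform_tsv
NULL

#' @rdname platform_tsv
#' @export
write_platform_tsv <- function(x, path) {
  df <- if (inherits(x, "platform_scale")) x$a else as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname platform_tsv
#' @export
read_mature_map_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("mature", "stemloop") %in% names(df)))
    stop("expected columns `mature` and `stemloop`")
  df
}

#' @rdname platform_tsv
#' @export
read_reference_stats_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("feature", "mean", "sd") %in% names(df)))
    stop("expected columns `feature`, `mean`, `sd`")
  structure(df, class = c("reference_stats", "data.frame"))
}

#' @rdname platform_tsv
#' @export
read_platform_scale_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("feature", "a") %in% names(df)))
    stop("expected columns `feature` and `a`")
  structure(list(a = df, evaluations = NA_integer_,
                 initial_objective = NA_real_, final_objective = NA_real_,
                 seed = NA_integer_),
            class = "platform_scale")
}
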