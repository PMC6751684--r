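#' Specification of a synthetic miRNA-seq-like dataset
#'
#' Describes a labeled expression matrix emulating the structure of a
#' pan-cancer miRNA-seq compendium: many tumor classes with highly
#' unbalanced sizes, non-negative heavy-tailed expression values (RPM-like,
#' log-normal), and a minority of class-discriminative features. Each
#' informative feature is a marker of one class: its log-space mean is
#' shifted upward by `effect_size` (in units of the log-space SD) in that
#' class only, with marker classes assigned by cycling through the class
#' list. Optionally a fraction of samples is relabeled `"NT"` (normal
#' tissue) with the class signal attenuated, for tumor-vs-normal tasks.
#'
#' The default benchmark is 600 samples, 8 classes with proportions
#' 0.30/0.20/0.15/0.10/0.10/0.05/0.05/0.05, 200 features of which 20 are
#' informative, effect size 1.5 — small enough for minutes-scale runs while
#' keeping the unbalanced multiclass character of real tumor compendia.
#'
#' @param n_samples Number of samples.
#' @param n_classes Number of tumor classes.
#' @param class_proportions Per-class proportions, summing to 1.
#' @param n_features Total number of features.
#' @param n_informative Number of planted discriminative features
#'   (<= n_features).
#' @param effect_size Marker-class mean shift in log-space SD units.
#' @param base_location,base_scale Location/scale of the log-normal
#'   baseline; per-feature locations are jittered around `base_location` so
#'   features differ in overall abundance.
#' @param noise_sd Extra log-space noise SD added on top of `base_scale`.
#' @param normal_tissue_fraction Fraction of samples marked `"NT"` with
#'   attenuated class signal (0 disables the tissue-status column variation).
#' @param seed Integer seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 600L, n_classes = 8L,
                           class_proportions = c(0.30, 0.20, 0.15, 0.10,
                                                 0.10, 0.05, 0.05, 0.05),
                           n_features = 200L, n_informative = 20L,
                           effect_size = 1.5, base_location = 3,
                           base_scale = 1, noise_sd = 0,
                           normal_tissue_fraction = 0, seed = 42L) {
  if (n_informative > n_features) stop("n_informative must be <= n_features")
  if (length(class_proportions) != n_classes)
    stop("class_proportions must have n_classes entries")
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1")
  if (any(class_proportions <= 0)) stop("class proportions must be positive")
  if (base_scale < 0 || noise_sd < 0 || effect_size < 0)
    stop("scales must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 class_proportions = class_proportions,
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, base_location = base_location,
                 base_scale = base_scale, noise_sd = noise_sd,
                 normal_tissue_fraction = normal_tissue_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labeled synthetic expression dataset
#'
#' Draws labels by the spec proportions (largest-remainder rounding, so
#' class counts match the proportions within one sample), then expression
#' values as exp(Normal): per-feature baseline location, plus the
#' marker-class shift (informative features only, in log space), plus
#' log-space noise. All values are strictly positive; with
#' `effect_size = 0` no feature carries class signal. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `X` (expression matrix, features `mir-0001`...),
#'   `labels` (label table with `tumor_type`, `tissue_status`, `class_code`)
#'   and `planted` (the informative feature names, with their marker class
#'   as names).
#' @export
generate_labeled_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(spec$seed)
  classes <- sprintf("C%02d", seq_len(spec$n_classes))
  counts <- largest_remainder(spec$class_proportions, spec$n_samples)
  if (any(counts == 0)) stop("infeasible proportions: a class received 0 samples")
  y <- rep(classes, counts)
  y <- y[rng$sample_int(length(y))]
  features <- sprintf("mir-%04d", seq_len(spec$n_features))
  planted_idx <- seq_len(spec$n_informative)
  marker_class <- classes[((planted_idx - 1L) %% spec$n_classes) + 1L]
  loc <- spec$base_location + rng$rnorm(spec$n_features, sd = 0.5)
  sd_log <- sqrt(spec$base_scale^2 + spec$noise_sd^2)
  log_x <- matrix(rng$rnorm(spec$n_samples * spec$n_features, sd = sd_log),
                  spec$n_samples, spec$n_features)
  log_x <- sweep(log_x, 2L, loc, "+")
  tissue <- rep("TT", spec$n_samples)
  if (spec$normal_tissue_fraction > 0) {
    n_nt <- round(spec$normal_tissue_fraction * spec$n_samples)
    tissue[rng$sample_int(spec$n_samples, n_nt)] <- "NT"
  }
  shift_scale <- spec$effect_size * sd_log
  for (j in planted_idx) {
    hit <- y == marker_class[j] & tissue == "TT"
    log_x[hit, j] <- log_x[hit, j] + shift_scale
  }
  X <- exp(log_x)
  rownames(X) <- sprintf("S%04d", seq_len(spec$n_samples))
  colnames(X) <- features
  labels <- label_table(data.frame(sample_id = rownames(X), tumor_type = y,
                                   tissue_status = tissue,
                                   stringsAsFactors = FALSE))
  planted <- stats::setNames(features[planted_idx], marker_class)
  list(X = expression_matrix(X), labels = labels, planted = planted)
}

largest_remainder <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(-(raw - counts), seq_along(p))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Simulate an external platform as z-scores
#'
#' Fabricates the input of the cross-platform mapping by inverting it: the
#' reference expression is divided by the true per-feature scale, z-scored
#' with the reference column mean/SD, and perturbed with Gaussian noise.
#' With `noise_sd = 0` and `a_true = 1` the result equals the reference
#' z-scores exactly, so mapping back with the true scale reproduces the
#' reference matrix.
#'
#' @param X_ref Reference expression matrix.
#' @param a_true Per-feature positive scale (recycled if scalar).
#' @param noise_sd SD of additive z-space noise (default 0).
#' @param seed Seed.
#' @return List with `Z` (z-score matrix), `a_true` (named vector) and
#'   `stats` (the [reference_stats()] used).
#' @export
apply_platform_transform <- function(X_ref, a_true = 1, noise_sd = 0, seed = 0L) {
  features <- colnames(X_ref)
  a <- stats::setNames(rep_len(a_true, length(features)), features)
  if (any(a <= 0)) stop("a_true must be positive")
  st <- reference_stats(X_ref)
  Xp <- sweep(X_ref, 2L, a, "/")
  Z <- sweep(sweep(Xp, 2L, st$mean), 2L, pmax(st$sd, .Machine$double.eps), "/")
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    Z <- Z + matrix(rng$rnorm(length(Z), sd = noise_sd), nrow(Z), ncol(Z))
  }
  list(Z = Z, a_true = a, stats = st)
}
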