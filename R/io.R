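#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix of samples (rows) by
#' features (columns), with unique sample identifiers as row names and unique
#' miRNA identifiers (e.g. `"hsa-mir-10b"`) as column names. Values are
#' linear expression units: RPM for sequencing-like data, arbitrary linear
#' intensity for array-like data.
#'
#' @param values Numeric matrix, samples x features.
#' @param sample_ids Character vector of unique sample identifiers. Defaults
#'   to existing row names.
#' @param feature_names Character vector of unique feature names. Defaults to
#'   existing column names.
#' @return A numeric matrix with validated dimnames.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              feature_names = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(sample_ids) || is.null(feature_names))
    stop("sample and feature names are required")
  if (length(sample_ids) != nrow(values))
    stop("row count (", nrow(values), ") != number of sample ids (",
         length(sample_ids), ")")
  if (length(feature_names) != ncol(values))
    stop("column count (", ncol(values), ") != number of feature names (",
         length(feature_names), ")")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  dup <- unique(feature_names[duplicated(feature_names)])
  if (length(dup))
    stop("duplicate feature name(s): ", paste(dup, collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  dimnames(values) <- list(as.character(sample_ids),
                           as.character(feature_names))
  values
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated UTF-8 file with '.' decimal separator: a header
#' row of feature names, and one row per sample whose first column is the
#' sample identifier. Missing or non-numeric cells are an error (no
#' imputation), reported with their row/column coordinates.
#'
#' @param path Path to the TSV file.
#' @return Expression matrix (see [expression_matrix()]).
#' @seealso [write_expression_tsv()] for the exact inverse.
#' @export
read_expression_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) stop("expression TSV needs at least one feature column")
  feature_names <- header[-1L]
  dup <- unique(feature_names[duplicated(feature_names)])
  if (length(dup))
    stop("duplicate feature name(s) in header: ", paste(dup, collapse = ", "))
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  sample_ids <- raw[[1L]]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(feature_names))
  for (j in seq_along(feature_names)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric or missing value %s at row %d (sample '%s'), column '%s'",
                   dQuote(col[bad[1L]]), bad[1L], sample_ids[bad[1L]],
                   feature_names[j]))
    vals[, j] <- num
  }
  expression_matrix(vals, sample_ids, feature_names)
}

#' Write an expression matrix to TSV
#'
#' @param x Expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a sample label table
#'
#' The label table aligns one row per sample with an expression matrix:
#' columns `sample_id`, `tumor_type` (e.g. 28 cancer-type acronyms),
#' `tissue_status` (`"TT"` tumor / `"NT"` normal) and optional `subtype`.
#' `class_code` is an integer code assigned by sorted `tumor_type` order,
#' a bijection with the observed categories.
#'
#' @param path Path to the TSV file.
#' @return Data frame with a `class_code` column appended.
#' @export
read_label_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  label_table(df)
}

#' @rdname read_label_tsv
#' @param labels Label data frame with at least `sample_id` and `tumor_type`.
#' @export
label_table <- function(labels) {
  if (!all(c("sample_id", "tumor_type") %in% names(labels)))
    stop("label table needs `sample_id` and `tumor_type` columns")
  if (anyNA(labels$tumor_type))
    stop("every sample must have a tumor_type")
  labels$class_code <- class_codes(labels$tumor_type)
  labels
}

#' @rdname read_label_tsv
#' @param x Label data frame.
#' @export
write_label_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Integer class codes by sorted category order
#'
#' Categories are coded 0, 1, 2, ... following the sorted order of the
#' distinct category names, so the coding is reproducible across runs and
#' platforms.
#'
#' @param y Character or factor vector of class labels.
#' @return Integer vector of codes, named by label.
#' @export
class_codes <- function(y) {
  lev <- sort(unique(as.character(y)))
  stats::setNames(match(as.character(y), lev) - 1L, as.character(y))
}

#' Fit a standardization model on a training matrix
#'
#' Centers to zero mean and scales to unit variance per feature, with the
#' population SD convention (divide by n). The model is learned on the
#' training partition only and then applied unchanged to any other matrix,
#' so knowledge of held-out data never leaks into the transform. Constant
#' features (SD 0) are given a substitute SD of 1 and flagged, so the
#' transform stays defined and downstream selectors can ignore them.
#'
#' @param train Expression matrix used to learn mean/SD.
#' @param others Optional list of matrices (same features) to transform with
#'   the training mean/SD.
#' @return List with `model` (class `standardization_model`: `mean`, `sd`,
#'   `constant` flag per feature, `fitted_on` sample count, `sd_convention`)
#'   `train` (transformed training matrix) and `others` (transformed list).
#' @export
standardize <- function(train, others = list()) {
  model <- fit_standardization(train)
  list(model = model,
       train = apply_standardization(model, train),
       others = lapply(others, apply_standardization, model = model))
}

#' @rdname standardize
#' @export
fit_standardization <- function(train) {
  mu <- colMeans(train)
  n <- nrow(train)
  sdev <- sqrt(colMeans(sweep(train, 2L, mu)^2))  # population convention
  constant <- sdev == 0
  sdev[constant] <- 1
  structure(list(mean = mu, sd = sdev, constant = constant,
                 fitted_on = n, sd_convention = "population"),
            class = "standardization_model")
}

#' @rdname standardize
#' @param model A `standardization_model`.
#' @param x Matrix to transform; features must match the training features.
#' @export
apply_standardization <- function(model, x) {
  if (!identical(colnames(x), names(model$mean)))
    stop("feature names do not match the standardization model")
  sweep(sweep(x, 2L, model$mean), 2L, model$sd, "/")
}

#' Stratified fold assignment
#'
#' Assigns every sample to exactly one of `n_folds` folds such that each
#' fold preserves the per-class sample proportions: per-fold class counts
#' differ from the proportional share by at most one sample. Deterministic
#' given `seed`.
#'
#' @param y Vector of class labels, one per sample.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed for the within-class shuffle.
#' @return Integer vector of fold indices in `[0, n_folds)`, one per sample,
#'   with attributes `n_folds` and `seed`.
#' @export
stratified_folds <- function(y, n_folds, seed) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  y <- as.character(y)
  n <- length(y)
  if (!n) stop("no samples")
  rng <- local_rng(seed)
  fold <- integer(n)
  offset <- 0L
  small <- character(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    if (length(idx) < n_folds) small <- c(small, cl)
    idx <- idx[rng$sample_int(length(idx))]
    # deal shuffled samples round-robin, rotating the starting fold so that
    # leftover samples spread evenly across folds between classes
    fold[idx] <- (offset + seq_along(idx) - 1L) %% n_folds
    offset <- (offset + length(idx)) %% n_folds
  }
  if (length(small))
    warning("class(es) with fewer samples than folds: ",
            paste(small, collapse = ", "),
            "; some folds will lack these classes")
  structure(fold, n_folds = n_folds, seed = seed)
}

# Seed-scoped RNG helpers: draws never disturb the caller's RNG state.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample_int = function(n, size = n, replace = FALSE)
      with_state(function() sample.int(n, size = size, replace = replace)),
    runif = function(n, min = 0, max = 1)
      with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      with_state(function() stats::rnorm(n, mean, sd)),
    spawn = function(k) with_state(function()
      sample.int(.Machine$integer.max - 1L, k))
  )
}

# Derive a bounded child seed from a parent seed and an index (deterministic,
# independent of execution order).
child_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
}
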