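#' Ensemble feature-selection configuration
#'
#' Bundles the parameters of the consensus feature-ranking procedure: the
#' classifier roster, the number of repeated cross-validated runs per
#' family, the fold count, the size of each instance's top-k tally list,
#' and the final signature size. With the full roster and the default 10
#' runs, the ensemble comprises N_c = 80 classifier instances.
#'
#' @param classifier_families Subset of [classifier_families()].
#' @param n_runs Runs per family (default 10); each run is one stratified
#'   cross-validation and yields one ranked list.
#' @param n_folds Folds per run (default 10).
#' @param top_k_tally How many top-ranked features of each instance enter the
#'   tally (default 100).
#' @param signature_size Number of features in the final signature
#'   (default 100).
#' @param seed Master seed; per-(family, run) sub-seeds are derived from it
#'   by fixed enumeration order, so results are independent of execution
#'   order.
#' @param params Named list of per-family hyperparameter overrides, e.g.
#'   `list(gradient_boosting = list(n_estimators = 50))`.
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(classifier_families = mirsign::classifier_families(),
                            n_runs = 10L, n_folds = 10L, top_k_tally = 100L,
                            signature_size = 100L, seed = 42L,
                            params = list()) {
  stopifnot(n_runs >= 1L, top_k_tally >= 1L, signature_size >= 1L)
  unknown <- setdiff(classifier_families, mirsign::classifier_families())
  if (length(unknown))
    stop("unsupported classifier families: ", paste(unknown, collapse = ", "))
  structure(list(classifier_families = classifier_families,
                 n_runs = as.integer(n_runs), n_folds = as.integer(n_folds),
                 top_k_tally = as.integer(top_k_tally),
                 signature_size = as.integer(signature_size),
                 seed = as.integer(seed), params = params),
            class = "ensemble_config")
}

config_digest <- function(cfg) {
  flat <- paste(deparse(cfg[order(names(unclass(cfg)))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(flat) * (seq_along(utf8ToInt(flat)) %% 251 + 1)) %% 4294967291)
}

#' Tally feature appearances in top-k ranked lists
#'
#' For each feature, counts the number of ranked lists whose first
#' `min(k, length(list))` entries contain it (the tally N_t).
#'
#' @param lists List of ranked feature-name vectors (e.g. from
#'   [rank_top_k()]).
#' @param k Tally depth.
#' @param feature_names Full feature universe.
#' @return Named integer vector N_t over `feature_names`.
#' @export
tally_top_k <- function(lists, k, feature_names) {
  if (k < 1L) stop("k must be >= 1")
  tally <- stats::setNames(integer(length(feature_names)), feature_names)
  for (l in lists) {
    head_l <- unique(l[seq_len(min(k, length(l)))])
    unknown <- setdiff(head_l, feature_names)
    if (length(unknown))
      stop("ranked list contains unknown feature(s): ",
           paste(unknown, collapse = ", "))
    tally[head_l] <- tally[head_l] + 1L
  }
  tally
}

#' Consensus scores from a tally
#'
#' Converts the per-feature tally N_t over N_c classifier instances into the
#' consensus score s_f = N_t / N_c — e.g. a feature appearing in the top-k
#' lists of 73% of the instances scores s_f = 0.73.
#'
#' @param N_t Named integer tally per feature.
#' @param N_c Total number of classifier instances (>= 1).
#' @return Data frame (class `consensus_score_table`) with columns `feature`,
#'   `N_t`, `s_f`, and attribute `N_c`; rows in input feature order.
#' @export
consensus_scores <- function(N_t, N_c) {
  if (N_c < 1L) stop("N_c must be >= 1")
  if (any(N_t < 0) || any(N_t > N_c))
    stop("tallies must satisfy 0 <= N_t <= N_c")
  out <- data.frame(feature = names(N_t), N_t = as.integer(N_t),
                    s_f = as.numeric(N_t) / N_c, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, N_c = as.integer(N_c),
            class = c("consensus_score_table", "data.frame"))
}

#' Select the consensus signature
#'
#' Takes the top `min(k, n_features)` features by descending consensus score
#' s_f; ties are resolved by descending tally N_t (redundant when N_c is
#' shared) and then by ascending feature name, so the signature is
#' deterministic.
#'
#' @param table A `consensus_score_table` from [consensus_scores()].
#' @param k Signature size (>= 1).
#' @return Data frame (class `mirsign_signature`) with columns `rank`,
#'   `feature`, `N_t`, `s_f`.
#' @export
select_signature <- function(table, k) {
  if (k < 1L) stop("k must be >= 1")
  ord <- order(-table$s_f, -table$N_t, table$feature, method = "radix")
  keep <- ord[seq_len(min(k, nrow(table)))]
  out <- data.frame(rank = seq_along(keep), feature = table$feature[keep],
                    N_t = table$N_t[keep], s_f = table$s_f[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, N_c = attr(table, "N_c"),
            class = c("mirsign_signature", "data.frame"))
}

#' Run the ensemble feature selection
#'
#' The consensus procedure: for every (classifier family, run) pair —
#' a classifier *instance* — draw a fresh stratified fold partition from
#' the instance's sub-seed, fit the classifier on each of the `n_folds`
#' training partitions (standardization fitted on that partition only),
#' average the per-fold importance vectors into one instance-level vector,
#' and rank its top `top_k_tally` features. Features are then tallied over
#' all N_c instances, scored s_f = N_t / N_c, and the `signature_size`
#' highest-scoring features form the signature.
#'
#' @param X Expression matrix, samples x features.
#' @param y Class labels, one per sample.
#' @param cfg An [ensemble_config()].
#' @param fitters Optional named list overriding the fit function per family,
#'   each `function(X, y, params, seed)` returning an object accepted by
#'   [classifier_importance()]; used to inject lightweight estimators.
#' @return List with `scores` (consensus score table), `signature`,
#'   `ranked_lists` (one per instance) and `report` (config digest, N_c,
#'   per-instance status).
#' @export
run_ensemble_selection <- function(X, y, cfg = ensemble_config(),
                                   fitters = NULL) {
  y <- as.character(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (length(unique(y)) < 2L) stop("need at least 2 classes")
  feature_names <- colnames(X)
  instances <- expand.grid(run = seq_len(cfg$n_runs),
                           family = cfg$classifier_families,
                           stringsAsFactors = FALSE)
  ranked_lists <- list()
  status <- character(nrow(instances))
  for (i in seq_len(nrow(instances))) {
    family <- instances$family[i]
    run <- instances$run[i]
    sub_seed <- child_seed(cfg$seed, i)
    res <- tryCatch({
      fold <- stratified_folds(y, cfg$n_folds, seed = sub_seed)
      imp_sum <- stats::setNames(numeric(length(feature_names)), feature_names)
      for (f in 0:(cfg$n_folds - 1L)) {
        tr <- fold != f
        std <- fit_standardization(X[tr, , drop = FALSE])
        Xtr <- apply_standardization(std, X[tr, , drop = FALSE])
        fit_seed <- child_seed(sub_seed, f + 1L)
        model <- if (!is.null(fitters) && !is.null(fitters[[family]]))
          fitters[[family]](Xtr, y[tr], cfg$params[[family]] %||% list(), fit_seed)
        else
          fit_classifier(family, Xtr, y[tr],
                         params = cfg$params[[family]] %||% list(),
                         seed = fit_seed)
        imp_sum <- imp_sum + classifier_importance(model, feature_names)
      }
      rank_top_k(imp_sum / cfg$n_folds, cfg$top_k_tally,
                 instance_id = c(family, run))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("instance (", family, ", run ", run, ") failed and was skipped: ",
              conditionMessage(res))
      status[i] <- paste0("failed: ", conditionMessage(res))
    } else {
      ranked_lists[[length(ranked_lists) + 1L]] <- res
      status[i] <- "ok"
    }
  }
  N_c <- length(ranked_lists)
  if (!N_c) stop("all classifier instances failed")
  N_t <- tally_top_k(ranked_lists, cfg$top_k_tally, feature_names)
  scores <- consensus_scores(N_t, N_c)
  signature <- select_signature(scores, cfg$signature_size)
  report <- list(config_digest = config_digest(cfg),
                 n_instances = nrow(instances), N_c = N_c,
                 families = cfg$classifier_families, n_runs = cfg$n_runs,
                 n_folds = cfg$n_folds, top_k_tally = cfg$top_k_tally,
                 signature_size = cfg$signature_size, seed = cfg$seed,
                 sd_convention = "population",
                 instance_status = data.frame(
                   family = instances$family, run = instances$run,
                   status = status, stringsAsFactors = FALSE))
  list(scores = scores, signature = signature,
       ranked_lists = ranked_lists, report = report)
}

#' Write a signature, score table or run report to disk
#'
#' Signatures are written as TSV with columns `rank`, `feature`, `N_t`,
#' `s_f` and a comment header carrying N_c; score tables analogously; run
#' reports as JSON. All outputs are byte-stable for a fixed seed.
#'
#' @param signature A `mirsign_signature` (or a `consensus_score_table` for
#'   [write_scores_tsv()]).
#' @param path Output path.
#' @export
write_signature_tsv <- function(signature, path) {
  con <- file(path, "w")
  on.exit(close(con))
  N_c <- attr(signature, "N_c")
  if (!is.null(N_c)) writeLines(paste0("# N_c: ", N_c), con)
  utils::write.table(as.data.frame(signature), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  nc <- sub("^# N_c: ", "", grep("^# N_c:", meta, value = TRUE))
  structure(df, N_c = if (length(nc)) as.integer(nc) else NULL,
            class = c("mirsign_signature", "data.frame"))
}

#' @rdname write_signature_tsv
#' @param scores A `consensus_score_table`.
#' @export
write_scores_tsv <- function(scores, path) {
  write_signature_tsv(scores, path)
}

#' @rdname write_signature_tsv
#' @param report Run-report list from [run_ensemble_selection()].
#' @export
write_run_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
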