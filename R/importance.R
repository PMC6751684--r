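#' Feature importance from an ensemble of classification trees
#'
#' For tree-based classifiers, the importance of a feature is the number of
#' internal splits that use it, totalled across every tree in the ensemble
#' ("counted and sorted by frequency"). Counts are raw, not weighted by
#' depth, impurity decrease or sample coverage. Features never used in a
#' split get 0.
#'
#' @param tree_structures List of trees; each tree is a character vector of
#'   the feature names used at its internal split nodes (one entry per
#'   split, repeats allowed). See [extract_tree_splits()] for converting
#'   fitted models.
#' @param feature_names All candidate feature names.
#' @return An `importance_vector`: named non-negative numeric vector over
#'   `feature_names` with attribute `source_typology = "tree_ensemble"`.
#' @export
importance_from_tree_ensemble <- function(tree_structures, feature_names) {
  if (!length(tree_structures)) stop("empty tree ensemble")
  splits <- unlist(tree_structures, use.names = FALSE)
  unknown <- setdiff(splits, feature_names)
  if (length(unknown))
    stop("split on unknown feature(s): ", paste(unique(unknown), collapse = ", "))
  counts <- table(factor(splits, levels = feature_names))
  importance_vector(as.numeric(counts), feature_names, "tree_ensemble")
}

#' Feature importance from linear-model coefficients
#'
#' For linear classifiers, coefficient magnitude is a proxy for feature
#' relevance. For multiclass models fitted one-vs-rest, the per-feature
#' importance is the sum of absolute coefficients across class rows — a
#' reduction that is symmetric in the classes and monotone in every row, so
#' rescaling all coefficients leaves the ranking unchanged.
#'
#' @param coefficients Numeric matrix, classes x features (one row for a
#'   binary model). Column names, when present, must match `feature_names`.
#' @param feature_names Feature names, one per coefficient column.
#' @return An `importance_vector` with `source_typology = "linear"`.
#' @export
importance_from_linear_coefficients <- function(coefficients, feature_names) {
  coefficients <- rbind(coefficients)
  if (!nrow(coefficients)) stop("coefficient matrix needs at least one row")
  if (ncol(coefficients) != length(feature_names))
    stop("coefficient columns (", ncol(coefficients),
         ") != number of features (", length(feature_names), ")")
  if (!all(is.finite(coefficients))) stop("non-finite coefficient")
  if (!is.null(colnames(coefficients)) &&
      !identical(colnames(coefficients), as.character(feature_names)))
    stop("coefficient column names do not match feature_names")
  importance_vector(colSums(abs(coefficients)), feature_names, "linear")
}

importance_vector <- function(values, feature_names, typology) {
  if (any(!is.finite(values)) || any(values < 0))
    stop("importance values must be finite and non-negative")
  structure(stats::setNames(as.numeric(values), feature_names),
            source_typology = typology, class = "importance_vector")
}

#' Top-k ranked feature list from an importance vector
#'
#' Orders features by descending importance and truncates to the first
#' `min(k, n_features)` names. Ties are broken by ascending feature name so
#' the ranking is deterministic across runs and platforms.
#'
#' @param v Named numeric importance vector (e.g. from
#'   [importance_from_tree_ensemble()]).
#' @param k Number of features to keep (>= 1).
#' @param instance_id Optional identifier (classifier family, run index)
#'   attached to the returned list.
#' @return Character vector of feature names, most to least important, with
#'   attribute `instance_id`.
#' @export
rank_top_k <- function(v, k, instance_id = NULL) {
  if (k < 1L) stop("k must be >= 1")
  nm <- names(v)
  ord <- order(-as.numeric(v), nm, method = "radix")
  structure(nm[ord][seq_len(min(k, length(v)))], instance_id = instance_id)
}

#' Extract split-feature lists from fitted tree-ensemble models
#'
#' Converts a fitted model into the list-of-split-name representation
#' consumed by [importance_from_tree_ensemble()]: one character vector per
#' tree, holding the feature name of every internal split node.
#'
#' @param model A fitted `ranger` or `xgb.Booster` model.
#' @param feature_names Feature names the model was trained on (required for
#'   xgboost, which stores positional names).
#' @return List of character vectors, one per tree.
#' @export
extract_tree_splits <- function(model, feature_names = NULL) {
  if (inherits(model, "ranger")) {
    lapply(seq_len(model$num.trees), function(t) {
      info <- ranger::treeInfo(model, t)
      as.character(info$splitvarName[!info$terminal])
    })
  } else if (inherits(model, "xgb.Booster")) {
    dump <- xgboost::xgb.model.dt.tree(model = model)
    splits <- dump[dump$Feature != "Leaf", c("Tree", "Feature")]
    out <- split(as.character(splits$Feature), splits$Tree)
    # keep leaf-only trees as empty entries
    all_trees <- as.character(sort(unique(dump$Tree)))
    stats::setNames(lapply(all_trees, function(t) out[[t]] %||% character(0)),
                    NULL)
  } else {
    stop("unsupported tree-ensemble model class: ",
         paste(class(model), collapse = "/"))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ranked feature list as one-column TSV
#'
#' The instance identifier is stored in a `#` comment header line.
#'
#' @param ranked Character vector from [rank_top_k()].
#' @param path Output path.
#' @export
write_ranked_list_tsv <- function(ranked, path) {
  id <- attr(ranked, "instance_id")
  lines <- c(if (!is.null(id)) paste0("# instance_id: ", paste(id, collapse = ":")),
             "feature", as.character(ranked))
  writeLines(lines, path)
  invisible(path)
}
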