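#' ROC curve and area under the curve
#'
#' Sweeps a decision threshold over the distinct scores in descending
#' order (tied scores are grouped into a single operating point) and
#' plots the false positive rate `FPR = FP / (FP + TN)` against the
#' true positive rate `TPR = TP / (TP + FN)`. The curve starts at
#' (0, 0), ends at (1, 1), and the area under it is computed by the
#' trapezoid rule, which with grouped ties equals the tie-corrected
#' Mann-Whitney statistic `U / (n+ * n-)`. An AUC of 0.5 is chance
#' level; 1 is perfect separation.
#'
#' @param scores Numeric vector of classifier confidence scores (finite).
#' @param labels Class labels: `"positive"`/`"negative"` (or a logical
#'   vector, `TRUE` = positive). Both classes must be present.
#' @return A `roc_result`: list with `points` (data frame `threshold`,
#'   `fpr`, `tpr`; the first row is the empty classification at
#'   threshold `Inf`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  np <- sum(pos)
  nn <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE)  # last occurrence of each score
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  points <- data.frame(threshold = c(Inf, s[last]),
                       fpr = c(0, fp / nn),
                       tpr = c(0, tp / np))
  auc <- sum(diff(points$fpr) *
               (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' @exportS3Method base::print
print.roc_result <- function(x, ...) {
  cat("roc_result: AUC = ", signif(x$auc, 4), " (",
      nrow(x$points) - 1, " operating points)\n", sep = "")
  invisible(x)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels == "positive"
}

#' Sensitivity (TPR) of the score > 0 decision rule
#'
#' @param scores Numeric confidence scores.
#' @param labels Class labels (see [roc_curve()]).
#' @return `TP / (TP + FN)` for the classifier "positive iff score > 0".
#' @export
sensitivity_at_zero <- function(scores, labels) {
  pos <- as_positive(labels)
  sum(scores > 0 & pos) / sum(pos)
}

#' Stratified cross-validated ADTree scores
#'
#' Splits the usable (non-`excluded`) instances into stratified folds,
#' trains an ADTree on each training split and scores the held-out
#' fold, so every instance receives exactly one out-of-fold confidence
#' score. Fold assignment is controlled by `seed`; per-fold model seeds
#' are derived from it by fold index.
#'
#' In the default mode the disease neighbor ratio column is used as
#' computed up front on the full annotation, which mirrors the original
#' single-pass feature computation but lets each test protein's DNR see
#' the full label set. With `dnr_strict = TRUE` (requires `net`) the
#' DNR column of both splits is recomputed per fold from the positive
#' proteins of the training split only.
#'
#' @param dataset A `labeled_dataset`.
#' @param folds Number of folds (default 10); each class must have at
#'   least `folds` members.
#' @param n_iterations Boosting iterations per fold model.
#' @param seed Integer seed for fold assignment.
#' @param epsilon Smoothing constant, see [train_adtree()].
#' @param features Feature subset to train on.
#' @param dnr_strict Recompute DNR per training fold (no label leakage).
#' @param net Interaction network; required when `dnr_strict = TRUE`.
#' @return Data frame `protein`, `label`, `fold`, `score` (one row per
#'   usable instance), with attribute `seed`.
#' @export
cross_validate <- function(dataset, folds = 10, n_iterations = 20,
                           seed = 1, epsilon = 1, features = NULL,
                           dnr_strict = FALSE, net = NULL) {
  rows <- training_rows(dataset)
  n_by_class <- table(rows$label)
  if (any(n_by_class < folds)) {
    stop("each class needs at least ", folds, " members (have ",
         paste(names(n_by_class), n_by_class, collapse = ", "),
         "); use fewer folds", call. = FALSE)
  }
  if (dnr_strict && is.null(net)) {
    stop("dnr_strict = TRUE requires the interaction network",
         call. = FALSE)
  }

  set.seed(seed)
  fold_id <- integer(nrow(rows))
  for (cl in names(n_by_class)) {
    idx <- which(rows$label == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  out <- vector("list", folds)
  for (k in seq_len(folds)) {
    train <- rows[fold_id != k, , drop = FALSE]
    test <- rows[fold_id == k, , drop = FALSE]
    if (dnr_strict) {
      dg <- train$protein[train$label == "positive"]
      dnr <- disease_neighbor_ratio(net, dg)
      train$dnr <- unname(dnr[train$protein])
      test$dnr <- unname(dnr[test$protein])
    }
    model <- train_adtree(train, n_iterations = n_iterations,
                          epsilon = epsilon, seed = seed + k,
                          features = features)
    out[[k]] <- data.frame(protein = test$protein, label = test$label,
                           fold = k, score = adtree_score(model, test),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  res
}

#' Cross-validated AUC over a series of disease-count thresholds
#'
#' Builds one labeled dataset per minimum-disease threshold `k` (the
#' feature table is computed once on the full network) and reports the
#' stratified cross-validated AUC of each under identical pipeline
#' settings. Raising the threshold removes weak positives only, so the
#' series shows how class purity affects separability.
#'
#' @param net An `igraph` interaction network.
#' @param annotation A `disease_annotation`.
#' @param k_values Thresholds to evaluate (default 1..5).
#' @param folds,n_iterations,seed,epsilon Passed to [cross_validate()];
#'   the per-threshold seed is derived as `seed + k`.
#' @return Data frame `k_min`, `n_pos`, `n_neg`, `auc`.
#' @export
threshold_series <- function(net, annotation, k_values = 1:5, folds = 10,
                             n_iterations = 20, seed = 1, epsilon = 1) {
  ft <- build_feature_table(net, annotation, k_min = 1)
  out <- lapply(k_values, function(k) {
    ds <- assign_labels(ft, k)
    cv <- cross_validate(ds, folds = folds, n_iterations = n_iterations,
                         seed = seed + k, epsilon = epsilon)
    data.frame(k_min = k, n_pos = attr(ds, "n_pos"),
               n_neg = attr(ds, "n_neg"),
               auc = roc_curve(cv$score, cv$label)$auc)
  })
  do.call(rbind, out)
}

#' Single-feature ablation study
#'
#' Re-runs the cross-validated evaluation with one feature removed at a
#' time and reports the change in sensitivity (TPR of the score > 0
#' rule, see [sensitivity_at_zero()]) and in AUC relative to the
#' all-features baseline. A large sensitivity drop marks a feature the
#' classifier depends on.
#'
#' @param dataset A `labeled_dataset`.
#' @param features_to_drop Features to remove one at a time (default:
#'   every available canonical feature). Unknown names are an error.
#' @param folds,n_iterations,seed,epsilon Passed to [cross_validate()];
#'   the same fold seed is used for the baseline and every ablation so
#'   the splits are identical.
#' @return Data frame `dropped`, `sensitivity`, `auc`,
#'   `delta_sensitivity`, `delta_auc` (deltas are ablated minus
#'   baseline), with the baseline row first (`dropped = "<none>"`).
#' @export
ablation_study <- function(dataset, features_to_drop = NULL, folds = 10,
                           n_iterations = 20, seed = 1, epsilon = 1) {
  avail <- intersect(adnet_features(), names(dataset))
  if (is.null(features_to_drop)) features_to_drop <- avail
  bad <- setdiff(features_to_drop, avail)
  if (length(bad) > 0) {
    stop("unknown feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(setdiff(avail, features_to_drop)) == 0 &&
      length(avail) == 1) {
    stop("cannot drop every feature", call. = FALSE)
  }

  eval_with <- function(feats) {
    cv <- cross_validate(dataset, folds = folds,
                         n_iterations = n_iterations, seed = seed,
                         epsilon = epsilon, features = feats)
    c(sensitivity = sensitivity_at_zero(cv$score, cv$label),
      auc = roc_curve(cv$score, cv$label)$auc)
  }
  base <- eval_with(avail)
  rows <- lapply(features_to_drop, function(f) {
    m <- eval_with(setdiff(avail, f))
    data.frame(dropped = f, sensitivity = m[["sensitivity"]],
               auc = m[["auc"]],
               delta_sensitivity = m[["sensitivity"]] - base[["sensitivity"]],
               delta_auc = m[["auc"]] - base[["auc"]],
               stringsAsFactors = FALSE)
  })
  out <- rbind(data.frame(dropped = "<none>",
                          sensitivity = base[["sensitivity"]],
                          auc = base[["auc"]], delta_sensitivity = 0,
                          delta_auc = 0, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Read an external score file for side-by-side ROC comparison
#'
#' Reads a tab-separated file with columns `protein` and `score` (for
#' example the exported predictions of another classifier) so external
#' models can be evaluated with the same [roc_curve()] machinery.
#'
#' @param path Path to the TSV file.
#' @return Data frame `protein`, `score`.
#' @export
read_scores_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein", "score") %in% names(tab))) {
    stop("score file must have columns 'protein' and 'score'",
         call. = FALSE)
  }
  tab$score <- as.numeric(tab$score)
  tab[, c("protein", "score")]
}

#' Write ROC operating points as TSV
#'
#' @param roc A `roc_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
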