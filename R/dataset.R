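#' Assign class labels at a disease-count threshold
#'
#' Relabels a feature table at a given minimum-disease threshold
#' `k_min`: proteins with at least `k_min` distinct disease annotations
#' are `positive`, proteins with none are `negative`, and proteins with
#' an intermediate count are `excluded` — weak positives are removed
#' from training rather than moved to the negative class, so raising the
#' threshold affects only the positive class.
#'
#' @param features A `feature_table` from [build_feature_table()].
#' @param k_min Minimum number of distinct diseases for the positive
#'   class; must be >= 1.
#' @return A `labeled_dataset`: the feature table with refreshed
#'   `label` column and attributes `k_min`, `n_pos`, `n_neg`,
#'   `n_excluded`.
#' @export
assign_labels <- function(features, k_min) {
  stopifnot(is.data.frame(features), "n_diseases" %in% names(features))
  lab <- label_from_counts(features$n_diseases, k_min)
  out <- features
  out$label <- lab
  structure(out,
            k_min = k_min,
            n_pos = sum(lab == "positive"),
            n_neg = sum(lab == "negative"),
            n_excluded = sum(lab == "excluded"),
            class = c("labeled_dataset", "data.frame"))
}

#' Build a labeled dataset from network and annotation
#'
#' Convenience wrapper: computes the feature table on the full network
#' (see [build_feature_table()]) and labels it at threshold `k_min`.
#'
#' @inheritParams build_feature_table
#' @inheritParams assign_labels
#' @return A `labeled_dataset`.
#' @export
build_dataset <- function(net, annotation, k_min = 1, dnr_genes = NULL) {
  assign_labels(build_feature_table(net, annotation, k_min = k_min,
                                    dnr_genes = dnr_genes), k_min)
}

#' Summary counts of a labeled dataset
#'
#' @param dataset A `labeled_dataset`.
#' @return List with `k_min`, `n_pos`, `n_neg`, `n_excluded`, `n_total`.
#' @export
dataset_counts <- function(dataset) {
  list(k_min = attr(dataset, "k_min"),
       n_pos = attr(dataset, "n_pos"),
       n_neg = attr(dataset, "n_neg"),
       n_excluded = attr(dataset, "n_excluded"),
       n_total = nrow(dataset))
}

# rows usable for training/evaluation, with -1/+1 class coding
training_rows <- function(dataset) {
  keep <- dataset$label %in% c("positive", "negative")
  out <- dataset[keep, , drop = FALSE]
  out$y <- ifelse(out$label == "positive", 1, -1)
  out
}

#' Greedy correlation-based feature selection
#'
#' Forward stepwise search over feature subsets scored by a
#' correlation-based merit: with `k` selected features, mean
#' feature-class symmetric uncertainty `r_cf` and mean feature-feature
#' symmetric uncertainty `r_ff`,
#' \deqn{merit = k\,\bar r_{cf} / \sqrt{k + k(k-1)\,\bar r_{ff}}}
#' Features are discretized by equal-frequency binning before the
#' symmetric uncertainties are computed. Selection adds the
#' merit-maximizing feature until no addition improves the merit;
#' the unselected features are then appended, ranked by the merit each
#' would achieve if added next (ties broken alphabetically). A constant
#' feature has zero symmetric uncertainty with everything and so never
#' improves the merit.
#'
#' @param dataset A `labeled_dataset` with both classes present.
#' @param features Candidate feature names (default the canonical ten).
#' @param bins Number of equal-frequency bins for discretization.
#' @return Character vector: selected features in order of selection,
#'   then the remainder by marginal merit. Attributes `n_selected` (how
#'   many were chosen by the stopping rule) and `merit` (the subset
#'   merit as each feature is appended).
#' @export
greedy_feature_selection <- function(dataset, features = adnet_features(),
                                     bins = 10) {
  stopifnot(length(features) >= 2)
  rows <- training_rows(dataset)
  if (length(unique(rows$label)) < 2) {
    stop("both classes must be present for feature selection", call. = FALSE)
  }
  disc <- lapply(rows[features], discretize_ef, bins = bins)
  cls <- rows$label

  su_cf <- vapply(disc, symmetric_uncertainty, numeric(1), y = cls)
  su_ff <- matrix(NA_real_, length(features), length(features),
                  dimnames = list(features, features))
  ff <- function(a, b) {
    if (is.na(su_ff[a, b])) {
      v <- symmetric_uncertainty(disc[[a]], disc[[b]])
      su_ff[a, b] <<- v
      su_ff[b, a] <<- v
    }
    su_ff[a, b]
  }
  merit_of <- function(set) {
    k <- length(set)
    rcf <- mean(su_cf[set])
    rff <- if (k < 2) 0 else {
      pr <- utils::combn(set, 2)
      mean(vapply(seq_len(ncol(pr)), function(i) ff(pr[1, i], pr[2, i]),
                  numeric(1)))
    }
    k * rcf / sqrt(k + k * (k - 1) * rff)
  }

  selected <- character(0)
  best_merit <- -Inf
  merits <- numeric(0)
  candidates <- sort(features, method = "radix")
  repeat {
    rest <- setdiff(candidates, selected)
    if (length(rest) == 0) break
    trial <- vapply(rest, function(f) merit_of(c(selected, f)), numeric(1))
    pick <- rest[which.max(trial)]   # ties -> first alphabetically
    if (trial[pick] <= best_merit + 1e-12) break
    best_merit <- trial[pick]
    selected <- c(selected, pick)
    merits <- c(merits, best_merit)
  }

  rest <- setdiff(candidates, selected)
  if (length(rest) > 0) {
    marginal <- vapply(rest, function(f) merit_of(c(selected, f)),
                       numeric(1))
    ord <- order(-marginal, rest, method = "radix")
    rest <- rest[ord]
    merits <- c(merits, marginal[ord])
  }
  structure(c(selected, rest),
            n_selected = length(selected),
            merit = unname(merits))
}

# equal-frequency discretization into at most `bins` bins; features
# with few distinct values keep one bin per value
discretize_ef <- function(x, bins = 10) {
  u <- sort(unique(x))
  if (length(u) <= bins) return(match(x, u))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))  # constant feature
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

# symmetric uncertainty between two discrete vectors, in [0, 1]
symmetric_uncertainty <- function(x, y) {
  hx <- shannon_entropy(table(x))
  hy <- shannon_entropy(table(y))
  if (hx + hy == 0) return(0)
  hxy <- shannon_entropy(table(x, y))
  2 * (hx + hy - hxy) / (hx + hy)
}

shannon_entropy <- function(tab) {
  p <- as.numeric(tab) / sum(tab)
  p <- p[p > 0]
  -sum(p * log2(p))
}
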