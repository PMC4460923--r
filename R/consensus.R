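# identity of a decision rule for conservation matching: the attribute
# path from the root to its precondition node (with branch directions)
# plus the rule's own attribute; thresholds are deliberately excluded
rule_path_key <- function(model, j) {
  p <- model$rules$precondition[j]
  parts <- character(0)
  while (p > 0) {
    r <- (p + 1L) %/% 2L             # rule that created node p
    dir <- if (p %% 2L == 1L) "T" else "F"
    parts <- c(paste0(model$rules$attribute[r], ":", dir), parts)
    p <- model$rules$precondition[r]
  }
  paste0(paste(parts, collapse = "/"), "::", model$rules$attribute[j])
}

rule_keys <- function(model) {
  vapply(seq_len(nrow(model$rules)), function(j) rule_path_key(model, j),
         character(1))
}

#' Train an ensemble of ADTrees on bootstrap resamples
#'
#' Draws `B` size-n resamples (with replacement) of the usable
#' instances and trains one ADTree on each. A resample that comes out
#' single-class is redrawn (up to 100 attempts). Per-tree seeds are
#' derived deterministically from the master seed.
#'
#' @param dataset A `labeled_dataset`.
#' @param B Number of bootstrap trees; default 100.
#' @param n_iterations,epsilon,features Passed to [train_adtree()].
#' @param seed Master seed for resampling.
#' @return List of `B` `adtree` models.
#' @export
bootstrap_trees <- function(dataset, B = 100, n_iterations = 20,
                            seed = 1, epsilon = 1, features = NULL) {
  stopifnot(B >= 2)
  rows <- training_rows(dataset)
  n <- nrow(rows)
  set.seed(seed)
  lapply(seq_len(B), function(b) {
    for (attempt in seq_len(100)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(rows$label[idx])) == 2) {
        return(train_adtree(rows[idx, , drop = FALSE],
                            n_iterations = n_iterations,
                            epsilon = epsilon, seed = seed + b,
                            features = features))
      }
    }
    stop("could not draw a two-class bootstrap resample in 100 attempts",
         call. = FALSE)
  })
}

#' Rule conservation across a bootstrap ensemble
#'
#' Annotates every rule of a reference ADTree with the fraction of
#' ensemble trees containing a matching rule. Two rules match when they
#' test the same attribute under the same precondition path (same
#' ancestor attributes and branch directions) and their thresholds
#' differ by at most `threshold_tolerance` times the attribute's
#' interquartile range in the dataset — bootstrap thresholds jitter, so
#' rule identity is tolerance-matched rather than exact. Conservation
#' fractions are binned into the bands >= 0.9, >= 0.7, >= 0.5, >= 0.3,
#' >= 0.1 and < 0.1 (each fraction gets the highest band whose lower
#' bound it reaches).
#'
#' @param reference The `adtree` whose rules are annotated (typically
#'   the tree trained on the full dataset).
#' @param ensemble List of `adtree` models from [bootstrap_trees()].
#' @param dataset The `labeled_dataset` used to compute attribute
#'   interquartile ranges.
#' @param threshold_tolerance Threshold match tolerance as a fraction
#'   of the attribute IQR; default 0.25.
#' @return A `consensus_tree`: list with `root_value`, `rules` (the
#'   reference rules plus `path_key`, `conservation`, `bin`), `B` and
#'   `threshold_tolerance`.
#' @export
rule_conservation <- function(reference, ensemble, dataset,
                              threshold_tolerance = 0.25) {
  stopifnot(length(ensemble) >= 1)
  rows <- training_rows(dataset)
  rules <- reference$rules
  keys <- rule_keys(reference)
  iqr <- vapply(unique(rules$attribute), function(a) {
    stats::IQR(rows[[a]])
  }, numeric(1))

  ens_tab <- lapply(ensemble, function(m) {
    data.frame(key = rule_keys(m), threshold = m$rules$threshold,
               stringsAsFactors = FALSE)
  })

  conservation <- vapply(seq_len(nrow(rules)), function(j) {
    tol <- threshold_tolerance * iqr[[rules$attribute[j]]]
    hit <- vapply(ens_tab, function(tb) {
      any(tb$key == keys[j] &
            abs(tb$threshold - rules$threshold[j]) <= tol)
    }, logical(1))
    mean(hit)
  }, numeric(1))

  rules$path_key <- keys
  rules$conservation <- conservation
  rules$bin <- conservation_bin(conservation)
  structure(list(root_value = reference$root_value, rules = rules,
                 B = length(ensemble),
                 threshold_tolerance = threshold_tolerance),
            class = "consensus_tree")
}

#' Conservation band of a conservation fraction
#'
#' @param conservation Numeric vector in `[0, 1]`.
#' @return Character vector with levels `">=0.9"`, `">=0.7"`,
#'   `">=0.5"`, `">=0.3"`, `">=0.1"`, `"<0.1"`.
#' @export
conservation_bin <- function(conservation) {
  stopifnot(all(conservation >= 0 & conservation <= 1))
  cuts <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  vapply(conservation, function(x) {
    hit <- cuts[cuts <= x]
    if (length(hit) == 0) "<0.1" else paste0(">=", format(hit[1]))
  }, character(1))
}

#' @exportS3Method base::print
print.consensus_tree <- function(x, ...) {
  cat("consensus_tree: ", nrow(x$rules), " rules over B = ", x$B,
      " bootstrap trees\n", sep = "")
  if (nrow(x$rules) > 0) {
    cat(paste0("  (", x$rules$index, ") ", x$rules$attribute, " >= ",
               signif(x$rules$threshold, 4), "  conservation ",
               format(x$rules$conservation, digits = 2), " [",
               x$rules$bin, "]", collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Stability of discovered rules under data removal
#'
#' Removes a fraction of the usable instances at random, retrains the
#' full-data reference tree and its bootstrap ensemble on the reduced
#' data, and compares the discovered rule sets: the Jaccard similarity
#' of the (attribute, path) rule identities and the per-rule change in
#' conservation for rules found in both runs.
#'
#' @param dataset A `labeled_dataset`.
#' @param fraction_removed Fraction of usable instances to drop;
#'   `0 <= fraction_removed < 1` (0 is the degenerate self-comparison).
#' @param seed Seed for the removal draw and both ensembles.
#' @param B,n_iterations,epsilon,threshold_tolerance As in
#'   [bootstrap_trees()] and [rule_conservation()].
#' @return A `stability_report`: list with `jaccard`, `full` and
#'   `reduced` consensus trees, and `shared` (data frame of path keys
#'   present in both, with both conservations and their delta).
#' @export
stability_check <- function(dataset, fraction_removed = 0.15, seed = 1,
                            B = 100, n_iterations = 20, epsilon = 1,
                            threshold_tolerance = 0.25) {
  stopifnot(fraction_removed >= 0, fraction_removed < 1)
  rows <- training_rows(dataset)

  consensus_on <- function(d, s) {
    ref <- train_adtree(d, n_iterations = n_iterations, epsilon = epsilon,
                        seed = s)
    ens <- bootstrap_trees(d, B = B, n_iterations = n_iterations,
                           seed = s, epsilon = epsilon)
    rule_conservation(ref, ens, d, threshold_tolerance)
  }

  full <- consensus_on(rows, seed)
  set.seed(seed + 104729L)
  n_drop <- round(fraction_removed * nrow(rows))
  reduced_rows <- if (n_drop > 0) {
    rows[-sample.int(nrow(rows), n_drop), , drop = FALSE]
  } else {
    rows
  }
  reduced <- consensus_on(reduced_rows, seed)

  kf <- unique(full$rules$path_key)
  kr <- unique(reduced$rules$path_key)
  jaccard <- if (length(kf) == 0 && length(kr) == 0) 1 else
    length(intersect(kf, kr)) / length(union(kf, kr))

  shared_keys <- intersect(kf, kr)
  shared <- data.frame(
    path_key = shared_keys,
    conservation_full = full$rules$conservation[
      match(shared_keys, full$rules$path_key)],
    conservation_reduced = reduced$rules$conservation[
      match(shared_keys, reduced$rules$path_key)],
    stringsAsFactors = FALSE)
  shared$delta <- shared$conservation_reduced - shared$conservation_full

  structure(list(jaccard = jaccard, fraction_removed = fraction_removed,
                 full = full, reduced = reduced, shared = shared),
            class = "stability_report")
}

#' @exportS3Method base::print
print.stability_report <- function(x, ...) {
  cat("stability_report: removed ", 100 * x$fraction_removed,
      "% of instances\n  rule-set Jaccard similarity: ",
      signif(x$jaccard, 3), "\n  shared rules: ", nrow(x$shared),
      "\n", sep = "")
  invisible(x)
}

#' Serialize a consensus tree to JSON
#'
#' @param ct A `consensus_tree`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
consensus_json <- function(ct, path = NULL) {
  json <- jsonlite::toJSON(list(format = "adnet/consensus", version = 1L,
                                root_value = ct$root_value, B = ct$B,
                                threshold_tolerance = ct$threshold_tolerance,
                                rules = ct$rules),
                           auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Export a consensus tree as Graphviz DOT
#'
#' Decision nodes are boxes colored by conservation band (red >= 0.9,
#' orange >= 0.7, yellow >= 0.5, green >= 0.3, blue >= 0.1, black
#' below); prediction nodes are ovals holding the weighted-vote values.
#' Edges to the true branch are labeled with the threshold
#' (`>= threshold` goes left/true).
#'
#' @param ct A `consensus_tree`.
#' @param path Optional output path.
#' @return DOT source as a character string (invisibly when written).
#' @export
consensus_dot <- function(ct, path = NULL) {
  cols <- c(">=0.9" = "red", ">=0.7" = "orange", ">=0.5" = "yellow3",
            ">=0.3" = "green4", ">=0.1" = "blue", "<0.1" = "black")
  out <- c("digraph consensus {",
           "  node [fontname=\"Helvetica\"];",
           sprintf("  p0 [shape=oval,label=\"%.3f\"];", ct$root_value))
  for (j in seq_len(nrow(ct$rules))) {
    r <- ct$rules[j, ]
    out <- c(out,
      sprintf("  d%d [shape=box,color=%s,label=\"%s (%d)\\n%.0f%%\"];",
              r$index, cols[[r$bin]], r$attribute, r$index,
              100 * r$conservation),
      sprintf("  p%d -> d%d;", r$precondition, r$index),
      sprintf("  p%d [shape=oval,label=\"%.3f\"];", 2L * r$index - 1L,
              r$a_true),
      sprintf("  p%d [shape=oval,label=\"%.3f\"];", 2L * r$index,
              r$a_false),
      sprintf("  d%d -> p%d [label=\">= %.3g\"];", r$index,
              2L * r$index - 1L, r$threshold),
      sprintf("  d%d -> p%d [label=\"< %.3g\"];", r$index, 2L * r$index,
              r$threshold))
  }
  out <- c(out, "}")
  dot <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
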