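#' Rank high-confidence false positives as disease-gene candidates
#'
#' Negative-class proteins that the classifier nevertheless scores at
#' or above `min_confidence` look, to the model, like disease proteins:
#' they are returned ranked by confidence as candidate novel
#' disease-gene predictions. Scores may come from the full-data model
#' (default reading of a final classifier's predictions) or from
#' out-of-fold evaluation; record which via `mode`.
#'
#' @param scores Numeric confidence scores.
#' @param labels Class labels aligned with `scores`.
#' @param proteins Protein ids aligned with `scores`.
#' @param min_confidence Minimum confidence score to report; default
#'   0.5.
#' @param mode Provenance of the scores, recorded in the report
#'   (`"full_model"` or `"out_of_fold"`).
#' @return A `candidate_report`: data frame `protein`, `score`, `rank`,
#'   sorted by score descending (ties broken by protein id), possibly
#'   empty; attributes `min_confidence` and `mode`.
#' @export
rank_false_positives <- function(scores, labels, proteins,
                                 min_confidence = 0.5,
                                 mode = c("full_model", "out_of_fold")) {
  mode <- match.arg(mode)
  stopifnot(length(scores) == length(labels),
            length(scores) == length(proteins))
  neg <- !as_positive(labels)
  keep <- neg & scores >= min_confidence
  out <- data.frame(protein = as.character(proteins[keep]),
                    score = scores[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$protein, method = "radix"), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, min_confidence = min_confidence, mode = mode,
            class = c("candidate_report", "data.frame"))
}

#' Disease distribution of a protein's network neighborhood
#'
#' Counts, for each disease, how many of a protein's first-order
#' neighbors (direct interaction partners) or second-order neighbors
#' (proteins at shortest-path distance exactly 2, excluding the protein
#' itself and its direct partners) carry that disease annotation. A
#' neighbor annotated to a disease counts once regardless of its PMID
#' support.
#'
#' @param net An `igraph` interaction network.
#' @param annotation A `disease_annotation`.
#' @param protein Query protein id; must be in the network.
#' @param order Neighborhood order, 1 or 2.
#' @param top_n Number of diseases to report (by count, ties by disease
#'   id); default 5.
#' @return Data frame `disease_id`, `disease_name`, `neighbor_count`,
#'   at most `top_n` rows (empty when no neighbor is annotated).
#' @export
neighbor_disease_distribution <- function(net, annotation, protein,
                                          order = 1, top_n = 5) {
  stopifnot(order %in% c(1, 2))
  if (!protein %in% igraph::V(net)$name) {
    stop("protein '", protein, "' is not in the network", call. = FALSE)
  }
  nb <- neighbor_set(net, protein, order)
  hits <- annotation[annotation$gene %in% nb, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(disease_id = character(0),
                      disease_name = character(0),
                      neighbor_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  # one row per (gene, disease) pair already, so counting rows per
  # disease counts annotated neighbors once each
  agg <- stats::aggregate(hits$gene,
                          by = list(disease_id = hits$disease_id),
                          FUN = function(g) length(unique(g)))
  names(agg)[2] <- "neighbor_count"
  agg$disease_name <- hits$disease_name[match(agg$disease_id,
                                              hits$disease_id)]
  agg <- agg[order(-agg$neighbor_count, agg$disease_id,
                   method = "radix"), ]
  agg <- utils::head(agg, top_n)
  rownames(agg) <- NULL
  agg[, c("disease_id", "disease_name", "neighbor_count")]
}

# first-order: direct neighbors; second-order: distance exactly 2
neighbor_set <- function(net, protein, order) {
  first <- igraph::V(net)$name[
    as.integer(igraph::neighbors(net, protein))]
  if (order == 1) return(first)
  second <- unique(unlist(lapply(first, function(p) {
    igraph::V(net)$name[as.integer(igraph::neighbors(net, p))]
  })))
  as.character(setdiff(second, c(protein, first)))
}

#' Candidate dossier: top candidates with neighborhood disease profiles
#'
#' Builds a deterministic Markdown document describing the `top_k`
#' highest-confidence candidates: confidence score, degree, disease
#' neighbor ratio, and the top-5 disease tables of the first- and
#' second-order network neighborhoods.
#'
#' @param report A non-empty `candidate_report`.
#' @param net An `igraph` interaction network.
#' @param annotation A `disease_annotation`.
#' @param top_k Number of candidates to detail (default 15; fewer when
#'   the report is shorter).
#' @param top_n Diseases per neighborhood table.
#' @return A character scalar of Markdown, class `candidate_dossier`.
#' @export
candidate_dossier <- function(report, net, annotation, top_k = 15,
                              top_n = 5) {
  stopifnot(nrow(report) > 0)
  top <- utils::head(report, top_k)
  deg <- igraph::degree(net)
  dnr <- disease_neighbor_ratio(net, disease_genes(annotation))

  dist_md <- function(d) {
    if (nrow(d) == 0) return("    (no annotated neighbors)")
    paste0("    - ", d$disease_id, " ", d$disease_name, ": ",
           d$neighbor_count, collapse = "\n")
  }
  blocks <- vapply(seq_len(nrow(top)), function(i) {
    p <- top$protein[i]
    paste0(
      "## ", top$rank[i], ". ", p, "\n\n",
      "- confidence score: ", sprintf("%.6f", top$score[i]), "\n",
      "- degree: ", deg[[p]], "\n",
      "- disease neighbor ratio: ", sprintf("%.4f", dnr[[p]]), "\n",
      "- first-order neighbor diseases (top ", top_n, "):\n",
      dist_md(neighbor_disease_distribution(net, annotation, p, 1, top_n)),
      "\n- second-order neighbor diseases (top ", top_n, "):\n",
      dist_md(neighbor_disease_distribution(net, annotation, p, 2, top_n)),
      "\n")
  }, character(1))
  md <- paste0("# Candidate disease proteins (",
               attr(report, "mode"), " scores, confidence >= ",
               format(attr(report, "min_confidence")), ")\n\n",
               paste(blocks, collapse = "\n"))
  structure(md, class = "candidate_dossier")
}

#' @exportS3Method base::print
print.candidate_dossier <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}

#' Write a candidate report as TSV
#'
#' @param report A `candidate_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
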