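#' Read a protein-protein interaction network from an edge list
#'
#' Parses a tab-separated edge list of gene symbols into a simple
#' undirected [igraph][igraph::igraph-package] graph. The first two
#' columns of every non-comment line are taken as the interacting pair;
#' lines starting with `#` and blank lines are ignored. Gene symbols are
#' whitespace-trimmed and matched case-sensitively; no alias resolution
#' is attempted.
#'
#' Self-interactions and duplicate pairs are removed during construction
#' (binary interaction sets from curated databases routinely contain
#' both), and the counts of dropped records are reported via [message()].
#'
#' @param path Path to a tab-separated file with at least two columns.
#' @param self_loop_policy How self-interactions are handled. Only
#'   `"drop"` is supported.
#' @return An undirected simple `igraph` graph whose vertex `name`
#'   attribute holds the gene symbols.
#' @examples
#' f <- tempfile()
#' writeLines(c("# demo", "A\tB", "B\tA", "C\tC", "B\tC"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)  # 3
#' igraph::ecount(g)  # 2
#' @seealso [network_summary()], [read_annotations()]
#' @export
read_edge_list <- function(path, self_loop_policy = c("drop")) {
  self_loop_policy <- match.arg(self_loop_policy)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) {
    stop("no interaction records found in '", path, "'", call. = FALSE)
  }
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- vapply(fields, function(f) {
    length(f) < 2L || !nzchar(trimws(f[1])) || !nzchar(trimws(f[2]))
  }, logical(1))
  if (any(bad)) {
    stop("malformed interaction line(s): ",
         paste(lineno[bad], collapse = ", "),
         " (expected two tab-separated identifiers)", call. = FALSE)
  }
  from <- trimws(vapply(fields, `[`, character(1), 1L))
  to <- trimws(vapply(fields, `[`, character(1), 2L))

  n_loops <- sum(from == to)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  n_dup <- igraph::ecount(g) - n_loops -
    igraph::ecount(igraph::simplify(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  message("read ", igraph::vcount(g), " proteins / ", igraph::ecount(g),
          " interactions (dropped ", n_loops, " self-loops, ",
          n_dup, " duplicate edges)")
  g
}

#' Write a network back to the two-column edge-list format
#'
#' @param net An `igraph` graph with named vertices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read a disease-gene annotation table
#'
#' Reads a tab-separated table with header columns `gene`, `disease_id`,
#' `disease_name` and optionally `pmids` (a `;`-separated PubMed id
#' list). A gene is annotated to a disease at most once: duplicate
#' (gene, disease) rows are merged and their PMID sets unioned. Genes
#' absent from any particular interaction network are retained here;
#' intersection with a network happens when labels are assigned.
#'
#' @param path Path to the annotation TSV.
#' @return A `disease_annotation` object; see [disease_annotation()].
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  needed <- c("gene", "disease_id", "disease_name")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("annotation file '", path, "' lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"pmids" %in% names(tab)) tab$pmids <- ""
  disease_annotation(tab[, c("gene", "disease_id", "disease_name", "pmids")])
}

#' Construct a disease-gene annotation object
#'
#' Container for gene-to-disease assignments with supporting PMIDs.
#' Duplicate (gene, disease) pairs are merged, with PMID sets unioned;
#' the first non-empty disease name seen for a disease id is kept.
#'
#' @param records Data frame with columns `gene`, `disease_id`,
#'   `disease_name` and optionally `pmids` (`;`-separated string).
#' @return An object of class `disease_annotation`: a data frame of
#'   deduplicated records, one row per (gene, disease) pair, ordered by
#'   gene then disease id.
#' @export
disease_annotation <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"pmids" %in% names(records)) records$pmids <- ""
  records$gene <- trimws(as.character(records$gene))
  records$disease_id <- trimws(as.character(records$disease_id))
  records$disease_name <- as.character(records$disease_name)
  records$pmids <- as.character(records$pmids)
  records$pmids[is.na(records$pmids)] <- ""

  key <- paste(records$gene, records$disease_id, sep = "\r")
  merged_pmids <- vapply(split(records$pmids, key), function(p) {
    ids <- unique(unlist(strsplit(p, ";", fixed = TRUE)))
    ids <- sort(ids[nzchar(trimws(ids))])
    paste(ids, collapse = ";")
  }, character(1))
  first <- !duplicated(key)
  out <- records[first, c("gene", "disease_id", "disease_name")]
  out$pmids <- unname(merged_pmids[key[first]])
  out <- out[order(out$gene, out$disease_id), ]
  rownames(out) <- NULL
  structure(out, class = c("disease_annotation", "data.frame"))
}

#' @exportS3Method base::print
print.disease_annotation <- function(x, ...) {
  cat("disease_annotation: ", nrow(x), " gene-disease pairs, ",
      length(disease_genes(x)), " genes, ",
      length(unique(x$disease_id)), " diseases\n", sep = "")
  invisible(x)
}

#' Genes carrying at least one disease annotation
#'
#' @param annotation A `disease_annotation`.
#' @return Character vector of distinct annotated gene symbols.
#' @export
disease_genes <- function(annotation) {
  unique(annotation$gene)
}

#' Number of distinct diseases annotated to each gene
#'
#' @param annotation A `disease_annotation`.
#' @param genes Genes to report on; defaults to all annotated genes.
#'   Genes without annotation get count 0.
#' @return Named integer vector of distinct-disease counts.
#' @export
disease_count <- function(annotation, genes = disease_genes(annotation)) {
  tab <- table(annotation$gene)
  counts <- as.integer(tab[genes])
  counts[is.na(counts)] <- 0L
  names(counts) <- genes
  counts
}

#' Write a disease annotation table as TSV
#'
#' @param annotation A `disease_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Global summary statistics of an interaction network
#'
#' Reports node and edge counts, the mean neighbor count (2E/N on a
#' simple graph), the diameter (maximum eccentricity over the largest
#' connected component), the characteristic path length (mean
#' shortest-path distance over all connected pairs) and the number of
#' connected components. On an edgeless network the diameter and path
#' length are reported as 0 with a warning.
#'
#' @param net An `igraph` graph.
#' @return A list of class `network_summary` with fields `node_count`,
#'   `edge_count`, `mean_neighbor_count`, `diameter`,
#'   `characteristic_path_length` and `component_count`.
#' @export
network_summary <- function(net) {
  stopifnot(igraph::vcount(net) >= 1)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  comps <- igraph::components(net)
  if (m == 0) {
    warning("network has no edges; diameter and path length undefined, ",
            "reported as 0")
    diam <- 0L
    cpl <- 0
  } else {
    largest <- which(comps$membership == which.max(comps$csize))
    sub <- igraph::induced_subgraph(net, largest)
    diam <- as.integer(igraph::diameter(sub, unconnected = FALSE))
    cpl <- igraph::mean_distance(net, unconnected = TRUE)
  }
  structure(list(
    node_count = n,
    edge_count = m,
    mean_neighbor_count = if (n > 0) 2 * m / n else 0,
    diameter = diam,
    characteristic_path_length = cpl,
    component_count = comps$no
  ), class = "network_summary")
}

#' @exportS3Method base::print
print.network_summary <- function(x, ...) {
  cat("network_summary\n",
      "  nodes: ", x$node_count, "  edges: ", x$edge_count, "\n",
      "  mean neighbors: ", round(x$mean_neighbor_count, 2), "\n",
      "  diameter: ", x$diameter,
      "  characteristic path length: ",
      round(x$characteristic_path_length, 2), "\n",
      "  components: ", x$component_count, "\n", sep = "")
  invisible(x)
}

#' Serialize a network summary to JSON
#'
#' @param x A `network_summary`.
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
network_summary_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
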