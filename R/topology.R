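#' Canonical feature order
#'
#' The ten per-protein features used throughout the package, in the
#' fixed column order of every feature table: nine topological measures
#' plus the disease neighbor ratio.
#'
#' @return Character vector of feature names.
#' @export
adnet_features <- function() {
  c("degree", "closeness", "betweenness", "stress", "eccentricity",
    "radiality", "neighborhood_connectivity", "topological_coefficient",
    "clustering_coefficient", "dnr")
}

#' Disease neighbor ratio
#'
#' For each protein, the fraction of its direct interaction partners
#' that carry a disease annotation:
#' \deqn{DNR_i = n_{disease}(i) / \sum_j A_{ij}}
#' where the denominator is the degree of protein \eqn{i}. Isolated
#' proteins (degree 0) get a ratio of 0, since no disease neighbor is
#' observable there.
#'
#' @param net An `igraph` interaction network with named vertices.
#' @param disease_genes Character vector of disease-annotated gene
#'   symbols; members absent from the network are ignored.
#' @return Named numeric vector in `[0, 1]`, one entry per network
#'   protein.
#' @export
disease_neighbor_ratio <- function(net, disease_genes) {
  nodes <- igraph::V(net)$name
  flag <- as.numeric(nodes %in% disease_genes)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  n_dis <- as.numeric(A %*% flag)
  deg <- igraph::degree(net)
  dnr <- ifelse(deg > 0, n_dis / deg, 0)
  names(dnr) <- nodes
  dnr
}

#' Shortest-path centrality features
#'
#' Computes the five distance-based features for every protein:
#' eccentricity (maximum distance to any reachable protein), closeness
#' (reciprocal of the mean distance to reachable proteins), radiality
#' (`(D_c + 1 - mean distance) / D_c` with `D_c` the diameter of the
#' protein's connected component), betweenness (Brandes pair-dependency
#' accumulation, unnormalized, each unordered pair counted once) and
#' stress (number of shortest paths between other protein pairs passing
#' through the protein). Isolated proteins score 0 on all five.
#'
#' @param net An `igraph` interaction network.
#' @return Data frame with columns `protein`, `eccentricity`,
#'   `closeness`, `radiality`, `betweenness`, `stress`, one row per
#'   protein in vertex order.
#' @export
shortest_path_features <- function(net) {
  nodes <- igraph::V(net)$name
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  stats <- .cpp_sp_stats(matrix(as.integer(el - 1L), ncol = 2), n)

  comp <- igraph::components(net)$membership
  # eccentricity is computed within the component, so the component
  # diameter is the max eccentricity among its members
  comp_diam <- tapply(stats$eccentricity, comp, max)[as.character(comp)]

  reach <- stats$reach
  mean_dist <- ifelse(reach > 0, stats$sum_dist / reach, 0)
  closeness <- ifelse(reach > 0, 1 / mean_dist, 0)
  radiality <- ifelse(reach > 0 & comp_diam > 0,
                      (comp_diam + 1 - mean_dist) / comp_diam, 0)

  data.frame(protein = nodes,
             eccentricity = as.integer(stats$eccentricity),
             closeness = closeness,
             radiality = as.numeric(radiality),
             betweenness = stats$betweenness,
             stress = stats$stress,
             stringsAsFactors = FALSE)
}

#' Neighborhood-based local features
#'
#' Computes, for every protein: neighborhood connectivity (mean degree
#' of its direct neighbors), clustering coefficient
#' (`2 e_N / (k (k - 1))` with `e_N` the number of interactions among
#' its `k` neighbors; 0 for `k < 2`) and the topological coefficient.
#'
#' The topological coefficient of protein `v` with `k >= 2` neighbors is
#' the mean of `J(v, m) / k` over all partner proteins `m`: the proteins
#' sharing at least one neighbor with `v` together with `v`'s direct
#' neighbors, where `J(v, m)` is the number of shared neighbors plus 1
#' when `v` and `m` interact directly. Proteins with fewer than two
#' neighbors get 0.
#'
#' @param net An `igraph` interaction network.
#' @return Data frame with columns `protein`,
#'   `neighborhood_connectivity`, `topological_coefficient`,
#'   `clustering_coefficient`, one row per protein in vertex order.
#' @export
local_features <- function(net) {
  nodes <- igraph::V(net)$name
  deg <- igraph::degree(net)

  nc <- rep(0, length(nodes))
  if (igraph::ecount(net) > 0) {
    knn <- igraph::knn(net)$knn
    nc[deg > 0] <- knn[deg > 0]
  }

  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  cc[deg < 2] <- 0

  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  S <- A %*% A            # shared-neighbor counts
  M <- S + A              # J values; nonzero pattern = partner set
  Matrix::diag(M) <- 0
  M <- Matrix::drop0(M)
  j_sum <- Matrix::rowSums(M)
  n_partner <- Matrix::rowSums(M != 0)
  tc <- ifelse(deg >= 2 & n_partner > 0, j_sum / (n_partner * deg), 0)

  data.frame(protein = nodes,
             neighborhood_connectivity = as.numeric(nc),
             topological_coefficient = as.numeric(tc),
             clustering_coefficient = as.numeric(cc),
             stringsAsFactors = FALSE)
}

#' Build the per-protein feature table
#'
#' Computes all ten features on the full network and attaches class
#' labels from the disease annotation: `positive` when a protein has at
#' least `k_min` distinct disease annotations, `negative` when it has
#' none, and `excluded` in between (weak positives are dropped from
#' training rather than relabeled). By default the disease neighbor
#' ratio is computed from the full annotation's gene set, matching the
#' single up-front feature computation of the original protocol; pass
#' `dnr_genes` to restrict the DNR to a chosen gene set (for example the
#' positives of a training fold in leakage-strict cross-validation).
#'
#' @param net An `igraph` interaction network with named vertices.
#' @param annotation A `disease_annotation`, or `NULL` for an
#'   unannotated table (all labels `negative`, all DNR 0).
#' @param k_min Minimum number of distinct diseases for the positive
#'   class (default 1).
#' @param dnr_genes Optional character vector overriding the gene set
#'   that counts as "disease" in the DNR.
#' @return A `feature_table`: data frame with columns `protein`, the
#'   ten features in the [adnet_features()] order, `n_diseases` and
#'   `label`, rows ordered lexicographically by protein id.
#' @export
build_feature_table <- function(net, annotation = NULL, k_min = 1,
                                dnr_genes = NULL) {
  nodes <- igraph::V(net)$name
  if (is.null(dnr_genes)) {
    dnr_genes <- if (is.null(annotation)) character(0) else
      disease_genes(annotation)
  }
  sp <- shortest_path_features(net)
  loc <- local_features(net)
  dnr <- disease_neighbor_ratio(net, dnr_genes)

  n_dis <- if (is.null(annotation)) {
    stats::setNames(integer(length(nodes)), nodes)
  } else {
    disease_count(annotation, nodes)
  }

  ft <- data.frame(
    protein = nodes,
    degree = as.integer(igraph::degree(net)),
    closeness = sp$closeness,
    betweenness = sp$betweenness,
    stress = sp$stress,
    eccentricity = sp$eccentricity,
    radiality = sp$radiality,
    neighborhood_connectivity = loc$neighborhood_connectivity,
    topological_coefficient = loc$topological_coefficient,
    clustering_coefficient = loc$clustering_coefficient,
    dnr = as.numeric(dnr),
    n_diseases = as.integer(n_dis),
    stringsAsFactors = FALSE
  )
  ft$label <- label_from_counts(ft$n_diseases, k_min)
  ft <- ft[order(ft$protein, method = "radix"), ]
  rownames(ft) <- NULL
  structure(ft, k_min = k_min, class = c("feature_table", "data.frame"))
}

label_from_counts <- function(n_diseases, k_min) {
  if (k_min < 1) stop("k_min must be >= 1", call. = FALSE)
  ifelse(n_diseases >= k_min, "positive",
         ifelse(n_diseases == 0, "negative", "excluded"))
}

#' Write a feature table as CSV
#'
#' @param ft A `feature_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature table in ARFF format
#'
#' Emits the Weka-style attribute-relation format used by many
#' attribute-selection tools; `excluded` rows are written too, so the
#' consumer decides how to filter.
#'
#' @param ft A `feature_table`.
#' @param path Output file path.
#' @param relation Relation name in the ARFF header.
#' @return `path`, invisibly.
#' @export
write_feature_arff <- function(ft, path, relation = "adnet_features") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@RELATION ", relation), con)
  for (f in adnet_features()) {
    writeLines(paste0("@ATTRIBUTE ", f, " NUMERIC"), con)
  }
  writeLines("@ATTRIBUTE class {positive,negative,excluded}", con)
  writeLines("@DATA", con)
  rows <- apply(ft[, adnet_features(), drop = FALSE], 1,
                paste, collapse = ",")
  writeLines(paste(rows, ft$label, sep = ","), con)
  invisible(path)
}
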