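# Independent brute-force oracles for the topological features. These
# work from first principles on adjacency lists (BFS distance layers and
# direct shortest-path counting) and deliberately share no code with the
# package implementation.

oracle_adj <- function(net) {
  lapply(igraph::as_adj_list(net), as.integer)
}

# single-source BFS: distances (-1 unreachable)
oracle_bfs <- function(adj, s) {
  n <- length(adj)
  dist <- rep(-1L, n)
  dist[s] <- 0L
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# number of shortest paths between every pair, by layer-wise counting
oracle_sigma <- function(adj, dist_mat) {
  n <- length(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- dist_mat[s, ]
    sigma[s, s] <- 1
    reach <- which(d > 0)
    for (v in reach[order(d[reach])]) {
      preds <- adj[[v]][d[adj[[v]]] == d[v] - 1L]
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  sigma
}

# all ten features by enumeration; returns a data.frame in vertex order
oracle_features <- function(net, disease_genes = character(0)) {
  adj <- oracle_adj(net)
  n <- length(adj)
  nodes <- igraph::V(net)$name
  dist_mat <- do.call(rbind, lapply(seq_len(n), oracle_bfs, adj = adj))
  sigma <- oracle_sigma(adj, dist_mat)
  deg <- lengths(adj)

  ecc <- apply(dist_mat, 1, max)        # within component: -1 < any d
  closeness <- radiality <- numeric(n)
  comp <- igraph::components(net)$membership
  for (v in seq_len(n)) {
    reach <- which(dist_mat[v, ] >= 0)
    reach <- setdiff(reach, v)
    if (length(reach) == 0) next
    md <- mean(dist_mat[v, reach])
    closeness[v] <- 1 / md
    cd <- max(ecc[comp == comp[v]])
    if (cd > 0) radiality[v] <- (cd + 1 - md) / cd
  }

  betweenness <- stress <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (dist_mat[s, t] <= 1) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (dist_mat[s, v] >= 0 && dist_mat[v, t] >= 0 &&
          dist_mat[s, v] + dist_mat[v, t] == dist_mat[s, t]) {
        through <- sigma[s, v] * sigma[v, t]
        stress[v] <- stress[v] + through
        betweenness[v] <- betweenness[v] + through / sigma[s, t]
      }
    }
  }

  nc <- tc <- cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k > 0) nc[v] <- mean(deg[nb])
    if (k >= 2) {
      e_nb <- 0
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        if (nb[j] %in% adj[[nb[i]]]) e_nb <- e_nb + 1
      }
      cc[v] <- 2 * e_nb / (k * (k - 1))
      # partners: nodes sharing >= 1 neighbor with v, plus neighbors
      j_vals <- c()
      for (m in seq_len(n)) {
        if (m == v) next
        shared <- length(intersect(adj[[v]], adj[[m]]))
        direct <- m %in% adj[[v]]
        if (shared >= 1 || direct) {
          j_vals <- c(j_vals, shared + as.integer(direct))
        }
      }
      if (length(j_vals) > 0) tc[v] <- mean(j_vals / k)
    }
  }

  dnr <- numeric(n)
  flag <- nodes %in% disease_genes
  for (v in seq_len(n)) {
    if (deg[v] > 0) dnr[v] <- sum(flag[adj[[v]]]) / deg[v]
  }

  data.frame(protein = nodes, degree = as.numeric(deg),
             closeness = closeness, betweenness = betweenness,
             stress = stress, eccentricity = as.numeric(ecc),
             radiality = radiality, neighborhood_connectivity = nc,
             topological_coefficient = tc, clustering_coefficient = cc,
             dnr = dnr, stringsAsFactors = FALSE)
}

# random simple graph with named vertices (guaranteed >= 1 edge)
random_test_graph <- function(n, p = 0.2) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# tie-corrected Mann-Whitney AUC from ranks: an independent route to
# the area under the ROC curve
mann_whitney_auc <- function(scores, labels) {
  pos <- labels == "positive"
  r <- rank(scores)               # midranks on ties
  np <- sum(pos)
  nn <- sum(!pos)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}
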