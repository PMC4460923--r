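star <- function(k) {
  g <- igraph::make_star(k + 1, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("hub", paste0("leaf", seq_len(k)))
  g
}

test_that("disease neighbor ratio counts annotated interaction partners", {
  g <- star(4)
  expect_equal(unname(disease_neighbor_ratio(g, character(0))["hub"]), 0)
  expect_equal(unname(disease_neighbor_ratio(
    g, paste0("leaf", 1:4))["hub"]), 1)

  g2 <- igraph::make_graph(~ v - a, v - b, v - c)
  expect_equal(unname(disease_neighbor_ratio(g2, "a")["v"]), 1 / 3)
  # non-network genes are ignored
  expect_equal(unname(disease_neighbor_ratio(g2, c("a", "zzz"))["v"]),
               1 / 3)
})

test_that("isolated proteins get zero for every distance-based feature", {
  g <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(g)$name <- c("solo1", "solo2")
  sp <- shortest_path_features(g)
  expect_true(all(sp[, -1] == 0))
  expect_equal(unname(disease_neighbor_ratio(g, "solo2")["solo1"]), 0)
})

test_that("path and cycle centralities match hand-derived values", {
  p3 <- igraph::make_graph(~ A - B, B - C)
  sp <- shortest_path_features(p3)
  rownames(sp) <- sp$protein
  expect_equal(sp["B", "betweenness"], 1)
  expect_equal(sp["B", "stress"], 1)
  expect_equal(sp["A", "eccentricity"], 2L)
  expect_equal(sp["B", "eccentricity"], 1L)

  cyc <- igraph::make_ring(4)
  igraph::V(cyc)$name <- letters[1:4]
  sp4 <- shortest_path_features(cyc)
  expect_equal(sp4$betweenness, rep(0.5, 4))
  expect_equal(sp4$stress, rep(1, 4))
})

test_that("local features match hand-derived values on triangle and star", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  lf <- local_features(tri)
  expect_equal(lf$clustering_coefficient, rep(1, 3))
  expect_equal(lf$neighborhood_connectivity, rep(2, 3))

  s4 <- star(4)
  lf2 <- local_features(s4)
  rownames(lf2) <- lf2$protein
  expect_equal(lf2["hub", "clustering_coefficient"], 0)
  expect_equal(lf2["hub", "neighborhood_connectivity"], 1)
  # degree-1 leaves: the coefficient is defined as 0
  expect_equal(lf2["leaf1", "topological_coefficient"], 0)
})

test_that("every feature agrees with the brute-force oracle", {
  set.seed(11)
  for (i in 1:12) {
    g <- random_test_graph(sample(8:20, 1), runif(1, 0.12, 0.35))
    dg <- sample(igraph::V(g)$name, 4)
    got <- build_feature_table(g, NULL, dnr_genes = dg)
    want <- oracle_features(g, dg)
    want <- want[order(want$protein, method = "radix"), ]
    for (f in c("degree", "stress", "eccentricity")) {
      expect_equal(got[[f]], want[[f]], tolerance = 0,
                   label = paste("feature", f))
    }
    for (f in c("closeness", "betweenness", "radiality",
                "neighborhood_connectivity", "topological_coefficient",
                "clustering_coefficient", "dnr")) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9,
                   label = paste("feature", f))
    }
  }
})

test_that("adding a disease neighbor strictly increases the ratio", {
  set.seed(7)
  for (i in 1:10) {
    g <- random_test_graph(12, 0.3)
    v <- sample(igraph::V(g)$name[igraph::degree(g) > 0], 1)
    nbs <- igraph::V(g)$name[as.integer(igraph::neighbors(g, v))]
    dg <- sample(setdiff(igraph::V(g)$name, c(v, nbs[1])),
                 sample(3, 1))
    before <- disease_neighbor_ratio(g, dg)[v]
    after <- disease_neighbor_ratio(g, union(dg, nbs[1]))[v]
    expect_gt(after, before)
    # relabeling a non-neighbor never changes the ratio
    other <- setdiff(igraph::V(g)$name, c(v, nbs, dg))
    if (length(other) > 0) {
      expect_equal(unname(disease_neighbor_ratio(
        g, union(dg, other[1]))[v]), unname(before))
    }
  }
})

test_that("feature table labels, order and DNR follow the annotation", {
  p3 <- igraph::make_graph(~ C - B, B - A)   # deliberately unsorted
  ann <- disease_annotation(data.frame(
    gene = "B", disease_id = "D1", disease_name = "x", pmids = "1"))
  ft <- build_feature_table(p3, ann, k_min = 1)
  expect_equal(ft$protein, c("A", "B", "C"))  # lexicographic rows
  expect_equal(ft$dnr, c(1, 0, 1))
  expect_equal(ft$label, c("negative", "positive", "negative"))
  expect_equal(colnames(ft)[2:11], adnet_features())

  ft0 <- build_feature_table(p3, NULL)
  expect_true(all(ft0$dnr == 0))
  expect_true(all(ft0$label == "negative"))
})

test_that("total stress equals the oracle's path-through-vertex count", {
  set.seed(3)
  g <- random_test_graph(15, 0.25)
  got <- shortest_path_features(g)
  want <- oracle_features(g)
  expect_equal(sum(got$stress), sum(want$stress))
})
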