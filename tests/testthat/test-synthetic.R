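test_that("identical configs and seeds reproduce identical scenarios", {
  cfg <- scenario_config(n_nodes = 300, module_walk_length = 12,
                         hidden_gene_count = 2, seed = 42)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_identical(igraph::as_edgelist(s1$net),
                   igraph::as_edgelist(s2$net))
  expect_identical(as.data.frame(s1$annotation),
                   as.data.frame(s2$annotation))
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("the attachment process yields the expected edge count", {
  cfg <- scenario_config(n_nodes = 1000, attachment_edges_per_node = 4,
                         seed = 1)
  g <- generate_network(cfg)
  expect_equal(igraph::vcount(g), 1000)
  # growth rule: m edges per new node, fewer while < m nodes exist
  expect_equal(igraph::ecount(g), 1000 * 4 - 4 * 5 / 2)
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
})

test_that("generated degree distributions are heavy-tailed", {
  for (s in 1:5) {
    g <- generate_network(scenario_config(n_nodes = 1000, seed = s))
    deg <- igraph::degree(g)
    expect_gt(max(deg), 5 * mean(deg))
  }
})

test_that("the generator hits its coverage and multiplicity targets", {
  for (s in 1:3) {
    sc <- generate_scenario(scenario_config(
      n_nodes = 800, module_walk_length = 25, seed = s))
    frac <- length(disease_genes(sc$annotation)) / 800
    expect_lt(abs(sc$stats$disease_fraction - 0.32), 0.02 + 1e-9)
    expect_lt(abs(sc$stats$mean_diseases_per_positive - 4.3), 0.3 + 1e-9)
    # stats describe the pre-noise annotation; with the default zero
    # noise they match the emitted file exactly
    expect_equal(frac, sc$stats$disease_fraction)
    counts <- disease_count(sc$annotation)
    expect_equal(mean(counts), sc$stats$mean_diseases_per_positive)
  }
})

test_that("an infeasible coverage target is rejected", {
  expect_error(scenario_config(disease_fraction_target = 1.5))
  expect_error(
    generate_scenario(scenario_config(
      n_nodes = 300, n_diseases = 2, module_walk_length = 5, seed = 1)),
    "catalog exhausted")
})

test_that("modular annotation raises positive DNR; noise removes it", {
  gaps <- vapply(1:3, function(s) {
    vapply(c(0, 1), function(nf) {
      sc <- generate_scenario(scenario_config(
        n_nodes = 800, module_walk_length = 25, noise_fraction = nf,
        seed = s))
      ft <- build_feature_table(sc$net, sc$annotation)
      m <- tapply(ft$dnr, ft$label, mean)
      m[["positive"]] - m[["negative"]]
    }, numeric(1))
  }, numeric(2))
  expect_gt(mean(gaps[1, ]), 0.1)       # modular: clear DNR elevation
  expect_lt(abs(mean(gaps[2, ])), 0.05) # fully random: no elevation
})

test_that("hidden genes are withheld and reported as ground truth", {
  sc <- generate_scenario(scenario_config(
    n_nodes = 600, module_walk_length = 20, hidden_gene_count = 5,
    seed = 10))
  expect_equal(nrow(sc$ground_truth), 5)
  expect_length(intersect(sc$ground_truth$gene,
                          disease_genes(sc$annotation)), 0)
  expect_true(all(sc$ground_truth$n_diseases_removed >= 2))
  expect_true(all(sc$ground_truth$planted_disease %in%
                    sc$annotation$disease_id))
})

test_that("scenario files round-trip through the standard readers", {
  sc <- generate_scenario(scenario_config(
    n_nodes = 300, module_walk_length = 12, hidden_gene_count = 2,
    seed = 11))
  dir <- tempfile("scen_")
  write_scenario(sc, dir)
  g <- suppressMessages(read_edge_list(file.path(dir, "edges.tsv")))
  expect_equal(igraph::ecount(g), igraph::ecount(sc$net))
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  expect_equal(as.data.frame(ann), as.data.frame(sc$annotation))
  meta <- jsonlite::fromJSON(file.path(dir, "scenario.json"))
  expect_equal(meta$config$seed, 11)
  # the emitted annotation never contains the withheld genes
  expect_length(intersect(meta$ground_truth$gene, ann$gene), 0)
})

test_that("presets cover the four study conditions", {
  ps <- preset_scenarios(seed = 3)
  expect_named(ps, c("paperlike", "null", "strong_signal",
                     "hidden_genes"))
  expect_equal(ps$paperlike$disease_fraction_target, 0.32)
  expect_equal(ps$paperlike$mean_diseases_per_positive, 4.3)
  expect_equal(ps$null$noise_fraction, 1)
  expect_equal(ps$hidden_genes$hidden_gene_count, 5)
  expect_equal(ps$strong_signal$noise_fraction, 0)
  expect_true(all(vapply(ps, function(p) p$seed, numeric(1)) == 3))
})
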