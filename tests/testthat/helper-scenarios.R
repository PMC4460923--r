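# Labeled datasets for the preset scenarios are reused across test
# files; building one costs a full feature-table computation on a
# 2000-protein network, so they are cached per (scenario, seed).
.scenario_cache <- new.env(parent = emptyenv())

scenario_run <- function(name, seed) {
  key <- paste(name, seed, sep = "#")
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  sc <- generate_scenario(name, seed = seed)
  ds <- build_dataset(sc$net, sc$annotation, k_min = 1)
  run <- list(net = sc$net, annotation = sc$annotation,
              ground_truth = sc$ground_truth, dataset = ds)
  .scenario_cache[[key]] <- run
  run
}

# fraction of hidden ground-truth genes found in the top decile of the
# negative class by full-model confidence score
hidden_recovered <- function(run, n_iterations = 20) {
  model <- train_adtree(run$dataset, n_iterations = n_iterations)
  rows <- adnet:::training_rows(run$dataset)
  scores <- adtree_score(model, rows)
  neg <- rows$label == "negative"
  cutoff <- ceiling(sum(neg) / 10)
  top <- rows$protein[neg][rank(-scores[neg],
                                ties.method = "min") <= cutoff]
  sum(run$ground_truth$gene %in% top)
}
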