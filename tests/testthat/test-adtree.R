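test_that("the root prediction value is the log class-weight ratio", {
  bal <- toy_dataset(4, 4, seed = 1)
  m <- train_adtree(bal, n_iterations = 0, features = "f1")
  expect_equal(m$root_value, 0)
  expect_equal(adtree_score(m, bal), rep(0, 8))
  expect_equal(predict(m, bal, type = "class"), rep("negative", 8))

  skew <- toy_dataset(3, 1, seed = 1)
  m2 <- train_adtree(skew, n_iterations = 0, features = "f1")
  expect_equal(m2$root_value, 0.5 * log(3))
})

test_that("single-class training data is rejected", {
  d <- toy_dataset(5, 0, seed = 1)
  expect_error(train_adtree(d, 1, features = "f1"), "both classes")
})

test_that("the attribute comparison is inclusive at the threshold", {
  model <- structure(list(
    root_value = 0.1,
    rules = data.frame(index = 1L, precondition = 0L, attribute = "attr",
                       threshold = 2, a_true = 0.4, a_false = -0.2,
                       stringsAsFactors = FALSE),
    n_iterations = 1L, epsilon = 1, features = "attr",
    total_weight = NULL, seed = NULL), class = "adtree")
  expect_equal(adtree_score(model, data.frame(attr = 2)), 0.5)
  expect_equal(adtree_score(model, data.frame(attr = 2 - 1e-9)), -0.1)
})

test_that("scoring requires every attribute the model uses", {
  d <- toy_dataset(6, 6, p = 2, seed = 2)
  m <- train_adtree(d, 2, features = c("f1", "f2"))
  expect_error(adtree_score(m, d[, c("protein", "f1")]), "f2")
})

test_that("each boosting iteration matches the exhaustive Z oracle", {
  cases <- list(list(np = 4, nn = 4, p = 1, iters = 3, seed = 31),
                list(np = 6, nn = 6, p = 2, iters = 4, seed = 32),
                list(np = 12, nn = 8, p = 2, iters = 5, seed = 33))
  for (cs in cases) {
    d <- toy_dataset(cs$np, cs$nn, p = cs$p, seed = cs$seed)
    feats <- paste0("f", seq_len(cs$p))
    m <- train_adtree(d, cs$iters, features = feats)
    X <- as.matrix(d[, feats, drop = FALSE])
    colnames(X) <- feats
    o <- oracle_train_adtree(X, ifelse(d$label == "positive", 1, -1),
                             cs$iters)
    expect_equal(m$root_value, o$root_value)
    expect_equal(nrow(m$rules), length(o$rules))
    for (j in seq_along(o$rules)) {
      expect_equal(m$rules$precondition[j], o$rules[[j]]$node)
      expect_equal(m$rules$attribute[j], o$rules[[j]]$attribute)
      expect_equal(m$rules$threshold[j], o$rules[[j]]$threshold)
      expect_equal(m$rules$a_true[j], o$rules[[j]]$a_true)
      expect_equal(m$rules$a_false[j], o$rules[[j]]$a_false)
    }
    expect_equal(m$total_weight, o$total_weight)
  }
})

test_that("total instance weight never increases across iterations", {
  for (seed in 41:44) {
    d <- toy_dataset(10, 10, p = 2, seed = seed)
    m <- train_adtree(d, 8, features = c("f1", "f2"))
    expect_true(all(diff(m$total_weight) <= 1e-12))
  }
})

test_that("training error is non-increasing in the iteration count", {
  d <- toy_dataset(12, 12, p = 2, seed = 51)
  errs <- vapply(c(0, 1, 2, 4, 8, 12), function(it) {
    m <- train_adtree(d, it, features = c("f1", "f2"))
    mean((adtree_score(m, d) > 0) != (d$label == "positive"))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("flipping the class labels negates the learned scores", {
  d <- toy_dataset(9, 7, p = 2, seed = 61)
  flipped <- d
  flipped$label <- ifelse(d$label == "positive", "negative", "positive")
  m1 <- train_adtree(d, 5, features = c("f1", "f2"))
  m2 <- train_adtree(flipped, 5, features = c("f1", "f2"))
  expect_equal(adtree_score(m1, d), -adtree_score(m2, d),
               tolerance = 1e-12)
})

test_that("the additive score equals an independent path-walker", {
  sc <- generate_scenario(scenario_config(
    n_nodes = 300, module_walk_length = 12, seed = 3))
  ds <- build_dataset(sc$net, sc$annotation, 1)
  m <- train_adtree(ds, 20)
  expect_equal(nrow(m$rules), 20)
  idx <- seq(1, nrow(ds), by = 17)
  fast <- adtree_score(m, ds[idx, ])
  slow <- vapply(idx, function(i) oracle_score_one(m, ds[i, ]),
                 numeric(1))
  expect_equal(fast, slow)
})

test_that("models survive a JSON round trip bit-identically", {
  d <- toy_dataset(10, 10, p = 2, seed = 71)
  m <- train_adtree(d, 6, features = c("f1", "f2"), seed = 9L)
  m2 <- deserialize_adtree(serialize_adtree(m))
  expect_identical(m2$root_value, m$root_value)
  expect_identical(m2$rules$threshold, m$rules$threshold)
  expect_identical(m2$rules$a_true, m$rules$a_true)
  expect_identical(m2$rules$a_false, m$rules$a_false)
  expect_identical(m2$rules$precondition, m$rules$precondition)
  expect_identical(adtree_score(m2, d), adtree_score(m, d))

  f <- tempfile(fileext = ".json")
  serialize_adtree(m, f)
  expect_identical(deserialize_adtree(f)$rules$threshold,
                   m$rules$threshold)

  m0 <- train_adtree(d, 0, features = "f1")
  expect_identical(deserialize_adtree(serialize_adtree(m0))$root_value,
                   m0$root_value)
})

test_that("a dangling precondition is rejected on deserialization", {
  d <- toy_dataset(8, 8, seed = 81)
  m <- train_adtree(d, 2, features = "f1")
  bad <- jsonlite::fromJSON(serialize_adtree(m))
  bad$rules$precondition[2] <- 7L  # rule 2 may reference at most node 2
  expect_error(deserialize_adtree(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "dangling precondition")
})
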