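test_that("ROC handles perfect separation and constant scores", {
  r <- roc_curve(c(2, 1, 0, -1),
                 c("positive", "positive", "negative", "negative"))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(utils::tail(r$points$tpr, 1), 1)

  r2 <- roc_curve(rep(0.3, 6), rep(c("positive", "negative"), 3))
  expect_equal(r2$auc, 0.5)
  expect_equal(nrow(r2$points), 2)  # (0,0) then the single tie group
})

test_that("degenerate or malformed score vectors are rejected", {
  expect_error(roc_curve(1:3, rep("positive", 3)), "both classes")
  expect_error(roc_curve(c(1, NA), c("positive", "negative")), "finite")
})

test_that("ROC points are monotone and anchored at both corners", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    scores <- sample(round(rnorm(n), 1))  # coarse: force ties
    labels <- sample(c("positive", "negative"), n, TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_curve(scores, labels)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(utils::tail(r$points$fpr, 1), 1)
    expect_equal(utils::tail(r$points$tpr, 1), 1)
  }
})

test_that("trapezoid AUC equals the tie-corrected rank statistic", {
  set.seed(22)
  for (i in 1:25) {
    n <- sample(8:80, 1)
    scores <- round(rnorm(n), sample(0:2, 1))
    labels <- sample(c("positive", "negative"), n, TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_curve(scores, labels)$auc,
                 mann_whitney_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("the ROC curve is invariant under monotone score transforms", {
  set.seed(23)
  scores <- rnorm(40)
  labels <- sample(c("positive", "negative"), 40, TRUE)
  r1 <- roc_curve(scores, labels)
  r2 <- roc_curve(exp(2 * scores), labels)
  r3 <- roc_curve(rank(scores, ties.method = "average"), labels)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_equal(r1$auc, r3$auc, tolerance = 1e-12)
  expect_equal(r1$points[, c("fpr", "tpr")], r2$points[, c("fpr", "tpr")])
})

test_that("stratified folds partition the data with balanced classes", {
  d <- toy_dataset(10, 10, p = 1, seed = 24)
  cv <- cross_validate(d, folds = 10, n_iterations = 1, seed = 3,
                       features = "f1")
  expect_equal(sort(cv$protein), sort(d$protein))  # scored exactly once
  per_fold <- table(cv$fold, cv$label)
  expect_true(all(per_fold == 1))  # 10+10 over 10 folds, stratified

  d2 <- toy_dataset(12, 20, p = 1, seed = 25)
  cv2 <- cross_validate(d2, folds = 4, n_iterations = 1, seed = 3,
                        features = "f1")
  balance <- table(cv2$fold, cv2$label)
  expect_true(all(balance[, "positive"] == 3))
  expect_true(all(balance[, "negative"] == 5))
})

test_that("cross-validation is deterministic given the seed", {
  d <- toy_dataset(15, 15, p = 2, seed = 26)
  cv1 <- cross_validate(d, folds = 5, n_iterations = 3, seed = 11,
                        features = c("f1", "f2"))
  cv2 <- cross_validate(d, folds = 5, n_iterations = 3, seed = 11,
                        features = c("f1", "f2"))
  expect_identical(cv1, cv2)
  cv3 <- cross_validate(d, folds = 5, n_iterations = 3, seed = 12,
                        features = c("f1", "f2"))
  expect_false(identical(cv1$protein, cv3$protein))
})

test_that("a class smaller than the fold count is refused", {
  d <- toy_dataset(4, 20, p = 1, seed = 27)
  expect_error(cross_validate(d, folds = 10, features = "f1"),
               "fewer folds")
})

test_that("labels independent of features give chance-level AUC", {
  set.seed(28)
  aucs <- vapply(1:8, function(i) {
    d <- data.frame(protein = sprintf("P%03d", 1:120),
                    f1 = rnorm(120), f2 = rnorm(120),
                    label = rep(c("positive", "negative"), 60))
    cv <- cross_validate(d, folds = 5, n_iterations = 5, seed = i,
                         features = c("f1", "f2"))
    roc_curve(cv$score, cv$label)$auc
  }, numeric(1))
  # binomial-ish SE of an AUC on 60/60 instances is about 0.053
  expect_lt(abs(mean(aucs) - 0.5), 3 * 0.053 / sqrt(8))
})

test_that("strict DNR mode recomputes the ratio inside each fold", {
  sc <- generate_scenario(scenario_config(
    n_nodes = 300, module_walk_length = 12, seed = 4))
  ds <- build_dataset(sc$net, sc$annotation, 1)
  cv_leaky <- cross_validate(ds, folds = 5, n_iterations = 5, seed = 2)
  cv_strict <- cross_validate(ds, folds = 5, n_iterations = 5, seed = 2,
                              dnr_strict = TRUE, net = sc$net)
  expect_false(identical(cv_leaky$score, cv_strict$score))
  expect_error(cross_validate(ds, folds = 5, dnr_strict = TRUE),
               "network")
})

test_that("the threshold series evaluates every requested cutoff", {
  sc <- generate_scenario(scenario_config(
    n_nodes = 500, module_walk_length = 18, seed = 6))
  ts <- threshold_series(sc$net, sc$annotation, k_values = 1:3,
                         folds = 4, n_iterations = 5, seed = 1)
  expect_equal(ts$k_min, 1:3)
  expect_true(all(diff(ts$n_pos) < 0))
  expect_true(all(ts$n_neg == ts$n_neg[1]))
  expect_true(all(ts$auc > 0 & ts$auc < 1))
})

test_that("ablation reports deltas against the all-feature baseline", {
  sc <- generate_scenario(scenario_config(
    n_nodes = 300, module_walk_length = 12, seed = 8))
  ds <- build_dataset(sc$net, sc$annotation, 1)
  ab <- ablation_study(ds, c("dnr", "degree"), folds = 4,
                       n_iterations = 5, seed = 3)
  expect_equal(ab$dropped, c("<none>", "dnr", "degree"))
  expect_equal(ab$delta_sensitivity,
               ab$sensitivity - ab$sensitivity[1])
  expect_equal(ab$delta_auc, ab$auc - ab$auc[1])
  expect_error(ablation_study(ds, "not_a_feature"), "unknown feature")
})

test_that("external score tables round-trip through the TSV reader", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("protein\tscore", "A\t0.5", "B\t-1.25"), f)
  tab <- read_scores_tsv(f)
  expect_equal(tab$score, c(0.5, -1.25))
  writeLines(c("protein\tvalue", "A\t1"), f)
  expect_error(read_scores_tsv(f), "score")
})
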