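test_that("MCC endpoints, hand-evaluated value and conventions hold", {
  expect_identical(mcc(10, 10, 0, 0), 1)
  expect_identical(mcc(0, 0, 10, 10), -1)
  expect_equal(mcc(9, 6, 1, 4), (9 * 6 - 1 * 4) / sqrt(10 * 13 * 7 * 10),
               tolerance = 1e-15)
  # zero-denominator convention
  expect_identical(mcc(5, 0, 5, 0), 0)
  expect_error(mcc(0, 0, 0, 0), "empty")
  expect_error(mcc(-1, 2, 0, 0), "non-negative")
})

test_that("stratified folds preserve class proportions to within one unit", {
  lab <- rep(c("agonist", "antagonist"), c(72, 28))
  fold <- aifp:::make_stratified_folds(sprintf("u%03d", 1:100), lab, k = 5,
                                       seed = 3)
  for (f in 1:5) {
    n_ant <- sum(lab[fold == f] == "antagonist")
    n_ag <- sum(lab[fold == f] == "agonist")
    expect_true(abs(n_ant - 28 / 5) < 1)
    expect_true(abs(n_ag - 72 / 5) < 1)
  }
  expect_identical(sum(fold %in% 1:5), 100L)
  expect_error(aifp:::make_stratified_folds(1:10, rep(c("a", "b"), c(8, 2)),
                                            k = 3, seed = 1), "at least k")
})

test_that("cross-validation is perfect on separable data and leak-free by grouping", {
  g <- generate_matrix(matrix_spec(n_ligands = 40, poses_per_ligand = 3,
                                   p_signal_in_class = 1,
                                   p_signal_out_class = 0,
                                   correct_pose_fraction = 1,
                                   n_noise_features = 5, seed = 2))
  ev <- repeated_stratified_kfold(
    g$matrix, model_spec("random_forest", estimators = 100),
    k = 4, repeats = 2, seed = 1)
  expect_equal(ev$summary$mean_mcc, 1)
  expect_identical(nrow(ev$folds), 8L)
  expect_true(ev$summary$ci_mcc[1] <= ev$summary$mean_mcc)
  expect_true(ev$summary$ci_mcc[2] >= ev$summary$mean_mcc)
})

test_that("cross-validated MCC on shuffled labels is compatible with zero", {
  g <- generate_matrix(matrix_spec(n_ligands = 60, poses_per_ligand = 2,
                                   correct_pose_fraction = 1,
                                   n_noise_features = 10, seed = 3))
  null <- permute_ligand_labels(g$matrix, seed = 11)
  ev <- repeated_stratified_kfold(
    null, model_spec("random_forest", estimators = 150),
    k = 3, repeats = 2, seed = 5)
  expect_lt(abs(ev$summary$mean_mcc), 0.25)
})

test_that("bootstrap intervals degenerate, nest and bracket correctly", {
  expect_error(bootstrap_ci(numeric(0)), "at least 2")
  const <- bootstrap_ci(rep(0.7, 5), seed = 1)
  expect_identical(const$lower, 0.7)
  expect_identical(const$upper, 0.7)
  scores <- aifp:::with_seed(4, rnorm(40, 0.6, 0.05))
  wide <- bootstrap_ci(scores, level = 0.99, seed = 2)
  narrow <- bootstrap_ci(scores, level = 0.90, seed = 2)
  expect_lte(wide$lower, narrow$lower)
  expect_gte(wide$upper, narrow$upper)
  expect_true(wide$lower <= wide$mean && wide$mean <= wide$upper)
})

test_that("bootstrap coverage is near nominal on Gaussian draws", {
  hits <- 0
  n_trials <- 300
  for (t in seq_len(n_trials)) {
    x <- aifp:::with_seed(1000 + t, rnorm(30, mean = 0.5, sd = 0.1))
    ci <- bootstrap_ci(x, level = 0.9, n_boot = 400, seed = t)
    if (ci$lower <= 0.5 && 0.5 <= ci$upper) hits <- hits + 1
  }
  # nominal 0.90; percentile bootstrap at n = 30 undercovers slightly
  expect_gt(hits / n_trials, 0.82)
  expect_lt(hits / n_trials, 0.97)
})

test_that("the repeats formula evaluates and scales exactly", {
  est <- estimate_repeats(0.02, 0.01, 0.99)
  expect_identical(est$n, 27L)
  expect_equal(est$z, qnorm(0.995), tolerance = 1e-12)
  # sigma = delta with z ~ 1 gives a single repeat
  lowconf <- estimate_repeats(0.05, 0.05, confidence = 2 * pnorm(1) - 1)
  expect_identical(lowconf$n, 1L)
  # doubling delta divides the pre-ceiling count by exactly 4
  a <- estimate_repeats(0.03, 0.01, 0.95)
  b <- estimate_repeats(0.03, 0.02, 0.95)
  expect_equal(a$n_exact / b$n_exact, 4, tolerance = 1e-12)
  expect_error(estimate_repeats(-1, 0.01), "sigma")
  expect_error(estimate_repeats(0.02, 0), "delta")
  expect_error(estimate_repeats(0.02, 0.01, 0.4), "confidence")
})

test_that("training is deterministic under a fixed seed and refuses one class", {
  g <- small_planted_study(seed = 37, n_ligands = 60)
  spec <- model_spec("gradient_boosted_trees", estimators = 60)
  m1 <- train_model(g$matrix, spec, seed = 5)
  m2 <- train_model(g$matrix, spec, seed = 5)
  expect_identical(predict_model(m1, g$matrix, "prob"),
                   predict_model(m2, g$matrix, "prob"))
  ag_only <- make_matrix(g$matrix$values[g$matrix$label == "agonist", ],
                         rep("agonist", sum(g$matrix$label == "agonist")))
  expect_error(train_model(ag_only, spec), "single class")
})

test_that("ligand-level prediction is a majority vote over poses", {
  y <- rep(c("antagonist", "agonist"), c(30, 40))
  sep <- as.integer(y == "antagonist")
  m <- make_matrix(cbind(sep, rep(0:1, 35)), y)
  model <- train_model(m, model_spec("gradient_boosted_trees",
                                     estimators = 40), seed = 1)
  # one ligand, 10 poses: 6 carry the antagonist-defining feature
  vals <- cbind(c(rep(1L, 6), rep(0L, 4)), rep(0L, 10))
  rownames(vals) <- sprintf("lig 900_%02d", 1:10)
  colnames(vals) <- colnames(m$values)
  probe <- make_matrix(vals, rep("binder", 10), rep("lig 900", 10))
  pose_cls <- predict_model(model, probe, "class")
  expect_identical(sum(pose_cls == "antagonist"), 6L)
  vote <- predict_ligands(model, probe)
  expect_identical(as.character(vote$predicted), "antagonist")
})

test_that("hyperparameter search honours its argmax contract", {
  g <- small_planted_study(seed = 41, n_ligands = 50)
  # defaults-only space: returned unchanged
  expect_warning(res0 <- hyperparameter_search(g$matrix, budget = 0),
                 "zero search budget")
  expect_identical(res0$best_spec$params, model_spec("gradient_boosted_trees")$params)
  res <- hyperparameter_search(
    g$matrix, family = "gradient_boosted_trees",
    space = list(estimators = c(30, 80), max_depth = c(2, 5)),
    budget = 3, k = 3, repeats = 1, seed = 2)
  expect_equal(res$best_score, max(res$history$mean_mcc), tolerance = 1e-12)
  # the family defaults are always evaluated, so the winner never scores
  # below them on the search objective
  expect_gte(res$best_score, res$history$mean_mcc[1])
})
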