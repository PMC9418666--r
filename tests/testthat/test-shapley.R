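test_that("exact enumeration satisfies the additive, dummy and symmetry axioms", {
  w <- c(0.5, -1.2, 2.0, 0.3)
  additive <- function(S) sum(w[S])
  res <- exact_shapley(additive, 4)
  expect_equal(res$phi, w, tolerance = 1e-12)
  expect_equal(res$base_value, 0)
  # dummy: a feature the value function ignores gets exactly zero
  with_dummy <- function(S) sum(w[setdiff(S, 2)])
  expect_equal(exact_shapley(with_dummy, 4)$phi[2], 0, tolerance = 1e-12)
  # symmetry: interchangeable players receive equal attribution
  symm <- function(S) as.numeric(1 %in% S) + as.numeric(2 %in% S) +
    3 * as.numeric(all(c(1, 2) %in% S))
  ss <- exact_shapley(symm, 3)
  expect_equal(ss$phi[1], ss$phi[2], tolerance = 1e-12)
  expect_equal(ss$phi[3], 0, tolerance = 1e-12)
  # efficiency
  expect_equal(sum(ss$phi), symm(1:3) - symm(integer(0)), tolerance = 1e-12)
  expect_error(exact_shapley(additive, 20), "capped")
})

test_that("exact enumeration matches a literal transcription of the formula", {
  # non-additive 3-player game with interactions
  vf <- function(S) {
    s <- sum(2^(S - 1))
    c(0, 1, 0.5, 2.5, -1, 0.7, 0.2, 3)[s + 1]
  }
  res <- exact_shapley(vf, 3)
  expect_equal(res$phi, shapley_oracle(vf, 3), tolerance = 1e-12)
})

test_that("tree-path attributions equal exact enumeration through the model", {
  g <- generate_matrix(matrix_spec(n_ligands = 60, poses_per_ligand = 3,
                                   correct_pose_fraction = 1,
                                   n_signal_features = 3,
                                   n_noise_features = 7, seed = 9))
  X <- matrix_rows(g$matrix, 1:25)
  B <- matrix_rows(g$matrix, 26:33)
  for (fam in c("gradient_boosted_trees", "random_forest")) {
    spec <- if (fam == "gradient_boosted_trees") {
      model_spec(fam, estimators = 50, max_depth = 3)
    } else model_spec(fam, estimators = 40)
    model <- train_model(g$matrix, spec, seed = 1)
    ts <- tree_shapley(model, X, B)
    ex <- aifp:::exact_shapley_model(model, X$values, B$values)
    expect_lt(max(abs(ts$phi - ex$phi)), 1e-6)
    # local accuracy on the model's own output scale
    out <- predict_model(model, X,
                         if (fam == "gradient_boosted_trees") "margin"
                         else "prob")
    # boosted-tree predictions accumulate in single precision
    expect_lt(max(abs(ts$base_value + rowSums(ts$phi) - out)), 1e-5)
  }
})

test_that("the exact route through model_value_function agrees per sample", {
  g <- generate_matrix(matrix_spec(n_ligands = 40, poses_per_ligand = 2,
                                   correct_pose_fraction = 1,
                                   n_signal_features = 2,
                                   n_noise_features = 4, seed = 19))
  model <- train_model(g$matrix, model_spec("gradient_boosted_trees",
                                            estimators = 30, max_depth = 3),
                       seed = 2)
  x <- g$matrix$values[5, ]
  B <- g$matrix$values[11:18, ]
  vf <- model_value_function(model, x, B)
  res <- exact_shapley(vf, length(x))
  ts <- tree_shapley(model, g$matrix$values[5, , drop = FALSE], B)
  expect_lt(max(abs(res$phi - as.vector(ts$phi))), 1e-6)
  expect_lt(abs(res$base_value - ts$base_value), 1e-6)
})

test_that("tree attribution rejects non-tree input and empty summaries error", {
  expect_error(tree_shapley(list(), matrix(0, 1, 1)), "not a tree-ensemble")
  expect_error(global_importance(list(phi = matrix(numeric(0), 0, 2))),
               "no Shapley values")
})

test_that("planted features dominate the global Shapley ranking", {
  g <- small_planted_study(seed = 43)
  model <- train_model(g$matrix, model_spec("gradient_boosted_trees",
                                            estimators = 150), seed = 3)
  shap <- tree_shapley(model, matrix_rows(g$matrix, 1:120),
                       matrix_rows(g$matrix, 121:135))
  gi <- global_importance(shap)
  expect_true(all(g$truth$signal$feature_key %in% head(gi$feature_key, 10)))
  # signal features carry far more attribution than a label-shuffled model
  null <- permute_ligand_labels(g$matrix, seed = 4)
  nmodel <- train_model(null, model_spec("gradient_boosted_trees",
                                         estimators = 150), seed = 3)
  nshap <- tree_shapley(nmodel, matrix_rows(null, 1:120),
                        matrix_rows(null, 121:135))
  ngi <- global_importance(nshap)
  expect_gt(gi$mean_abs_phi[1], 5 * ngi$mean_abs_phi[1])
})

test_that("global ranking is invariant to sample order", {
  g <- small_planted_study(seed = 47, n_ligands = 60)
  model <- train_model(g$matrix, model_spec("gradient_boosted_trees",
                                            estimators = 80), seed = 1)
  idx <- 1:60
  perm <- rev(idx)
  s1 <- tree_shapley(model, matrix_rows(g$matrix, idx),
                     matrix_rows(g$matrix, 61:70))
  s2 <- tree_shapley(model, matrix_rows(g$matrix, perm),
                     matrix_rows(g$matrix, 61:70))
  g1 <- global_importance(s1)
  g2 <- global_importance(s2)
  expect_identical(g1$feature_key, g2$feature_key)
  expect_equal(g1$mean_abs_phi, g2$mean_abs_phi, tolerance = 1e-12)
})

test_that("presence direction recovers the planted class associations", {
  g <- small_planted_study(seed = 53)
  model <- train_model(g$matrix, model_spec("gradient_boosted_trees",
                                            estimators = 150), seed = 1)
  shap <- tree_shapley(model, matrix_rows(g$matrix, 1:150),
                       matrix_rows(g$matrix, 151:165))
  gi <- global_importance(shap)
  sig <- merge(gi, g$truth$signal, by = "feature_key")
  expect_identical(sig$presence_direction, sig$class)
})
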