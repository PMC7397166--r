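test_that("the options grid is the full Cartesian product in stable order", {
  g <- generate_options_grid(c("quantile", "robust", "standard", "none"),
                             c(10, 50, 100, 150, 200, 250),
                             c("mrmr", "jmi", "jmim"),
                             c("tenfold_cv", "loocv"))
  expect_equal(nrow(g), 144)
  expect_equal(anyDuplicated(g), 0L)
  g2 <- generate_options_grid(c("quantile", "robust", "standard", "none"),
                              c(10, 50, 100, 150, 200, 250),
                              c("mrmr", "jmi", "jmim"),
                              c("tenfold_cv", "loocv"))
  expect_identical(as.data.frame(g), as.data.frame(g2))
  single <- generate_options_grid("standard", 10, "mrmr", "loocv")
  expect_equal(nrow(single), 1)
  expect_error(generate_options_grid(character(0), 10, "mrmr", "loocv"),
               "nonempty")
})

test_that("grid sampling is seeded, sized by floor, and eventually covers", {
  g <- generate_options_grid(c("quantile", "robust", "standard", "none"),
                             c(10, 50, 100, 150, 200, 250),
                             c("mrmr", "jmi", "jmim"),
                             c("tenfold_cv", "loocv"))
  s <- sample_grid(g, 0.5, seed = 10)
  expect_equal(nrow(s), 72)
  expect_identical(as.data.frame(sample_grid(g, 0.5, seed = 10)),
                   as.data.frame(s))
  expect_false(identical(as.data.frame(sample_grid(g, 0.5, seed = 11)),
                         as.data.frame(s)))
  expect_equal(nrow(sample_grid(g, 1.0, seed = 1)), 144)
  seen <- unique(do.call(rbind, lapply(1:20, function(sd) {
    as.data.frame(sample_grid(g, 0.5, seed = sd))
  })))
  expect_gte(nrow(seen), ceiling(0.99 * 144))
})

test_that("a LIG soldier on separable data beats the threshold oracle bar", {
  sim <- generate_synthetic(synthetic_spec(
    n_train = 60, n_valid = 40, n_features = 100, n_informative = 5,
    n_redundant = 0, effect_size = 10, missing_rate = 0, seed = 44))
  av <- generate_options_grid("standard", 5, "mrmr", "tenfold_cv")
  # independent oracle: threshold the single best-MI feature at the midpoint
  tr <- sim$train
  rel <- apply(tr$matrix, 2, function(v) {
    oracle_mi(oracle_discretize(v, 5), tr$labels)
  })
  top <- which.max(rel)
  thr <- mean(c(mean(tr$matrix[tr$labels == 1, top]),
                mean(tr$matrix[tr$labels == 0, top])))
  oracle_pred <- as.integer(sim$valid$matrix[, top] > thr)
  expect_equal(evaluate_predictions(oracle_pred, sim$valid$labels)$mcc, 1)
  for (fam in c("decision_tree", "adaboost", "extra_trees")) {
    s <- train_lig_soldier(tr, av, fam, seed = 5)
    expect_gt(s$selection_eval$mcc, 0.9)
    expect_equal(evaluate_on_holdout(s, sim$valid)$mcc, 1)
  }
})

test_that("soldier training is bit-reproducible under a fixed seed", {
  sim <- generate_synthetic(synthetic_spec(
    n_train = 40, n_valid = 20, n_features = 60, n_informative = 3,
    n_redundant = 0, effect_size = 2, missing_rate = 0, seed = 17))
  av <- generate_options_grid("robust", 5, "jmi", "tenfold_cv")
  a <- train_lig_soldier(sim$train, av, "extra_trees", seed = 33)
  b <- train_lig_soldier(sim$train, av, "extra_trees", seed = 33)
  expect_identical(a$selection_eval, b$selection_eval)
  expect_identical(a$oof, b$oof)
  expect_identical(a$selection$feature_id, b$selection$feature_id)
  # holdout predictions are a pure function of (model, data): tied tree
  # votes must not consult the session RNG
  ha <- evaluate_on_holdout(a, sim$valid)
  hb <- evaluate_on_holdout(b, sim$valid)
  expect_identical(attr(ha, "predictions"), attr(hb, "predictions"))
  expect_identical(attr(ha, "predictions"),
                   attr(evaluate_on_holdout(a, sim$valid), "predictions"))
})

test_that("permuted labels drive selection MCC to the null", {
  set.seed(60)
  base <- tiny_dataset(n = 150, nf = 15, seed = 61, signal = 0)
  av <- generate_options_grid("none", 3, "mrmr", "tenfold_cv")
  mccs <- sapply(1:50, function(i) {
    ds <- ito_dataset(base$matrix, sample(base$labels))
    train_lig_soldier(ds, av, "decision_tree", seed = i)$selection_eval$mcc
  })
  expect_gte(mean(abs(mccs) < 0.3), 0.95)
})

test_that("FT grid search picks the dominating assignment", {
  sim <- generate_synthetic(synthetic_spec(
    n_train = 50, n_valid = 20, n_features = 40, n_informative = 4,
    n_redundant = 0, effect_size = 2, missing_rate = 0, seed = 71))
  av <- generate_options_grid("standard", 4, "mrmr", "tenfold_cv")
  # degenerate one-point grid behaves like a default fit with those params
  one <- train_ft_soldier(sim$train, av, "svm",
                          param_grid = list(cost = 1, kernel = "linear"),
                          seed = 9)
  expect_equal(one$best_params$cost, 1)
  # two assignments: evaluate both independently, the better rho must win
  grid <- list(cost = c(1e-6, 1), kernel = "linear")
  both <- lapply(c(1e-6, 1), function(cc) {
    train_ft_soldier(sim$train, av, "svm",
                     param_grid = list(cost = cc, kernel = "linear"),
                     seed = 9)
  })
  rhos <- sapply(both, function(s) s$selection_eval$rho)
  winner <- train_ft_soldier(sim$train, av, "svm", param_grid = grid, seed = 9)
  expect_equal(winner$best_params$cost, c(1e-6, 1)[which.max(rhos)])
  expect_equal(winner$selection_eval$rho, max(rhos))
  # random search over the full grid equals exhaustive search
  exh <- train_ft_soldier(sim$train, av, "svm", param_grid = grid,
                          search = "exhaustive", seed = 9)
  rnd <- train_ft_soldier(sim$train, av, "svm", param_grid = grid,
                          search = "random", n_random = 2, seed = 9)
  expect_identical(exh$best_params, rnd$best_params)
  expect_error(train_ft_soldier(sim$train, av, "svm",
                                param_grid = list(), seed = 1), "empty")
})

test_that("holdout evaluation matches an independent confusion tally", {
  sim <- generate_synthetic(synthetic_spec(
    n_train = 40, n_valid = 20, n_features = 30, n_informative = 3,
    n_redundant = 0, effect_size = 1.5, missing_rate = 0, seed = 13))
  av <- generate_options_grid("standard", 3, "mrmr", "tenfold_cv")
  s <- train_lig_soldier(sim$train, av, "decision_tree", seed = 2)
  h <- evaluate_on_holdout(s, sim$valid)
  pred <- attr(h, "predictions")
  y <- sim$valid$labels
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  expect_equal(h$accuracy, (tp + tn) / 20)
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  expect_equal(h$mcc, if (den == 0) 0 else num / den)
  # feature misalignment is a hard error
  chopped <- ito_dataset(sim$valid$matrix[, 1:10], sim$valid$labels,
                         feature_ids = sim$valid$feature_ids[1:10])
  expect_error(evaluate_on_holdout(s, chopped), "lacks")
})

test_that("degenerate predictors score as expected on a balanced holdout", {
  y <- rep(c(1L, 0L), 10)
  maj <- rep(0L, 20)
  ev <- evaluate_predictions(maj, y)
  expect_equal(ev$accuracy, 0.5)
  expect_equal(ev$mcc, 0)
  perf <- evaluate_predictions(y, y)
  expect_equal(c(perf$accuracy, perf$mcc, perf$rho), c(1, 1, 1))
})

test_that("subset sizes larger than the surviving features clamp with a warning", {
  ds <- tiny_dataset(n = 20, nf = 4, seed = 3, signal = 2)
  av <- generate_options_grid("none", 50, "mrmr", "tenfold_cv")
  expect_warning(s <- train_lig_soldier(ds, av, "decision_tree", seed = 1),
                 "clamped")
  expect_equal(nrow(s$selection), 4)
})

test_that("every registered FT family trains, tunes, and reproduces", {
  fams <- classifier_families()
  expect_setequal(fams$family[fams$phase == "lig"],
                  c("decision_tree", "adaboost", "extra_trees"))
  expect_true(all(c("random_forest", "svm", "mlp") %in% fams$family))
  sim <- generate_synthetic(synthetic_spec(
    n_train = 40, n_valid = 20, n_features = 30, n_informative = 4,
    n_redundant = 0, effect_size = 3, missing_rate = 0, seed = 55))
  av <- generate_options_grid("standard", 4, "jmim", "tenfold_cv")
  grids <- list(
    random_forest = list(num_trees = c(100, 300), splitrule = "gini",
                         bootstrap = TRUE),
    mlp = list(decay = c(0.1, 1e-4), size = 5)
  )
  for (fam in names(grids)) {
    a <- train_ft_soldier(sim$train, av, fam, param_grid = grids[[fam]],
                          seed = 8)
    b <- train_ft_soldier(sim$train, av, fam, param_grid = grids[[fam]],
                          seed = 8)
    expect_identical(a$oof, b$oof)
    expect_identical(a$best_params, b$best_params)
    expect_gt(a$selection_eval$mcc, 0.5)
    h <- evaluate_on_holdout(a, sim$valid)
    expect_gte(h$accuracy, 0.7)
  }
})
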