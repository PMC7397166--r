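test_that("generation is byte-identical under a fixed seed", {
  spec <- synthetic_spec(n_train = 30, n_valid = 15, n_features = 50,
                         n_informative = 4, n_redundant = 3, seed = 5)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a$train$matrix, b$train$matrix)
  expect_identical(a$valid$matrix, b$valid$matrix)
  expect_identical(a$truth, b$truth)
  d <- generate_synthetic(synthetic_spec(n_train = 30, n_valid = 15,
                                         n_features = 50, n_informative = 4,
                                         n_redundant = 3, seed = 6))
  expect_false(identical(a$train$matrix, d$train$matrix))
})

test_that("the default shape mirrors the benchmark cohort composition", {
  sim <- generate_synthetic(synthetic_spec(seed = 2))
  s <- summarize_dataset(sim$train)
  expect_equal(s$n_samples, 70)
  expect_equal(s$n_positive, 26)
  expect_equal(s$n_negative, 44)
  expect_equal(summarize_dataset(sim$valid)$n_samples, 88)
})

test_that("summaries agree with an independent pass over the matrix", {
  sim <- generate_synthetic(synthetic_spec(n_train = 25, n_valid = 10,
                                           n_features = 40, n_informative = 3,
                                           n_redundant = 2, missing_rate = 0.1,
                                           seed = 9))
  s <- summarize_dataset(sim$train)
  m <- sim$train$matrix
  miss <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (is.na(m[i, j])) miss <- miss + 1L
  }
  expect_equal(s$n_missing, miss)
  expect_equal(s$n_positive, sum(sim$train$labels))
  expect_gt(miss, 0)
  zero <- generate_synthetic(synthetic_spec(n_train = 10, n_valid = 5,
                                            n_features = 20, n_informative = 2,
                                            n_redundant = 0, missing_rate = 0,
                                            seed = 1))
  expect_equal(summarize_dataset(zero$train)$n_missing, 0)
})

test_that("planted effects and redundancy have the advertised strength", {
  spec <- synthetic_spec(n_train = 200, n_valid = 10, n_features = 100,
                         n_informative = 6, n_redundant = 6,
                         effect_size = 1.5, redundancy_noise_sd = 0.3,
                         missing_rate = 0, seed = 12)
  sim <- generate_synthetic(spec)
  m <- sim$train$matrix
  y <- sim$train$labels
  for (f in sim$truth$informative) {
    diff <- mean(m[y == 1, f]) - mean(m[y == 0, f])
    se <- sqrt(1 / sum(y == 1) + 1 / sum(y == 0))
    expect_lt(abs(diff - 1.5), 3 * se)
  }
  for (r in names(sim$truth$sources)) {
    expect_gt(cor(m[, r], m[, sim$truth$sources[[r]]]), 0.9)
  }
})

test_that("missing cells land only in noise features by default", {
  sim <- generate_synthetic(synthetic_spec(n_train = 40, n_valid = 20,
                                           n_features = 60, n_informative = 5,
                                           n_redundant = 5, missing_rate = 0.2,
                                           seed = 30))
  planted <- c(sim$truth$informative, sim$truth$redundant)
  na_features <- sim$train$feature_ids[apply(is.na(sim$train$matrix), 2, any)]
  expect_length(intersect(na_features, planted), 0)
  anywhere <- generate_synthetic(synthetic_spec(
    n_train = 40, n_valid = 20, n_features = 60, n_informative = 20,
    n_redundant = 20, missing_rate = 0.4, missing_in = "anywhere", seed = 30))
  na2 <- anywhere$train$feature_ids[apply(is.na(anywhere$train$matrix), 2, any)]
  expect_gt(length(intersect(
    na2, c(anywhere$truth$informative, anywhere$truth$redundant))), 0)
})

test_that("zero effect size leaves no recoverable class signal", {
  mccs <- sapply(1:50, function(seed) {
    sim <- generate_synthetic(synthetic_spec(
      n_train = 150, n_valid = 10, n_features = 15, n_informative = 3,
      n_redundant = 0, effect_size = 0, missing_rate = 0, seed = seed))
    av <- generate_options_grid("none", 3, "mrmr", "tenfold_cv")
    train_lig_soldier(sim$train, av, "decision_tree",
                      seed = seed)$selection_eval$mcc
  })
  expect_gte(mean(abs(mccs) < 0.3), 0.95)
})

test_that("spec validation rejects impossible configurations", {
  expect_error(synthetic_spec(n_features = 5, n_informative = 4,
                              n_redundant = 4), "exceed")
  expect_error(synthetic_spec(positive_fraction = 0), "positive_fraction")
  expect_error(synthetic_spec(missing_rate = 1), "missing_rate")
  expect_error(synthetic_spec(n_train = 0), "positive")
})

test_that("simulated datasets round-trip through the on-disk layout", {
  sim <- generate_synthetic(synthetic_spec(n_train = 8, n_valid = 4,
                                           n_features = 6, n_informative = 2,
                                           n_redundant = 1, missing_rate = 0,
                                           seed = 3))
  dir <- tempfile()
  write_synthetic(sim, dir)
  expect_setequal(list.files(dir), c("train.tsv", "valid.tsv", "truth.json"))
  back <- read_expression_matrix(file.path(dir, "train.tsv"),
                                 label_source = "class", positive_label = "1")
  expect_equal(back$matrix, sim$train$matrix, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(sort(truth$informative), sort(sim$truth$informative))
})
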