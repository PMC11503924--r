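test_that("min-max scaling follows the train-only, no-clipping contract", {
  sc <- minmax_fit(matrix(c(2, 4, 6)))
  expect_equal(drop(minmax_apply(sc, matrix(c(2, 4, 6)))), c(0, 0.5, 1))
  sc2 <- minmax_fit(matrix(c(0, 10)))
  expect_equal(unname(drop(minmax_apply(sc2, matrix(12)))), 1.2)
  X <- matrix(runif(40), 20, 2)
  sc3 <- minmax_fit(X)
  expect_equal(minmax_invert(sc3, minmax_apply(sc3, X)), X,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(minmax_fit(cbind(a = rep(1, 5), b = 1:5)), "constant")
  expect_error(minmax_apply(list(), matrix(1)), "minmax_scaler")
})

test_that("the split protocol yields the canonical 1280/320 and 1152/128 sizes", {
  sp <- make_splits(1600, seed = 4)
  expect_equal(length(sp$train_indices), 1280)
  expect_equal(length(sp$test_indices), 320)
  expect_equal(length(sp$repetitions), 10)
  for (rp in sp$repetitions) {
    expect_equal(length(rp$train), 1152)
    expect_equal(length(rp$validation), 128)
    expect_equal(sort(c(rp$train, rp$validation)), sp$train_indices)
  }
  expect_equal(sort(c(sp$train_indices, sp$test_indices)), 1:1600)
  expect_identical(make_splits(1600, seed = 4), sp)
  expect_false(identical(make_splits(1600, seed = 5)$test_indices,
                         sp$test_indices))
  expect_error(make_splits(3), "too small")
})

test_that("MAE and Pearson R match hand values and brute-force oracles", {
  expect_equal(mae(c(5, 5), c(5, 5)), 0)
  expect_equal(mae(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_equal(pearson_r(1:10, 1:10), 1.0)
  expect_equal(pearson_r(1:10, -(1:10)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-4)
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_lt(abs(mae(a, b) - oracle_mae(a, b)), 1e-12)
    expect_lt(abs(pearson_r(a, b) - oracle_pearson(a, b)), 1e-12)
  }
  expect_error(mae(1:3, 1:4), "length mismatch")
  expect_error(pearson_r(rep(1, 5), 1:5), "`actual`")
  expect_error(pearson_r(1:5, rep(1, 5)), "`predicted`")
})

test_that("relative improvement is the percentage MAE reduction", {
  expect_equal(relative_improvement(2, 1), 50)
  expect_equal(relative_improvement(0.7, 0.7), 0)
  expect_error(relative_improvement(0, 1), "positive")
  expect_error(relative_improvement(-1, 1), "positive")
})

test_that("grid search picks dominant configs and breaks ties simpler-first", {
  set.seed(42)
  X <- matrix(runif(200), 100, 2)
  y <- drop(X %*% c(1, -1)) + rnorm(100, sd = 0.01)
  sp <- make_splits(100, seed = 1)
  one <- grid_search("knn", list(knn_config(k = 3)), X, y, sp)
  expect_equal(one$best_config$k, 3L)
  # k = 1 interpolates this nearly noiseless target better than k = 50
  gs <- grid_search("knn", list(knn_config(k = 50), knn_config(k = 1)), X, y, sp)
  expect_equal(gs$best_config$k, 1L)
  expect_equal(gs$best_mae, min(gs$results$mean_validation_mae))
  # identical configs score identically; the simpler (here: equal keys,
  # grid order) wins, and leaf size never enters the score
  tie <- grid_search("knn", list(knn_config(k = 5, leaf_size = 30),
                                 knn_config(k = 5, leaf_size = 1)), X, y, sp)
  expect_equal(tie$best_config$leaf_size, 1L)
  expect_equal(tie$results$mean_validation_mae[1],
               tie$results$mean_validation_mae[2])
})

test_that("test rows can never influence the scaler or the tuning", {
  d <- generate_dataset(generator_config(n_records = 1024, seed = 5))
  sp <- make_splits(nrow(d), seed = 2)
  X <- as.matrix(d[c("t", "rh")])
  sc1 <- minmax_fit(X[sp$train_indices, ])
  X2 <- X
  X2[sp$test_indices, ] <- X2[sp$test_indices, ] * 100 + 7
  sc2 <- minmax_fit(X2[sp$train_indices, ])
  expect_identical(sc1, sc2)
  g1 <- grid_search("knn", list(knn_config(k = 3), knn_config(k = 9)),
                    X, d$nh3, sp)
  g2 <- grid_search("knn", list(knn_config(k = 3), knn_config(k = 9)),
                    X2, d$nh3, sp)
  expect_identical(g1$results, g2$results)
})

test_that("the experiment report enumerates every requested cell, reproducibly", {
  d <- generate_dataset(generator_config(n_records = 1024, seed = 6))
  cfg <- experiment_config(families = c("lr", "knn"),
                           combinations = c("i", "vi"), arms = c("raw", "wt"),
                           grid_size = "smoke", seed = 3)
  rep1 <- suppressMessages(run_experiment(d, cfg))
  expect_s3_class(rep1, "evaluation_report")
  expect_equal(nrow(rep1), 2 * 2 * 2)
  expect_true(all(!is.na(rep1$test_mae)))
  expect_true(all(rep1$test_mae >= 0))
  expect_true(all(abs(rep1$test_r) <= 1))
  rep2 <- suppressMessages(run_experiment(d, cfg))
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
  # report round-trips to CSV/JSON
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_report(rep1, fc, fj)
  expect_equal(nrow(read.csv(fc)), nrow(rep1))
  expect_equal(length(jsonlite::read_json(fj)), nrow(rep1))
})

test_that("explicit selection overrides flow through the experiment", {
  d <- generate_dataset(generator_config(n_records = 1024, seed = 8))
  den <- denoise_predictors(
    d, experiment_config(selection_rule = "explicit",
                         selection_overrides = reference_component_selections())
  )
  expect_equal(den$selections$v$selected_levels, c(3L, 4L, 5L, 6L, 8L))
  expect_equal(den$selections$t$selected_levels, 2:10)
  # auto-rule selections are computed from the data itself
  den2 <- denoise_predictors(d, experiment_config())
  expect_equal(den2$selections$lmc$rule, "auto")
  expect_true(all(den2$selections$lmc$selected_levels %in% 1:10))
})
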