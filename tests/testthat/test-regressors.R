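make_instance <- function(n = 30, d = 3, seed = 3) {
  set.seed(seed)
  list(X = matrix(runif(n * d), n, d), y = runif(n))
}

test_that("ELM output weights match the generic ridge normal-equations oracle", {
  inst <- make_instance(30, 3)
  cfg <- elm_config(hidden_nodes = 15, activation = "sigmoid",
                    regularization = 0.01, seed = 5)
  m <- elm_fit(inst$X, inst$y, cfg)
  H <- nh3wt:::.activate(sweep(inst$X %*% m$W, 2, m$b, `+`), "sigmoid")
  expect_lt(max(abs(m$beta - oracle_ridge(H, inst$y, 0.01))), 1e-8)
})

test_that("ELM behaviour at the contract's limit points", {
  inst <- make_instance(20, 2, seed = 8)
  # frozen random layer: identical predictions across refits
  p1 <- elm_predict(elm_fit(inst$X, inst$y, elm_config(50, seed = 4)), inst$X)
  p2 <- elm_predict(elm_fit(inst$X, inst$y, elm_config(50, seed = 4)), inst$X)
  expect_identical(p1, p2)
  # interpolation regime: hn >= n, rp = 0 on noiseless smooth data drives
  # training error to zero
  y_smooth <- sin(2 * pi * inst$X[, 1]) + inst$X[, 2]^2
  suppressWarnings(
    m0 <- elm_fit(inst$X, y_smooth, elm_config(40, "sigmoid", 0, seed = 2))
  )
  expect_lt(mae(y_smooth, elm_predict(m0, inst$X)), 1e-6)
  # infinite shrinkage sends predictions to zero
  mS <- elm_fit(inst$X, inst$y, elm_config(20, "sigmoid", 1e9, seed = 2))
  expect_lt(max(abs(elm_predict(mS, inst$X))), 1e-3)
  # empty prediction set and row permutation
  m <- elm_fit(inst$X, inst$y, elm_config(10, seed = 1))
  expect_identical(elm_predict(m, inst$X[0, , drop = FALSE]), numeric(0))
  perm <- sample(nrow(inst$X))
  expect_equal(elm_predict(m, inst$X[perm, ]), elm_predict(m, inst$X)[perm])
  expect_error(elm_predict(m, inst$X[, 1, drop = FALSE]), "features")
})

test_that("ELM training error is non-increasing in hidden nodes (nested features)", {
  hn_grid <- c(5, 10, 20, 40, 80)
  err <- sapply(1:5, function(s) {
    inst <- make_instance(40, 3, seed = 40 + s)
    sapply(hn_grid, function(hn) {
      m <- suppressWarnings(
        elm_fit(inst$X, inst$y, elm_config(hn, "sigmoid", 0, seed = 77))
      )
      mae(inst$y, elm_predict(m, inst$X))
    })
  })
  med <- apply(err, 1, median)
  expect_true(all(diff(med) <= 1e-10))
})

test_that("KNN follows the neighbour-mean contract", {
  m <- knn_fit(matrix(c(0, 1, 2)), c(0, 10, 20),
               knn_config(k = 2, minkowski_power = 2))
  expect_equal(knn_predict(m, matrix(0.6)), 5.0)
  # k = 1 on training points returns the training targets
  inst <- make_instance(25, 2, seed = 6)
  m1 <- knn_fit(inst$X, inst$y, knn_config(k = 1))
  expect_equal(knn_predict(m1, inst$X), inst$y)
  # leaf size never changes predictions
  q <- matrix(runif(10), 5, 2)
  for (p in c(1, 2, 3.5)) {
    pa <- knn_predict(knn_fit(inst$X, inst$y, knn_config(5, 1, p)), q)
    pb <- knn_predict(knn_fit(inst$X, inst$y, knn_config(5, 30, p)), q)
    expect_identical(pa, pb)
  }
  # distance ties break by training index order
  mt <- knn_fit(matrix(c(-1, 1, 1)), c(0, 10, 20), knn_config(k = 2))
  expect_equal(knn_predict(mt, matrix(0)), 5)
  expect_error(knn_fit(inst$X, inst$y, knn_config(k = 26)), "exceeds")
})

test_that("random forest honours degeneracy, determinism, and importance ordering", {
  inst <- make_instance(60, 2, seed = 10)
  expect_equal(rf_predict(rf_fit(matrix(1), 5, rf_config()), matrix(99)), 5)
  expect_equal(rf_predict(rf_fit(inst$X, rep(2, 60), rf_config()), inst$X),
               rep(2, 60))
  p1 <- rf_predict(rf_fit(inst$X, inst$y, rf_config(seed = 3)), inst$X)
  p2 <- rf_predict(rf_fit(inst$X, inst$y, rf_config(seed = 3)), inst$X)
  expect_identical(p1, p2)
  # signal feature outranks a pure-noise feature in most seeds
  hits <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    X <- cbind(x1 = runif(80), x2 = runif(80))
    y <- X[, "x1"]
    imp <- rf_fit(X, y, rf_config(seed = s))$importance
    if (imp["x1"] > imp["x2"]) hits <- hits + 1
  }
  expect_gte(hits, 6)
})

test_that("the linear baseline is exact OLS with a pseudoinverse fallback", {
  x <- matrix(1:6)
  m <- lr_fit(x, 2 * (1:6))
  expect_equal(unname(m$coefficients), c(0, 2), tolerance = 1e-10)
  inst <- make_instance(25, 3, seed = 14)
  mo <- lr_fit(inst$X, inst$y)
  A <- cbind(1, inst$X)
  expect_lt(max(abs(mo$coefficients - oracle_ridge(A, inst$y, 0))), 1e-8)
  resid <- inst$y - lr_predict(mo, inst$X)
  expect_lt(abs(mean(resid)), 1e-10)
  Xc <- cbind(inst$X, inst$X[, 1])
  expect_warning(mc <- lr_fit(Xc, inst$y), "collinear")
  expect_true(all(is.finite(lr_predict(mc, Xc))))
})

test_that("fits are invariant to training-row order", {
  inst <- make_instance(40, 3, seed = 22)
  perm <- sample(40)
  q <- matrix(runif(15), 5, 3)
  for (fam in c("lr", "elm", "rf")) {
    m1 <- fit_model(fam, inst$X, inst$y)
    m2 <- fit_model(fam, inst$X[perm, ], inst$y[perm])
    tol <- if (fam == "rf") 0.25 else 1e-8
    expect_equal(predict_model(m1, q), predict_model(m2, q), tolerance = tol)
  }
})

test_that("ELM, KNN and LR fits round-trip through the JSON layout", {
  inst <- make_instance(20, 2, seed = 30)
  q <- matrix(runif(8), 4, 2)
  for (fam in c("elm", "knn", "lr")) {
    m <- fit_model(fam, inst$X, inst$y)
    f <- tempfile(fileext = ".json")
    save_fit(m, f)
    m2 <- load_fit(f)
    expect_equal(predict_model(m2, q), predict_model(m, q), tolerance = 1e-10)
  }
  mrf <- fit_model("rf", inst$X, inst$y)
  frf <- tempfile(fileext = ".rds")
  save_fit(mrf, frf)
  expect_equal(predict_model(load_fit(frf), q), predict_model(mrf, q))
})
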