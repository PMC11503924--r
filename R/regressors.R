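# The four regression families behind a single fit/predict contract:
# an extreme learning machine implemented from its closed-form solution,
# k-nearest-neighbour regression (Minkowski distance, neighbour-mean),
# random-forest regression (ranger backend), and an OLS baseline.

# ---- configs ---------------------------------------------------------------

#' Model-family configurations
#'
#' @param hidden_nodes Number of hidden nodes `hn` (>= 1).
#' @param activation Activation function `af`: `"sigmoid"` (logistic),
#'   `"tanh"`, or `"relu"`.
#' @param regularization Ridge penalty `rp` (>= 0) on the output weights.
#' @param seed Seed for the frozen random hidden layer.
#' @return A config object of class `elm_config`, `knn_config`, or
#'   `rf_config`.
#' @export
elm_config <- function(hidden_nodes = 100L, activation = c("sigmoid", "tanh", "relu"),
                       regularization = 0.001, seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(hidden_nodes >= 1, regularization >= 0)
  structure(list(hidden_nodes = as.integer(hidden_nodes),
                 activation = activation,
                 regularization = regularization, seed = as.integer(seed)),
            class = "elm_config")
}

#' @rdname elm_config
#' @param k Number of neighbours (>= 1).
#' @param leaf_size Search-structure leaf size `ls`; retained for sweep
#'   compatibility, it never changes predictions (a stated contract).
#' @param minkowski_power Minkowski distance power `p` (>= 1).
#' @export
knn_config <- function(k = 5L, leaf_size = 1L, minkowski_power = 2) {
  stopifnot(k >= 1, leaf_size >= 1, minkowski_power >= 1)
  structure(list(k = as.integer(k), leaf_size = as.integer(leaf_size),
                 minkowski_power = minkowski_power),
            class = "knn_config")
}

#' @rdname elm_config
#' @param n_trees Number of trees `nt` (>= 1).
#' @param max_depth Maximum tree depth `d` (>= 1).
#' @param min_samples_split Minimum node size eligible for a split `ss` (>= 2).
#' @param min_samples_leaf Minimum terminal-node size `sl` (>= 1).
#' @export
rf_config <- function(n_trees = 50L, max_depth = 10L, min_samples_split = 2L,
                      min_samples_leaf = 1L, seed = 1L) {
  stopifnot(n_trees >= 1, max_depth >= 1, min_samples_split >= 2,
            min_samples_leaf >= 1)
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 seed = as.integer(seed)),
            class = "rf_config")
}

.as_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

.check_xy <- function(X, y) {
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
}

# Minimum-norm least-squares solve via the SVD pseudoinverse, with the
# conventional max(dim) * eps * s_max rank cutoff.
.pinv_solve <- function(A, y) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  drop(sv$v[, keep, drop = FALSE] %*%
         ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep]))
}

.activate <- function(z, activation) {
  switch(activation,
         sigmoid = 1 / (1 + exp(-z)),
         tanh = tanh(z),
         relu = pmax(z, 0))
}

# ---- extreme learning machine ---------------------------------------------

#' Fit an extreme learning machine (closed form)
#'
#' Hidden weights and biases are drawn once from a seeded Uniform(-1, 1)
#' distribution and frozen; the hidden activations are
#' `H = af(X W + b)`; the output weights solve the ridge problem
#' `min ||H beta - y||^2 + rp ||beta||^2` in closed form
#' (`(H'H + rp I) beta = H'y`). There is no output bias term. The random
#' stream is consumed node by node, so for a fixed seed the first `hn`
#' hidden nodes are identical across sweeps of `hidden_nodes`.
#'
#' @param X Numeric feature matrix (conventionally min-max scaled to
#'   `[0, 1]`), rows = observations.
#' @param y Numeric target vector.
#' @param config An [elm_config()].
#' @return Object of class `c("elm_fit", "nh3wt_model")`.
#' @export
elm_fit <- function(X, y, config = elm_config()) {
  stopifnot(inherits(config, "elm_config"))
  X <- .as_matrix(X)
  .check_xy(X, y)
  d <- ncol(X)
  hn <- config$hidden_nodes
  draw <- .with_seed(config$seed,
                     matrix(stats::runif((d + 1) * hn, -1, 1), d + 1, hn))
  W <- draw[seq_len(d), , drop = FALSE]
  b <- draw[d + 1, ]
  H <- .activate(sweep(X %*% W, 2, b, `+`), config$activation)
  rp <- config$regularization
  beta <- if (rp > 0) {
    solve(crossprod(H) + diag(rp, hn), crossprod(H, y))
  } else {
    bt <- tryCatch(solve(crossprod(H), crossprod(H, y)), error = function(e) NULL)
    if (is.null(bt)) {
      warning("singular hidden-layer system with rp = 0; solved by pseudoinverse")
      bt <- .pinv_solve(H, y)
    }
    bt
  }
  structure(
    list(family = "elm", config = config, W = W, b = b, beta = drop(beta),
         feature_names = colnames(X)),
    class = c("elm_fit", "nh3wt_model")
  )
}

#' Predict from a fitted model
#'
#' @param model A fit returned by [elm_fit()], [knn_fit()], [rf_fit()] or
#'   [lr_fit()].
#' @param X Feature matrix with the training feature count (and order).
#' @return Numeric prediction vector (empty input gives an empty vector).
#' @export
elm_predict <- function(model, X) {
  stopifnot(inherits(model, "elm_fit"))
  X <- .as_matrix(X)
  if (ncol(X) != nrow(model$W)) {
    stop(sprintf("model was trained on %d features, got %d",
                 nrow(model$W), ncol(X)))
  }
  if (nrow(X) == 0) return(numeric(0))
  H <- .activate(sweep(X %*% model$W, 2, model$b, `+`), model$config$activation)
  drop(H %*% model$beta)
}

# ---- k-nearest neighbours --------------------------------------------------

#' Fit / predict k-nearest-neighbour regression
#'
#' Prediction is the unweighted mean of the `k` nearest training targets
#' under Minkowski-`p` distance. Ties in distance are broken by training-set
#' index order. `leaf_size` only parameterizes the (hypothetical) search
#' structure and never changes predictions.
#'
#' @inheritParams elm_fit
#' @param config A [knn_config()].
#' @return Object of class `c("knn_fit", "nh3wt_model")`.
#' @export
knn_fit <- function(X, y, config = knn_config()) {
  stopifnot(inherits(config, "knn_config"))
  X <- .as_matrix(X)
  .check_xy(X, y)
  if (config$k > nrow(X)) {
    stop(sprintf("k = %d exceeds the number of training records (%d)",
                 config$k, nrow(X)))
  }
  structure(
    list(family = "knn", config = config, X = X, y = as.numeric(y),
         feature_names = colnames(X)),
    class = c("knn_fit", "nh3wt_model")
  )
}

#' @rdname knn_fit
#' @param model A [knn_fit()] result.
#' @export
knn_predict <- function(model, X) {
  stopifnot(inherits(model, "knn_fit"))
  X <- .as_matrix(X)
  if (ncol(X) != ncol(model$X)) {
    stop(sprintf("model was trained on %d features, got %d",
                 ncol(model$X), ncol(X)))
  }
  if (nrow(X) == 0) return(numeric(0))
  k <- model$config$k
  p <- model$config$minkowski_power
  apply(X, 1, function(q) {
    d <- rowSums(abs(sweep(model$X, 2, q, `-`))^p)^(1 / p)
    nn <- order(d, seq_along(d))[seq_len(k)]
    mean(model$y[nn])
  })
}

# ---- random forest ---------------------------------------------------------

#' Fit / predict random-forest regression
#'
#' Bootstrap-resampled, depth- and size-constrained regression trees with
#' variance-reduction splits; the prediction is the mean over trees. The
#' ensemble is fitted with the ranger backend (single-threaded, seeded, so
#' results are deterministic given the config).
#'
#' @inheritParams elm_fit
#' @param config An [rf_config()].
#' @return Object of class `c("rf_fit", "nh3wt_model")`; tree-impurity
#'   feature importances are available in `$importance`.
#' @export
rf_fit <- function(X, y, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  X <- .as_matrix(X)
  .check_xy(X, y)
  if (nrow(X) == 1 || stats::var(y) == 0) {
    # degenerate training sets: predict the constant
    return(structure(
      list(family = "rf", config = config, constant = mean(y),
           importance = stats::setNames(rep(0, ncol(X)), colnames(X)),
           feature_names = colnames(X)),
      class = c("rf_fit", "nh3wt_model")
    ))
  }
  dat <- data.frame(.y = as.numeric(y), X, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = config$n_trees, max.depth = config$max_depth,
    min.node.size = config$min_samples_split,
    min.bucket = config$min_samples_leaf,
    importance = "impurity", seed = config$seed, num.threads = 1
  )
  structure(
    list(family = "rf", config = config, fit = fit,
         importance = fit$variable.importance, feature_names = colnames(X)),
    class = c("rf_fit", "nh3wt_model")
  )
}

#' @rdname rf_fit
#' @param model An [rf_fit()] result.
#' @export
rf_predict <- function(model, X) {
  stopifnot(inherits(model, "rf_fit"))
  X <- .as_matrix(X)
  if (ncol(X) != length(model$feature_names)) {
    stop(sprintf("model was trained on %d features, got %d",
                 length(model$feature_names), ncol(X)))
  }
  if (nrow(X) == 0) return(numeric(0))
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  colnames(X) <- model$feature_names
  stats::predict(model$fit, data = as.data.frame(X),
                 num.threads = 1)$predictions
}

# ---- linear baseline -------------------------------------------------------

#' Fit / predict the ordinary-least-squares baseline
#'
#' OLS with an intercept. Rank-deficient (collinear) designs fall back to
#' the minimum-norm solution via the pseudoinverse, with a warning.
#'
#' @inheritParams elm_fit
#' @return Object of class `c("lr_fit", "nh3wt_model")` with `$coefficients`
#'   (intercept first).
#' @export
lr_fit <- function(X, y) {
  X <- .as_matrix(X)
  .check_xy(X, y)
  A <- cbind(`(Intercept)` = 1, X)
  qr_a <- qr(A)
  coefs <- if (qr_a$rank < ncol(A)) {
    warning("collinear design; returning the minimum-norm coefficient vector")
    .pinv_solve(A, y)
  } else {
    drop(qr.coef(qr_a, y))
  }
  names(coefs) <- colnames(A)
  structure(
    list(family = "lr", config = NULL, coefficients = coefs,
         feature_names = colnames(X)),
    class = c("lr_fit", "nh3wt_model")
  )
}

#' @rdname lr_fit
#' @param model An [lr_fit()] result.
#' @export
lr_predict <- function(model, X) {
  stopifnot(inherits(model, "lr_fit"))
  X <- .as_matrix(X)
  if (ncol(X) != length(model$feature_names)) {
    stop(sprintf("model was trained on %d features, got %d",
                 length(model$feature_names), ncol(X)))
  }
  if (nrow(X) == 0) return(numeric(0))
  drop(cbind(1, X) %*% model$coefficients)
}

# ---- common dispatch -------------------------------------------------------

#' Fit / predict dispatcher over the model families
#'
#' @param family One of `"lr"`, `"knn"`, `"rf"`, `"elm"`.
#' @param X,y Training data.
#' @param config Family config (ignored for `"lr"`).
#' @return A fitted `nh3wt_model`.
#' @export
fit_model <- function(family = c("lr", "knn", "rf", "elm"), X, y, config = NULL) {
  family <- match.arg(family)
  switch(family,
         lr = lr_fit(X, y),
         knn = knn_fit(X, y, config %||% knn_config()),
         rf = rf_fit(X, y, config %||% rf_config()),
         elm = elm_fit(X, y, config %||% elm_config()))
}

#' @rdname fit_model
#' @param model A fitted `nh3wt_model`.
#' @export
predict_model <- function(model, X) {
  switch(model$family,
         lr = lr_predict(model, X),
         knn = knn_predict(model, X),
         rf = rf_predict(model, X),
         elm = elm_predict(model, X))
}

#' @export
predict.nh3wt_model <- function(object, newdata, ...) predict_model(object, newdata)

#' @export
print.nh3wt_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("nh3wt %s model (%d features: %s)\n", toupper(x$family),
              length(x$feature_names), paste(x$feature_names, collapse = ", ")))
  if (!is.null(cfg)) {
    cat("  config:", paste(sprintf("%s=%s", names(unclass(cfg)), unlist(cfg)),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / restore a fitted model
#'
#' ELM, KNN and LR fits (config plus learned arrays) round-trip through a
#' plain JSON layout; random-forest fits carry a compiled ranger ensemble
#' and are cached with R's native serialization instead.
#'
#' @param model A fitted `nh3wt_model`.
#' @param path Output path (`.json`, or `.rds` for random forests).
#' @return `path` invisibly; `load_fit()` returns the restored model.
#' @export
save_fit <- function(model, path) {
  stopifnot(inherits(model, "nh3wt_model"))
  if (model$family == "rf") {
    saveRDS(model, path)
  } else {
    payload <- unclass(model)
    payload$config <- if (!is.null(model$config)) unclass(model$config)
    payload$.class <- class(model)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname save_fit
#' @export
load_fit <- function(path) {
  if (grepl("\\.rds$", path)) return(readRDS(path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- unlist(raw$.class)
  raw$.class <- NULL
  cfg_class <- paste0(raw$family, "_config")
  if (!is.null(raw$config)) class(raw$config) <- cfg_class
  for (nm in c("W", "X")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.matrix(raw[[nm]])
  }
  if (!is.null(raw$X)) colnames(raw$X) <- raw$feature_names
  structure(raw, class = cls)
}
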