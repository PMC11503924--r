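# Experimental protocol: min-max scaling, 80/20 splitting with repeated
# 90/10 Monte-Carlo validation inside the training pool, MAE / Pearson-R
# metrics, grid search, and the standalone-vs-hybrid experiment runner.

# ---- scaling ---------------------------------------------------------------

#' Min-max scaling fitted on training data
#'
#' `minmax_fit()` learns per-column min and max from the training matrix;
#' `minmax_apply()` maps columns through `(x - min) / (max - min)`. Values
#' outside the training range deliberately fall outside `[0, 1]` (no
#' clipping), so the test set can never influence the scaler.
#' A constant training column is mapped to 0, with a warning.
#'
#' @param train_matrix Numeric matrix or data frame of training rows.
#' @return `minmax_fit()`: object of class `minmax_scaler`.
#' @export
minmax_fit <- function(train_matrix) {
  X <- .as_matrix(train_matrix)
  stopifnot(nrow(X) >= 1)
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  if (any(maxs == mins)) {
    warning("constant training column(s) mapped to 0: ",
            paste(colnames(X)[maxs == mins], collapse = ", "))
  }
  structure(list(mins = mins, ranges = maxs - mins, columns = colnames(X)),
            class = "minmax_scaler")
}

#' @rdname minmax_fit
#' @param scaler A fitted `minmax_scaler`.
#' @param matrix_ Matrix (or data frame) with the training columns.
#' @export
minmax_apply <- function(scaler, matrix_) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  X <- .as_matrix(matrix_)
  stopifnot(ncol(X) == length(scaler$mins))
  rng <- ifelse(scaler$ranges == 0, 1, scaler$ranges)
  out <- sweep(sweep(X, 2, scaler$mins, `-`), 2, rng, `/`)
  out[, scaler$ranges == 0] <- 0
  out
}

#' @rdname minmax_fit
#' @export
minmax_invert <- function(scaler, matrix_) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  X <- .as_matrix(matrix_)
  rng <- ifelse(scaler$ranges == 0, 1, scaler$ranges)
  sweep(sweep(X, 2, rng, `*`), 2, scaler$mins, `+`)
}

# ---- splits ----------------------------------------------------------------

#' Seeded train/test split with repeated inner validation partitions
#'
#' Draws a random test set of `round(n * test_fraction)` records; the rest
#' form the training pool. Inside the pool, `repetitions` independent seeded
#' partitions reserve `1 - inner_train_fraction` of the pool for validation
#' (Monte-Carlo cross-validation), for hyperparameter tuning.
#'
#' @param n_records Total record count.
#' @param test_fraction Fraction held out for final testing (default 0.2).
#' @param repetitions Number of inner partitions (default 10).
#' @param inner_train_fraction Fraction of the pool used for inner training
#'   in each repetition (default 0.9).
#' @param seed Integer seed; the plan is a pure function of the arguments.
#' @return Object of class `split_plan`: `train_indices`, `test_indices`,
#'   `repetitions` (list of `list(train, validation)`), `seed`.
#' @export
make_splits <- function(n_records, test_fraction = 0.2, repetitions = 10L,
                        inner_train_fraction = 0.9, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            inner_train_fraction > 0, inner_train_fraction < 1,
            repetitions >= 1)
  n_test <- round(n_records * test_fraction)
  n_train <- n_records - n_test
  if (n_test < 1 || n_train < 2) stop("n_records too small for a non-empty split")
  n_inner <- round(n_train * inner_train_fraction)
  if (n_inner < 1 || n_inner >= n_train) {
    stop("n_records too small: the inner train/validation partition is empty")
  }
  .with_seed(seed, {
    perm <- sample.int(n_records)
    test_idx <- sort(perm[seq_len(n_test)])
    train_idx <- sort(perm[-seq_len(n_test)])
    reps <- lapply(seq_len(repetitions), function(r) {
      p <- sample.int(n_train)
      list(train = train_idx[sort(p[seq_len(n_inner)])],
           validation = train_idx[sort(p[-seq_len(n_inner)])])
    })
    structure(list(train_indices = train_idx, test_indices = test_idx,
                   repetitions = reps, seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan (seed %d): %d train / %d test; %d repetitions of %d/%d\n",
              x$seed, length(x$train_indices), length(x$test_indices),
              length(x$repetitions), length(x$repetitions[[1]]$train),
              length(x$repetitions[[1]]$validation)))
  invisible(x)
}

# ---- metrics ---------------------------------------------------------------

#' Mean absolute error
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return `mean(abs(actual - predicted))`, in the units of the target (ppm
#'   for NH3).
#' @export
mae <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop(sprintf("length mismatch: %d vs %d", length(actual), length(predicted)))
  }
  if (length(actual) == 0) stop("empty input")
  mean(abs(actual - predicted))
}

#' Pearson product-moment correlation
#'
#' @param actual,predicted Equal-length numeric vectors, each with nonzero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop(sprintf("length mismatch: %d vs %d", length(actual), length(predicted)))
  }
  if (stats::sd(actual) == 0) stop("`actual` has zero variance")
  if (stats::sd(predicted) == 0) stop("`predicted` has zero variance")
  stats::cor(actual, predicted)
}

#' Relative improvement of a hybrid over a base value
#'
#' @param base_value Positive reference value (e.g. standalone-model MAE).
#' @param hybrid_value Comparison value (e.g. hybrid-model MAE).
#' @return `100 * (base_value - hybrid_value) / base_value`, percent.
#' @export
relative_improvement <- function(base_value, hybrid_value) {
  if (!is.numeric(base_value) || base_value <= 0) {
    stop("`base_value` must be positive")
  }
  100 * (base_value - hybrid_value) / base_value
}

# ---- input combinations and grids -----------------------------------------

#' The seven standard input combinations
#'
#' @return Named list `i`..`vii` of predictor sets: (i) LMC; (ii) LMC, LPH;
#'   (iii) LMC, LPH, LT; (iv) T; (v) T, RH; (vi) T, RH, V;
#'   (vii) LMC, LPH, T.
#' @export
input_combinations <- function() {
  list(
    i = "lmc",
    ii = c("lmc", "lph"),
    iii = c("lmc", "lph", "lt"),
    iv = "t",
    v = c("t", "rh"),
    vi = c("t", "rh", "v"),
    vii = c("lmc", "lph", "t")
  )
}

#' Hyperparameter grids for the tunable families
#'
#' `"default"` is a pragmatic discretization of the full search ranges
#' (neighbours 1-50, leaf size 1-30, power 1-10 for KNN; trees 1-50, depth
#' 1-10, split 2-10, leaf 1-10 for RF; hidden nodes 1-200, three
#' activations, penalty 1e-4-0.1 for ELM): hidden nodes in steps of 20 and
#' the penalty on a log grid, mirroring the values such sweeps actually
#' select. `"smoke"` is a two-point grid for fast runs; `"full"` enumerates
#' the complete ranges (expensive).
#'
#' @param family `"knn"`, `"rf"`, or `"elm"` (`"lr"` has no grid).
#' @param size `"default"`, `"smoke"`, or `"full"`.
#' @return List of family config objects.
#' @export
default_grid <- function(family = c("knn", "rf", "elm", "lr"),
                         size = c("default", "smoke", "full")) {
  family <- match.arg(family)
  size <- match.arg(size)
  grid_df <- switch(
    family,
    lr = return(list(NULL)),
    knn = switch(size,
      smoke = expand.grid(k = c(3, 7), ls = 1, p = 1),
      default = expand.grid(k = c(1, 3, 5, 7, 9, 11, 15, 19, 25, 31, 41),
                            ls = 1, p = c(1, 2)),
      full = expand.grid(k = 1:50, ls = 1:30, p = 1:10)),
    rf = switch(size,
      smoke = expand.grid(nt = c(25, 50), d = 10, ss = 2, sl = c(1, 3)),
      default = expand.grid(nt = c(20, 50), d = c(5, 10), ss = c(2, 5),
                            sl = c(1, 5)),
      full = expand.grid(nt = 1:50, d = 1:10, ss = 2:10, sl = 1:10)),
    elm = switch(size,
      smoke = expand.grid(hn = c(60, 140), af = "sigmoid", rp = 0.001,
                          stringsAsFactors = FALSE),
      default = expand.grid(hn = c(20, 60, 100, 140, 180),
                            af = c("sigmoid", "tanh", "relu"),
                            rp = c(1e-4, 1e-3, 1e-2, 1e-1),
                            stringsAsFactors = FALSE),
      full = expand.grid(hn = 1:200, af = c("sigmoid", "tanh", "relu"),
                         rp = c(1e-4, 1e-3, 1e-2, 1e-1),
                         stringsAsFactors = FALSE))
  )
  lapply(seq_len(nrow(grid_df)), function(i) {
    g <- grid_df[i, ]
    switch(family,
           knn = knn_config(k = g$k, leaf_size = g$ls, minkowski_power = g$p),
           rf = rf_config(n_trees = g$nt, max_depth = g$d,
                          min_samples_split = g$ss, min_samples_leaf = g$sl),
           elm = elm_config(hidden_nodes = g$hn, activation = g$af,
                            regularization = g$rp))
  })
}

# Simpler-first key for breaking validation-MAE ties: lexicographically
# smaller = simpler (fewer hidden nodes / stronger shrinkage; more
# neighbours; shallower and smaller forests).
.complexity_key <- function(family, config) {
  switch(family,
         lr = 0,
         elm = c(config$hidden_nodes, -config$regularization),
         knn = c(-config$k, config$minkowski_power, config$leaf_size),
         rf = c(config$max_depth, config$n_trees, -config$min_samples_split,
                -config$min_samples_leaf))
}

.config_label <- function(family, config) {
  if (is.null(config)) return("")
  switch(family,
         lr = "",
         knn = sprintf("k=%d, ls=%d, p=%g", config$k, config$leaf_size,
                       config$minkowski_power),
         rf = sprintf("nt=%d, d=%d, ss=%d, sl=%d", config$n_trees,
                      config$max_depth, config$min_samples_split,
                      config$min_samples_leaf),
         elm = sprintf("hn=%d, af=%s, rp=%g", config$hidden_nodes,
                       config$activation, config$regularization))
}

# ---- grid search -----------------------------------------------------------

# Fit on scaled features/target, return predictions on the ppm scale.
.fit_predict_ppm <- function(family, config, X_tr, y_tr, X_new) {
  sx <- minmax_fit(X_tr)
  sy <- minmax_fit(matrix(y_tr, ncol = 1))
  model <- fit_model(family, minmax_apply(sx, X_tr),
                     drop(minmax_apply(sy, matrix(y_tr, ncol = 1))), config)
  pred <- predict_model(model, minmax_apply(sx, X_new))
  drop(minmax_invert(sy, matrix(pred, ncol = 1)))
}

#' Monte-Carlo grid search over a hyperparameter grid
#'
#' Scores each config by its mean validation MAE over the split plan's
#' repetitions; the min-max scaler (features and target) is refit on each
#' repetition's inner training set, so no validation or test statistic ever
#' reaches the scaler. Ties are broken by a simpler-first complexity key,
#' then by grid order. Configs that fail to fit are excluded with a logged
#' reason; if every config fails, an error is raised.
#'
#' @param family `"lr"`, `"knn"`, `"rf"`, or `"elm"`.
#' @param grid List of family configs (see [default_grid()]).
#' @param X Feature matrix for all records.
#' @param y Target vector (ppm) for all records.
#' @param split_plan A [make_splits()] plan.
#' @return List: `best_config`, `best_mae`, and `results` (data frame of
#'   config labels and mean validation MAE).
#' @export
grid_search <- function(family, grid, X, y, split_plan) {
  stopifnot(inherits(split_plan, "split_plan"), length(grid) >= 1)
  X <- .as_matrix(X)
  scores <- vapply(grid, function(cfg) {
    rep_mae <- tryCatch(
      vapply(split_plan$repetitions, function(rp) {
        pred <- .fit_predict_ppm(family, cfg, X[rp$train, , drop = FALSE],
                                 y[rp$train], X[rp$validation, , drop = FALSE])
        mae(y[rp$validation], pred)
      }, numeric(1)),
      error = function(e) {
        message(sprintf("config excluded (%s): %s",
                        .config_label(family, cfg), conditionMessage(e)))
        NA_real_
      }
    )
    mean(rep_mae)
  }, numeric(1))
  if (all(is.na(scores))) stop("every config in the grid failed to fit")
  best_mae <- min(scores, na.rm = TRUE)
  cand <- which(!is.na(scores) & scores == best_mae)
  if (length(cand) > 1) {
    keys <- t(vapply(cand, function(i) .complexity_key(family, grid[[i]]),
                     .complexity_key(family, grid[[cand[1]]])))
    ord <- do.call(order, c(as.data.frame(keys), list(cand)))
    cand <- cand[ord]
  }
  best <- cand[1]
  list(
    best_config = grid[[best]],
    best_mae = scores[best],
    results = data.frame(
      config = vapply(grid, function(g) .config_label(family, g), character(1)),
      mean_validation_mae = scores
    )
  )
}

# ---- experiment runner -----------------------------------------------------

#' Configuration of a full standalone-vs-hybrid experiment
#'
#' @param families Model families to evaluate.
#' @param combinations Names of input combinations (subset of `i`..`vii`).
#' @param arms `"raw"` (original series), `"wt"` (wavelet-denoised), or both.
#' @param wavelet,levels Decomposition settings for the `wt` arm.
#' @param selection_rule `"auto"` (sign-consistency + threshold) or
#'   `"explicit"` (use `selection_overrides`).
#' @param threshold Minimum `|r|` for the auto rule.
#' @param selection_overrides Named list (per predictor) of
#'   `list(rule, levels)` as returned by [reference_component_selections()];
#'   consulted when `selection_rule = "explicit"`.
#' @param include_approximation Add `AL` to reconstructed features.
#' @param grid_size Grid preset passed to [default_grid()].
#' @param grids Optional named list of explicit grids per family (overrides
#'   `grid_size`).
#' @param test_fraction,repetitions,inner_train_fraction Split protocol.
#' @param seed Master seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(families = c("lr", "knn", "rf", "elm"),
                              combinations = names(input_combinations()),
                              arms = c("raw", "wt"),
                              wavelet = "db4", levels = 10L,
                              selection_rule = c("auto", "explicit"),
                              threshold = 0.08,
                              selection_overrides = NULL,
                              include_approximation = FALSE,
                              grid_size = "default",
                              grids = NULL,
                              test_fraction = 0.2, repetitions = 10L,
                              inner_train_fraction = 0.9, seed = 1L) {
  families <- match.arg(families, several.ok = TRUE)
  combinations <- match.arg(combinations, names(input_combinations()),
                            several.ok = TRUE)
  arms <- match.arg(arms, several.ok = TRUE)
  selection_rule <- match.arg(selection_rule)
  if (selection_rule == "explicit" && is.null(selection_overrides)) {
    stop("selection_rule = \"explicit\" requires `selection_overrides`")
  }
  structure(
    list(families = families, combinations = combinations, arms = arms,
         wavelet = wavelet, levels = as.integer(levels),
         selection_rule = selection_rule, threshold = threshold,
         selection_overrides = selection_overrides,
         include_approximation = include_approximation,
         grid_size = grid_size, grids = grids,
         test_fraction = test_fraction, repetitions = as.integer(repetitions),
         inner_train_fraction = inner_train_fraction, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Denoise every predictor of a dataset by wavelet sub-series selection
#'
#' Decomposes each predictor's full ordered series, correlates detail
#' sub-series with the NH3 series, selects levels (auto rule or explicit
#' override), and reconstructs the denoised feature. If the auto rule
#' selects no level for a predictor, all levels are kept (equivalent, up to
#' the near-constant approximation, to leaving the series undenoised).
#'
#' @param dataset Data frame with the standard columns.
#' @param config An [experiment_config()] (wavelet/selection settings used).
#' @return List: `features` (data frame of denoised predictors),
#'   `selections` (per-predictor `component_selection`), `decompositions`.
#' @export
denoise_predictors <- function(dataset, config = experiment_config()) {
  nh3 <- dataset$nh3
  out_feat <- dataset[predictor_names()]
  selections <- list()
  decomps <- list()
  for (vn in predictor_names()) {
    dec <- dwt_mra(dataset[[vn]], config$wavelet, config$levels)
    lev_cor <- subseries_correlations(dec, nh3)
    overall <- pearson_r(dataset[[vn]], nh3)
    ov <- config$selection_overrides[[vn]]
    sel <- if (config$selection_rule == "explicit" && !is.null(ov) &&
               identical(ov$rule, "explicit")) {
      component_selection(vn, lev_cor, overall, rule = "explicit",
                          levels = ov$levels)
    } else {
      component_selection(vn, lev_cor, overall, rule = "auto",
                          threshold = config$threshold)
    }
    if (length(sel$selected_levels) == 0) {
      message(sprintf("no level passed the rule for '%s'; keeping all levels", vn))
      sel <- component_selection(vn, lev_cor, overall, rule = "explicit",
                                 levels = seq_len(config$levels))
    }
    out_feat[[vn]] <- reconstruct_feature(dec, sel$selected_levels,
                                          config$include_approximation)
    selections[[vn]] <- sel
    decomps[[vn]] <- dec
  }
  list(features = out_feat, selections = selections, decompositions = decomps)
}

#' Run the full standalone-vs-hybrid experiment
#'
#' For every requested input combination x model family x arm: build the
#' feature block (raw series, or wavelet-denoised series for the `wt` arm),
#' tune hyperparameters by Monte-Carlo grid search on the training pool,
#' refit the winner on the whole pool, and report train/test MAE (ppm) and
#' Pearson R. A failing cell is reported as `NA` metrics without aborting
#' the rest.
#'
#' @param dataset Ordered data frame with the standard columns.
#' @param config An [experiment_config()].
#' @return Data frame (class `evaluation_report`), one row per cell, with
#'   the winning hyperparameters and metrics. The split plan and selections
#'   are attached as attributes.
#' @export
run_experiment <- function(dataset, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  combos <- input_combinations()[config$combinations]
  splits <- make_splits(nrow(dataset), config$test_fraction,
                        config$repetitions, config$inner_train_fraction,
                        seed = config$seed)
  denoised <- if ("wt" %in% config$arms) denoise_predictors(dataset, config)
  grids <- lapply(stats::setNames(nm = config$families), function(fam) {
    config$grids[[fam]] %||% default_grid(fam, config$grid_size)
  })

  rows <- list()
  for (combo_id in names(combos)) {
    for (arm in config$arms) {
      feat_src <- if (arm == "wt") denoised$features else dataset
      X <- .as_matrix(feat_src[combos[[combo_id]]])
      y <- dataset$nh3
      for (fam in config$families) {
        cell <- tryCatch({
          gs <- grid_search(fam, grids[[fam]], X, y, splits)
          tr <- splits$train_indices
          te <- splits$test_indices
          pred_tr <- .fit_predict_ppm(fam, gs$best_config,
                                      X[tr, , drop = FALSE], y[tr],
                                      X[tr, , drop = FALSE])
          pred_te <- .fit_predict_ppm(fam, gs$best_config,
                                      X[tr, , drop = FALSE], y[tr],
                                      X[te, , drop = FALSE])
          data.frame(
            combination = combo_id,
            inputs = paste(combos[[combo_id]], collapse = "+"),
            family = fam, arm = arm,
            hyperparameters = .config_label(fam, gs$best_config),
            validation_mae = gs$best_mae,
            train_mae = mae(y[tr], pred_tr),
            train_r = pearson_r(y[tr], pred_tr),
            test_mae = mae(y[te], pred_te),
            test_r = pearson_r(y[te], pred_te)
          )
        }, error = function(e) {
          message(sprintf("cell %s/%s/%s failed: %s", combo_id, fam, arm,
                          conditionMessage(e)))
          data.frame(combination = combo_id,
                     inputs = paste(combos[[combo_id]], collapse = "+"),
                     family = fam, arm = arm, hyperparameters = NA_character_,
                     validation_mae = NA_real_, train_mae = NA_real_,
                     train_r = NA_real_, test_mae = NA_real_,
                     test_r = NA_real_)
        })
        rows[[length(rows) + 1]] <- cell
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "split_plan") <- splits
  attr(report, "selections") <- denoised$selections
  attr(report, "config") <- config
  class(report) <- c("evaluation_report", "data.frame")
  report
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report A [run_experiment()] result.
#' @param path_csv,path_json Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) {
    utils::write.csv(as.data.frame(report), path_csv, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(as.data.frame(report), path_json, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(report)
}
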