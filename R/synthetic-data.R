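# Synthetic generator for ordered poultry-house microclimate records.
#
# The generator emulates the statistical structure the hybrid pipeline
# assumes: seven variables (litter moisture content, litter pH, litter
# surface temperature, air temperature, relative humidity, air velocity,
# and ammonia), marginal location/scale/bounds and skewness signs typical
# of commercial broiler-house measurements, a configurable signed
# correlation of each predictor with NH3, and band-limited noise injected
# into chosen wavelet-decomposition levels of selected predictors so that
# correlation-based sub-series selection measurably improves prediction.

.nh3_variables <- c("lmc", "lph", "lt", "t", "rh", "v")

.default_marginals <- function() {
  data.frame(
    variable = c(.nh3_variables, "nh3"),
    mean = c(30.69, 7.49, 27.87, 24.73, 64.66, 0.56, 19.38),
    sd = c(6.62, 0.54, 2.49, 3.32, 6.39, 0.54, 3.04),
    min = c(15.02, 6.02, 20.00, 19.10, 50.35, 0.11, 13.00),
    max = c(42.88, 8.34, 33.40, 32.44, 79.81, 2.10, 26.70),
    # shape parameter of the monotone exponential transform applied to the
    # latent Gaussian; its sign sets the skewness sign (air velocity is
    # strongly right-skewed, litter pH left-skewed).
    shape = c(-0.12, -0.45, -0.07, 0.00, 0.08, 0.70, 0.15),
    stringsAsFactors = FALSE
  )
}

.default_targets <- c(
  lmc = 0.720, lph = 0.547, lt = -0.398, t = 0.754, rh = 0.393, v = -0.224
)

.default_noise_levels <- list(
  lmc = integer(0), lph = integer(0), lt = c(1L, 2L),
  t = integer(0), rh = c(1L, 2L), v = c(1L, 2L)
)

# Relative amplitude (sd of injected band noise / sd of latent signal).
# Chosen so that removing the noisy levels raises each predictor-NH3
# correlation by about the margin seen between raw and wavelet-denoised
# series in field data.
.default_noise_amplitude <- c(lmc = 0, lph = 0, lt = 0.75, t = 0, rh = 0.62,
                              v = 1.65)

#' Configuration for the synthetic microclimate generator
#'
#' @param n_records Number of ordered records to generate (default 1600).
#'   Must be at least `2^levels` so a full wavelet decomposition is defined.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @param marginals Data frame with columns `variable, mean, sd, min, max,
#'   shape` for the six predictors and `nh3` (defaults emulate broiler-house
#'   training data).
#' @param target_correlations Named numeric vector (one per predictor), the
#'   signed Pearson correlation each raw predictor series should have with
#'   the NH3 series; each in (-1, 1).
#' @param noise_levels Named list mapping predictors to the decomposition
#'   levels into which independent band-limited noise is injected.
#' @param noise_amplitude Named numeric vector, sd of injected noise relative
#'   to the latent signal sd.
#' @param wavelet,levels Wavelet and level count used to synthesize the
#'   band-limited noise (and expected downstream).
#' @param factor_strength Correlation scale of the common environmental
#'   driver (controls predictor-predictor correlation); in (0, 1).
#' @param smoothness Gaussian kernel bandwidth (in samples) of the latent
#'   smooth series.
#' @param nonlinear_share Fraction of the non-predictable NH3 variance
#'   carried by a smooth nonlinear term (rest is white observation noise).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_records = 1600L,
                             seed = 42L,
                             marginals = .default_marginals(),
                             target_correlations = .default_targets,
                             noise_levels = .default_noise_levels,
                             noise_amplitude = .default_noise_amplitude,
                             wavelet = "db4",
                             levels = 10L,
                             factor_strength = 0.9,
                             smoothness = 4,
                             nonlinear_share = 0.35) {
  n_records <- as.integer(n_records)
  levels <- as.integer(levels)
  min_n <- 2L^levels
  if (n_records < min_n) {
    stop(sprintf(
      "n_records = %d is below the minimum %d (= 2^%d) required for a %d-level decomposition",
      n_records, min_n, levels, levels
    ))
  }
  stopifnot(
    is.data.frame(marginals),
    all(c("variable", "mean", "sd", "min", "max", "shape") %in% names(marginals)),
    all(c(.nh3_variables, "nh3") %in% marginals$variable),
    all(.nh3_variables %in% names(target_correlations)),
    all(abs(target_correlations[.nh3_variables]) < 1),
    factor_strength > 0, factor_strength < 1,
    nonlinear_share >= 0, nonlinear_share <= 1
  )
  structure(
    list(
      n_records = n_records, seed = as.integer(seed), marginals = marginals,
      target_correlations = target_correlations[.nh3_variables],
      noise_levels = lapply(noise_levels[.nh3_variables], as.integer),
      noise_amplitude = noise_amplitude[.nh3_variables],
      wavelet = wavelet, levels = levels,
      factor_strength = factor_strength, smoothness = smoothness,
      nonlinear_share = nonlinear_share
    ),
    class = "generator_config"
  )
}

# Run code under a seeded RNG without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Smooth standardized series: white noise circularly convolved with a
# Gaussian kernel, so latent energy sits in the coarse wavelet levels.
.smooth_series <- function(n, bandwidth) {
  w <- rnorm(n)
  half <- max(1L, ceiling(3 * bandwidth))
  kern <- exp(-0.5 * ((-half):half / bandwidth)^2)
  kern <- kern / sum(kern)
  idx <- outer(seq_len(n), (-half):half, function(i, j) ((i - 1 + j) %% n) + 1)
  y <- as.vector(matrix(w[idx], n) %*% kern)
  as.vector(scale(y))
}

# Band-limited noise: unit-variance coefficients placed only in the chosen
# detail levels of an otherwise empty wavelet pyramid, inverse-transformed.
.band_noise <- function(n, levels_set, wavelet, levels) {
  filt <- .wavelet_filter(wavelet)
  block <- 2^levels
  n_pad <- as.integer(block * ceiling(n / block))
  out <- numeric(n)
  for (lev in levels_set) {
    v <- rnorm(n_pad / 2^lev)
    v <- .idwt_step(numeric(length(v)), v, filt$lo, filt$hi)
    lev_up <- lev - 1L
    while (lev_up >= 1L) {
      v <- .idwt_step(v, numeric(length(v)), filt$lo, filt$hi)
      lev_up <- lev_up - 1L
    }
    out <- out + v[seq_len(n)]
  }
  out
}

# Monotone-increasing exponential shape transform; skewness sign = sign(k).
.shape_transform <- function(g, k) {
  if (abs(k) < 1e-8) g else expm1(k * g) / k
}

.std <- function(x) as.vector(scale(x))

#' Generate an ordered synthetic microclimate dataset
#'
#' Produces `n_records` ordered records of the six predictors plus NH3.
#' Construction: a smooth latent common driver and independent smooth
#' disturbances give each predictor a latent series with a single-factor
#' correlation structure; a monotone shape transform sets the skewness sign;
#' NH3 is a smooth deterministic function of the noise-free latent predictors
#' (a linear combination solved so the realized predictor-NH3 correlations
#' match the configured targets, plus a smooth nonlinear interaction term)
#' plus white observation noise; finally, independent band-limited noise is
#' injected into the configured wavelet levels of each predictor, and all
#' series are scaled to the configured units and clipped to their bounds.
#'
#' @param config A [generator_config()].
#' @return Data frame (class `nh3_dataset`) with columns
#'   `lmc, lph, lt, t, rh, v, nh3`, row order significant. Attributes:
#'   `config`, and `clip_fraction` (per-variable fraction of values clipped
#'   to the configured bounds).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    n <- config$n_records
    vars <- .nh3_variables
    marg <- config$marginals
    rownames(marg) <- marg$variable
    tgt <- config$target_correlations
    tau <- config$noise_amplitude
    # noiseless latent correlations needed so the *noisy* series hit the
    # targets: injected noise attenuates correlation by sqrt(1 + tau^2)
    rho <- tgt * sqrt(1 + tau^2)
    r <- config$factor_strength
    if (any(abs(rho) / r >= 0.98)) {
      stop("target correlations (after noise inflation) too strong for the configured factor_strength")
    }

    driver <- .smooth_series(n, config$smoothness)
    zmat <- sapply(vars, function(vn) {
      w <- rho[[vn]] / r
      .std(w * driver + sqrt(1 - w^2) * .smooth_series(n, config$smoothness))
    })
    # skewness-shaping, then restandardize
    zshaped <- sapply(vars, function(vn) {
      .std(.shape_transform(zmat[, vn], marg[vn, "shape"]))
    })

    # solve NH3 = Z v + extras so realized correlations equal rho exactly
    S <- stats::cor(zshaped)
    v <- solve(S, rho)
    q <- sum(rho * v)
    if (q >= 0.98) {
      stop("configured target correlations are jointly infeasible (explained variance >= 0.98)")
    }
    core <- drop(zshaped %*% v)

    resid_against <- function(x, basis) {
      .std(stats::lm.fit(cbind(1, basis), x)$residuals)
    }
    nonlin <- resid_against(zshaped[, "t"] * zshaped[, "rh"], zshaped)
    eps <- resid_against(rnorm(n), cbind(zshaped, nonlin))
    extra_var <- 1 - q
    nh3_std <- core +
      sqrt(config$nonlinear_share * extra_var) * nonlin +
      sqrt((1 - config$nonlinear_share) * extra_var) * eps

    # observed predictors: latent + band-limited noise, rescaled to unit sd
    out <- data.frame(matrix(NA_real_, n, 0))
    clip_frac <- numeric(0)
    for (vn in vars) {
      x <- zshaped[, vn]
      if (length(config$noise_levels[[vn]]) > 0 && tau[[vn]] > 0) {
        noise <- .band_noise(n, config$noise_levels[[vn]], config$wavelet,
                             config$levels)
        x <- x + tau[[vn]] * .std(noise)
        x <- x / sqrt(1 + tau[[vn]]^2)
      }
      phys <- marg[vn, "mean"] + marg[vn, "sd"] * x
      clipped <- pmin(pmax(phys, marg[vn, "min"]), marg[vn, "max"])
      clip_frac[[vn]] <- mean(clipped != phys)
      out[[vn]] <- clipped
    }
    phys_nh3 <- marg["nh3", "mean"] + marg["nh3", "sd"] * nh3_std
    nh3 <- pmin(pmax(phys_nh3, marg["nh3", "min"]), marg["nh3", "max"])
    clip_frac[["nh3"]] <- mean(nh3 != phys_nh3)
    out[["nh3"]] <- nh3

    structure(out, config = config, clip_fraction = clip_frac,
              class = c("nh3_dataset", "data.frame"))
  })
}

#' Descriptive statistics of a microclimate dataset
#'
#' @param dataset Data frame with the seven standard columns.
#' @return Data frame, one row per variable, with `min, max, mean, sd,
#'   skewness, kurtosis`. Skewness is the moment coefficient
#'   `m3 / m2^(3/2)`; kurtosis is excess kurtosis `m4 / m2^2 - 3`
#'   (negative for flatter-than-normal, near-uniform variables).
#' @export
summarize_dataset <- function(dataset) {
  stopifnot(is.data.frame(dataset), nrow(dataset) >= 1)
  num <- dataset[vapply(dataset, is.numeric, logical(1))]
  out <- data.frame(
    variable = names(num),
    min = vapply(num, min, numeric(1)),
    max = vapply(num, max, numeric(1)),
    mean = vapply(num, mean, numeric(1)),
    sd = vapply(num, stats::sd, numeric(1)),
    skewness = vapply(num, e1071::skewness, numeric(1), type = 1),
    kurtosis = vapply(num, e1071::kurtosis, numeric(1), type = 1),
    row.names = NULL
  )
  out
}

#' Write / read a dataset as CSV (with its generator config as JSON)
#'
#' The CSV has the fixed header `lmc,lph,lt,t,rh,v,nh3`, one record per row,
#' row order significant. When the dataset carries a `generator_config`
#' attribute it is written alongside as `<path>.json`.
#'
#' @param dataset An `nh3_dataset` (or plain data frame with the columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  cols <- c(.nh3_variables, "nh3")
  stopifnot(all(cols %in% names(dataset)))
  utils::write.csv(as.data.frame(dataset)[cols], path, row.names = FALSE)
  cfg <- attr(dataset, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(
      cfg[setdiff(names(cfg), "marginals")] |>
        c(list(marginals = cfg$marginals)),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  out <- utils::read.csv(path)
  cols <- c(.nh3_variables, "nh3")
  stopifnot(all(cols %in% names(out)))
  structure(out[cols], class = c("nh3_dataset", "data.frame"))
}

#' Names of the six predictor variables
#' @return `c("lmc", "lph", "lt", "t", "rh", "v")`.
#' @export
predictor_names <- function() .nh3_variables
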