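# Multilevel discrete wavelet decomposition (multiresolution analysis) of an
# ordered series. The transform is the classical periodized orthogonal DWT;
# each detail sub-series D1..DL and the approximation AL are reconstructed to
# full input length so that their elementwise sum reproduces the input.

# Standard orthonormal scaling-filter coefficients (Daubechies / Symlets),
# listed in ascending index order. The quadrature-mirror high-pass filter is
# derived from these at run time.
.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
          -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953),
  sym4 = c(0.0322231006040427, -0.012603967262037833, -0.09921954357684722,
           0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
           -0.02963552764599851, -0.07576571478927333),
  sym8 = c(0.0018899503327594609, -0.0003029205147213668, -0.01495225833704823,
           0.003808752013890615, 0.049137179673607506, -0.027219029917056003,
           -0.05194583810770904, 0.3644418948353314, 0.7771857517005235,
           0.4813596512583722, -0.061273359067658524, -0.1432942383508097,
           0.007607487324917605, 0.03169508781149298, -0.0005421323317911481,
           -0.0033824159510061256)
)

#' Supported mother wavelets
#'
#' @return Character vector of wavelet identifiers accepted by
#'   [dwt_mra()] (orthogonal Daubechies and Symlet families).
#' @export
wavelet_names <- function() names(.wavelet_filters)

.wavelet_filter <- function(name) {
  lo <- .wavelet_filters[[match.arg(name, names(.wavelet_filters))]]
  nf <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(nf) - 1)
  list(name = name, lo = lo, hi = hi)
}

# One periodized analysis step: x (even length) -> approximation and detail
# coefficients at the next coarser level.
.dwt_step <- function(x, lo, hi) {
  n <- length(x)
  n2 <- n %/% 2L
  nf <- length(lo)
  idx <- (outer(2L * (seq_len(n2) - 1L), seq_len(nf) - 1L, `+`) %% n) + 1L
  xm <- matrix(x[idx], n2, nf)
  list(a = drop(xm %*% lo), d = drop(xm %*% hi))
}

# Adjoint (inverse) step: coefficients at one level -> series of twice the
# length. For an orthonormal filter bank the adjoint is the exact inverse.
.idwt_step <- function(a, d, lo, hi) {
  n <- 2L * length(a)
  y <- numeric(n)
  k2 <- 2L * (seq_along(a) - 1L)
  for (i in seq_along(lo)) {
    pos <- ((k2 + (i - 1L)) %% n) + 1L
    y[pos] <- y[pos] + a * lo[i] + d * hi[i]
  }
  y
}

#' Maximum feasible decomposition level
#'
#' @param n Series length.
#' @return Largest `L` with `2^L <= n`.
#' @export
max_dwt_level <- function(n) floor(log2(max(n, 1)))

#' Multiresolution wavelet decomposition of an ordered series
#'
#' Decomposes a numeric series into `levels` full-length detail sub-series
#' `D1` (finest) to `DL` (coarsest) plus one approximation series `AL`, using
#' the periodized orthogonal discrete wavelet transform. Each detail series is
#' the inverse transform of that level's detail coefficients alone (all other
#' coefficients zeroed), so the components sum elementwise to the input
#' (the additive multiresolution identity).
#'
#' Series whose length is not a multiple of `2^levels` are internally extended
#' to the next such multiple by symmetric reflection of the tail before the
#' periodized transform; components are truncated back to the input length.
#' Truncation is linear, so the additive identity is preserved exactly.
#'
#' @param series Numeric vector, finite, `length(series) >= 2^levels`.
#' @param wavelet Mother-wavelet identifier, one of [wavelet_names()].
#'   Default `"db4"`.
#' @param levels Number of decomposition levels `L` (default 10).
#' @return Object of class `wavelet_mra`: list with `details` (an
#'   `n x levels` matrix, columns `D1..DL`), `approximation` (length-`n`
#'   vector `AL`), `wavelet`, `levels`, `boundary` (`"periodic"`), `n`.
#' @examples
#' m <- dwt_mra(sin(seq_len(256) / 10) + rnorm(256, sd = 0.1),
#'              wavelet = "db4", levels = 4)
#' reconstruction_residual(m, sin(seq_len(256) / 10) + 0) # large: wrong input
#' @export
dwt_mra <- function(series, wavelet = "db4", levels = 10L) {
  series <- as.numeric(series)
  n <- length(series)
  levels <- as.integer(levels)
  stopifnot(levels >= 1L)
  if (!all(is.finite(series))) {
    stop("`series` must be finite and free of missing values")
  }
  if (n < 2^levels) {
    stop(sprintf(
      "series of length %d supports at most %d decomposition levels (requested %d)",
      n, max_dwt_level(n), levels
    ))
  }
  filt <- .wavelet_filter(wavelet)

  block <- 2^levels
  n_pad <- as.integer(block * ceiling(n / block))
  x <- series
  if (n_pad > n) {
    x <- c(x, rev(x)[seq_len(n_pad - n)])
  }

  # forward pyramid
  d_coef <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    st <- .dwt_step(a, filt$lo, filt$hi)
    d_coef[[lev]] <- st$d
    a <- st$a
  }

  # reconstruct each component alone to full length
  up <- function(v, from_level, is_detail) {
    zero_d <- numeric(length(v))
    if (is_detail) {
      v <- .idwt_step(numeric(length(v)), v, filt$lo, filt$hi)
      from_level <- from_level - 1L
    }
    while (from_level >= 1L) {
      v <- .idwt_step(v, numeric(length(v)), filt$lo, filt$hi)
      from_level <- from_level - 1L
    }
    v
  }
  details <- vapply(
    seq_len(levels),
    function(lev) up(d_coef[[lev]], lev, TRUE)[seq_len(n)],
    numeric(n)
  )
  colnames(details) <- paste0("D", seq_len(levels))
  approx <- up(a, levels, FALSE)[seq_len(n)]

  structure(
    list(
      details = details,
      approximation = approx,
      wavelet = filt$name,
      levels = levels,
      boundary = "periodic",
      n = n
    ),
    class = "wavelet_mra"
  )
}

#' Maximum absolute reconstruction residual of a decomposition
#'
#' Validates the additive multiresolution identity: the elementwise sum of all
#' detail series plus the approximation must reproduce the original series.
#'
#' @param decomposition A [dwt_mra()] result.
#' @param original The series the decomposition was computed from.
#' @return `max(abs(original - (sum of details + approximation)))`.
#' @export
reconstruction_residual <- function(decomposition, original) {
  stopifnot(inherits(decomposition, "wavelet_mra"))
  original <- as.numeric(original)
  if (length(original) != decomposition$n) {
    stop(sprintf(
      "length mismatch: decomposition has %d rows, series has %d",
      decomposition$n, length(original)
    ))
  }
  recon <- rowSums(decomposition$details) + decomposition$approximation
  max(abs(original - recon))
}

#' @export
print.wavelet_mra <- function(x, ...) {
  cat(sprintf(
    "Wavelet MRA: %d levels (%s, %s boundary), series length %d\n",
    x$levels, x$wavelet, x$boundary, x$n
  ))
  cat(sprintf(
    "  detail sd, D1..D%d: %s\n", x$levels,
    paste(sprintf("%.3g", apply(x$details, 2, stats::sd)), collapse = " ")
  ))
  cat(sprintf("  approximation sd: %.3g\n", stats::sd(x$approximation)))
  invisible(x)
}

#' @export
as.data.frame.wavelet_mra <- function(x, ...) {
  out <- as.data.frame(x$details)
  out[[paste0("A", x$levels)]] <- x$approximation
  out
}
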