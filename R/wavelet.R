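#' Continuous Morlet wavelet transform
#'
#' Torrence & Compo-style CWT with the Morlet mother wavelet
#' (omega0 = 6 unless overridden) over dyadic scales s0 * 2^(j dj),
#' computed in Fourier space with zero-padding to the next power of two.
#' The cone of influence (COI) uses the e-folding time sqrt(2) s and is
#' reported in Fourier-period units.
#'
#' @param x numeric series, no NAs, n >= 32.
#' @param dt sampling interval (default 1).
#' @param dj scale resolution in octaves (default 1/12).
#' @param s0 smallest scale (default 2 dt).
#' @param max_scale largest scale (default n dt / 3).
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @param detrend remove a linear trend first (default TRUE).
#' @param standardize scale to unit variance first (default TRUE).
#' @return a `wavelet_spectrum`: complex `coefficients` (n_scale x n_time),
#'   `scales`, `periods` (Fourier periods), `times`, `coi` (max trustworthy
#'   period per time step), plus the transform parameters.
#' @export
cwt_morlet <- function(x, dt = 1, dj = 1 / 12, s0 = 2 * dt, max_scale = NULL,
                       omega0 = 6, detrend = TRUE, standardize = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x)) stop_arg("series contains NAs; mask or interpolate first")
  if (n < 32) stop_arg("need at least 32 samples for the CWT")
  if (detrend) x <- stats::lm.fit(cbind(1, seq_len(n)), x)$residuals
  if (standardize) {
    s <- stats::sd(x)
    if (s > 0) x <- x / s
  }
  if (is.null(max_scale)) max_scale <- n * dt / 3
  jmax <- max(1, floor(log2(max_scale / s0) / dj))
  scales <- s0 * 2^(dj * (0:jmax))

  npad <- 2^ceiling(log2(n))
  xpad <- c(x, rep(0, npad - n))
  xhat <- stats::fft(xpad)
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)

  # Morlet in Fourier space, one column per scale
  pos <- omega > 0
  M <- matrix(0 + 0i, npad, length(scales))
  for (j in seq_along(scales)) {
    psihat <- numeric(npad)
    psihat[pos] <- pi^(-1 / 4) * sqrt(2 * pi * scales[j] / dt) *
      exp(-(scales[j] * omega[pos] - omega0)^2 / 2)
    M[, j] <- xhat * psihat
  }
  W <- stats::mvfft(M, inverse = TRUE) / npad
  W <- t(W[seq_len(n), , drop = FALSE])   # n_scale x n_time

  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  coi <- fourier_factor / sqrt(2) * dt * pmin(seq_len(n) - 0.5,
                                              rev(seq_len(n)) - 0.5)
  structure(list(coefficients = W, scales = scales,
                 periods = fourier_factor * scales,
                 times = seq_len(n) * dt, coi = coi,
                 dt = dt, dj = dj, omega0 = omega0, n = n),
            class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> %d scales (%.1f-%.1f period) x %d times\n",
              length(x$scales), min(x$periods), max(x$periods), x$n))
  invisible(x)
}

# in-COI mask: TRUE where the Fourier period is shorter than the COI limit
in_coi_mask <- function(spec_or_res) {
  outer(spec_or_res$periods, spec_or_res$coi, "<=")
}

# smoothing operator of the coherence estimator: Gaussian of std s along
# time (per scale, via FFT), then a boxcar of 0.6 octaves along scale.
smooth_time <- function(W, scales, dt) {
  n <- ncol(W)
  npad <- 2^ceiling(log2(2 * n))
  Z <- matrix(0 + 0i, npad, nrow(W))
  Z[seq_len(n), ] <- t(W)
  Zhat <- stats::mvfft(Z)
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
  for (j in seq_len(nrow(W))) {
    Zhat[, j] <- Zhat[, j] * exp(-0.5 * (scales[j] * omega)^2)
  }
  S <- stats::mvfft(Zhat, inverse = TRUE) / npad
  t(S[seq_len(n), , drop = FALSE])
}

smooth_scale <- function(W, dj, dj0 = 0.6) {
  m <- max(1L, round(dj0 / dj))
  if (m %% 2 == 0) m <- m + 1L
  half <- (m - 1L) %/% 2L
  ns <- nrow(W)
  out <- W
  for (j in seq_len(ns)) {
    idx <- max(1, j - half):min(ns, j + half)
    out[j, ] <- colMeans(W[idx, , drop = FALSE])
  }
  out
}

smooth_spectrum <- function(W, scales, dt, dj) {
  smooth_scale(smooth_time(W, scales, dt), dj)
}

#' Cross wavelet transform
#'
#' W_xy = W_x conj(W_y): common power of two series and their relative
#' phase in time-frequency space. Positive phase at a point means the
#' second series lags the first there.
#'
#' @param x_spec,y_spec `wavelet_spectrum`s on identical scale/time axes.
#' @return a `coherence_result` with `cross_power` (|W_xy|), `phase`
#'   (Arg W_xy), `scales`, `periods`, `times`, `coi`; `coherence` is NULL
#'   (see [wtc()]).
#' @export
xwt <- function(x_spec, y_spec) {
  stopifnot(inherits(x_spec, "wavelet_spectrum"),
            inherits(y_spec, "wavelet_spectrum"))
  if (!isTRUE(all.equal(x_spec$scales, y_spec$scales)) ||
      x_spec$n != y_spec$n || x_spec$dt != y_spec$dt) {
    stop_arg("wavelet spectra are on different scale/time axes")
  }
  Wxy <- x_spec$coefficients * Conj(y_spec$coefficients)
  structure(list(cross_power = Mod(Wxy), phase = Arg(Wxy),
                 coherence = NULL, significance = NULL,
                 scales = x_spec$scales, periods = x_spec$periods,
                 times = x_spec$times, coi = x_spec$coi,
                 dt = x_spec$dt, dj = x_spec$dj),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> %d scales x %d times%s%s\n",
              length(x$scales), length(x$times),
              if (!is.null(x$coherence)) ", coherence" else "",
              if (!is.null(x$significance)) ", significance mask" else ""))
  invisible(x)
}

# lag-1 autocorrelation, capped below 1 for surrogate stationarity
estimate_ar1 <- function(x) {
  n <- length(x)
  a <- stats::cor(x[-1], x[-n])
  if (!is.finite(a)) a <- 0
  if (a >= 1) {
    warning("AR(1) estimate >= 1; falling back to 0.99")
    a <- 0.99
  }
  max(a, 0)
}

# coherence and smoothed-cross-spectrum phase for two spectra
coherence_core <- function(x_spec, y_spec) {
  s_inv <- 1 / x_spec$scales
  Wx2 <- s_inv * Mod(x_spec$coefficients)^2
  Wy2 <- s_inv * Mod(y_spec$coefficients)^2
  Wxy <- s_inv * (x_spec$coefficients * Conj(y_spec$coefficients))
  Sx <- Re(smooth_spectrum(Wx2, x_spec$scales, x_spec$dt, x_spec$dj))
  Sy <- Re(smooth_spectrum(Wy2, x_spec$scales, x_spec$dt, x_spec$dj))
  Sxy <- smooth_spectrum(Wxy, x_spec$scales, x_spec$dt, x_spec$dj)
  den <- Sx * Sy
  r2 <- Mod(Sxy)^2 / den
  r2[den <= 0] <- NA_real_
  r2 <- pmin(r2, 1)   # guard against rounding a hair above 1
  list(r2 = r2, phase = Arg(Sxy))
}

#' Wavelet coherence with red-noise Monte-Carlo significance
#'
#' Localized squared correlation R2 in time-frequency space between two
#' series: the smoothed cross-spectrum modulus squared over the product of
#' the smoothed individual power spectra, each pre-weighted by 1/s. The
#' smoothing operator is a Gaussian of width s in time composed with a
#' 0.6-octave boxcar in scale (the Morlet decorrelation length).
#' Significance at each (scale, time) cell is assessed against
#' `n_surrogates` AR(1) surrogate pairs matching each input's lag-1
#' autocorrelation and variance: the mask flags observed R2 above the null
#' 95th percentile.
#'
#' @param x,y aligned numeric series (no NAs).
#' @param dt sampling interval (default 1).
#' @param dj scale resolution (default 1/12).
#' @param s0,max_scale,omega0 passed to [cwt_morlet()].
#' @param n_surrogates AR(1) surrogate pairs for the null (default 300;
#'   0 skips the significance mask).
#' @param seed RNG seed for the surrogates.
#' @param quantile_level null quantile defining significance (default 0.95).
#' @return a `coherence_result` with `coherence` (R2), `phase`,
#'   `cross_power`, `significance` (logical matrix or NULL),
#'   `sig_threshold`, `ar1` (the two fitted coefficients), `scales`,
#'   `periods`, `times`, `coi`.
#' @export
wtc <- function(x, y, dt = 1, dj = 1 / 12, s0 = 2 * dt, max_scale = NULL,
                omega0 = 6, n_surrogates = 300, seed = 1L,
                quantile_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_arg("series must be aligned")
  xs <- cwt_morlet(x, dt, dj, s0, max_scale, omega0)
  ys <- cwt_morlet(y, dt, dj, s0, max_scale, omega0)
  cc <- coherence_core(xs, ys)
  res <- structure(list(
    coherence = cc$r2, phase = cc$phase,
    cross_power = Mod(xs$coefficients * Conj(ys$coefficients)),
    significance = NULL, sig_threshold = NULL,
    ar1 = c(x = estimate_ar1(x), y = estimate_ar1(y)),
    scales = xs$scales, periods = xs$periods, times = xs$times,
    coi = xs$coi, dt = dt, dj = dj
  ), class = "coherence_result")

  if (n_surrogates > 0) {
    thr <- wtc_null_threshold(length(x), res$ar1["x"], res$ar1["y"],
                              sd_x = stats::sd(x), sd_y = stats::sd(y),
                              dt = dt, dj = dj, s0 = s0,
                              max_scale = max_scale, omega0 = omega0,
                              n_surrogates = n_surrogates, seed = seed,
                              quantile_level = quantile_level)
    res$sig_threshold <- thr
    res$significance <- cc$r2 > thr
  }
  res
}

#' Null coherence threshold from AR(1) surrogate pairs
#'
#' Per-(scale, time) quantile of wavelet coherence under independent AR(1)
#' pairs with the given lag-1 coefficients and standard deviations — the
#' red-noise null the significance mask is tested against. Exposed so a
#' threshold can be reused across several observed pairs with the same
#' null.
#'
#' @param n series length.
#' @param ar1_x,ar1_y lag-1 coefficients of the two null processes.
#' @param sd_x,sd_y marginal standard deviations (default 1).
#' @param dt,dj,s0,max_scale,omega0 transform parameters as in [wtc()].
#' @param n_surrogates number of surrogate pairs (default 300).
#' @param seed RNG seed.
#' @param quantile_level null quantile (default 0.95).
#' @return numeric matrix (n_scale x n_time) of thresholds.
#' @export
wtc_null_threshold <- function(n, ar1_x, ar1_y, sd_x = 1, sd_y = 1, dt = 1,
                               dj = 1 / 12, s0 = 2 * dt, max_scale = NULL,
                               omega0 = 6, n_surrogates = 300, seed = 1L,
                               quantile_level = 0.95) {
  probe <- cwt_morlet(stats::rnorm(n), dt, dj, s0, max_scale, omega0)
  ns <- length(probe$scales); ntm <- n
  null_r2 <- matrix(NA_real_, ns * ntm, n_surrogates)
  with_seed(seed, {
    for (b in seq_len(n_surrogates)) {
      sx <- as.numeric(ar1_noise_matrix(n, 1L, ar1_x, max(sd_x, 1e-12)))
      sy <- as.numeric(ar1_noise_matrix(n, 1L, ar1_y, max(sd_y, 1e-12)))
      cc <- coherence_core(cwt_morlet(sx, dt, dj, s0, max_scale, omega0),
                           cwt_morlet(sy, dt, dj, s0, max_scale, omega0))
      null_r2[, b] <- as.numeric(cc$r2)
    }
  })
  k <- ceiling(quantile_level * n_surrogates)
  thr <- vapply(seq_len(nrow(null_r2)), function(i) {
    v <- null_r2[i, ]
    sort(v, partial = k)[k]
  }, numeric(1))
  matrix(thr, ns, ntm)
}

#' Fraction of in-COI cells flagged significant
#'
#' Headline statistics are reported for the region where edge effects are
#' negligible; this helper measures the significant share of that region.
#'
#' @param res a `coherence_result` with a significance mask.
#' @param coherence_min additionally require coherence above this value
#'   (default 0, i.e. mask only).
#' @return fraction in \[0, 1\].
#' @export
significant_area_fraction <- function(res, coherence_min = 0) {
  stopifnot(inherits(res, "coherence_result"))
  if (is.null(res$significance)) stop_arg("result has no significance mask")
  inc <- in_coi_mask(res)
  sel <- inc & is.finite(res$coherence)
  hits <- res$significance & res$coherence >= coherence_min
  sum(hits[sel], na.rm = TRUE) / sum(sel)
}

#' Circular mean of the in-COI phase where coherence is high
#'
#' Summarizes the dominant phase relationship (0 = in phase, +/-pi =
#' anti-phase), following the convention of drawing phase arrows only
#' where coherence exceeds 0.5.
#'
#' @param res a `coherence_result` with coherence populated.
#' @param coherence_min coherence cutoff (default 0.5).
#' @return mean phase angle in (-pi, pi\], or NA if no cell qualifies.
#' @export
dominant_phase <- function(res, coherence_min = 0.5) {
  stopifnot(inherits(res, "coherence_result"))
  if (is.null(res$coherence)) stop_arg("result has no coherence")
  sel <- in_coi_mask(res) & is.finite(res$coherence) &
    res$coherence >= coherence_min
  if (!any(sel)) return(NA_real_)
  ph <- res$phase[sel]
  atan2(mean(sin(ph)), mean(cos(ph)))
}
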