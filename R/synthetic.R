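#' Configuration for the synthetic weekly-cube generator
#'
#' Defaults emulate the climatology the analysis assumes: a single annual
#' NDVI harmonic peaking in early August (calendar week 32) at about 0.40
#' and bottoming in winter at about 0.11, a brightness-temperature (BT)
#' cycle peaking in summer, weekly AR(1) pixel noise, optional linear
#' trends, optional coupling of BT to an ENSO-like index, and a
#' missing-data mask. A year is exactly 52 weekly composites.
#'
#' @param n_years number of years (>= 3; climatology extrema need several).
#' @param n_lat,n_lon grid dimensions.
#' @param seasonal_ndvi_baseline,seasonal_ndvi_amplitude annual-mean NDVI
#'   and harmonic amplitude (unitless).
#' @param seasonal_bt_mean,seasonal_bt_amplitude BT annual mean and
#'   harmonic amplitude (degC).
#' @param noise_ar1_coeff lag-1 autocorrelation of the weekly pixel noise,
#'   in [0, 1).
#' @param noise_sd_ndvi,noise_sd_bt marginal standard deviation of the
#'   pixel noise (NDVI units / degC).
#' @param trend_ndvi_per_year,trend_bt_per_year linear trends (units/year).
#' @param enso_coupling_bt degC of BT response per unit of the ENSO-like
#'   index (applied to every pixel when nonzero).
#' @param enso_ar1,enso_period_years,enso_amplitude parameters forwarded to
#'   [generate_enso_like()]: AR(1) coefficient, period (years) and
#'   amplitude of the interannual sinusoid.
#' @param missing_fraction fraction of cube cells invalidated, in [0, 1).
#' @param rng_seed integer seed; identical config + seed gives identical
#'   output.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_years = 10, n_lat = 8, n_lon = 8,
                             seasonal_ndvi_baseline = 0.255,
                             seasonal_ndvi_amplitude = 0.145,
                             seasonal_bt_mean = 13,
                             seasonal_bt_amplitude = 15.5,
                             noise_ar1_coeff = 0.6,
                             noise_sd_ndvi = 0.02,
                             noise_sd_bt = 0.8,
                             trend_ndvi_per_year = 0,
                             trend_bt_per_year = 0,
                             enso_coupling_bt = 0,
                             enso_ar1 = 0.9,
                             enso_period_years = 4,
                             enso_amplitude = 0.8,
                             missing_fraction = 0,
                             rng_seed = 1L) {
  if (n_years < 3) stop_arg("n_years must be >= 3 (climatology extrema need multiple years)")
  if (n_lat < 1 || n_lon < 1) stop_arg("degenerate grid: need at least one pixel")
  check_scalar_in(noise_ar1_coeff, 0, 1, "noise_ar1_coeff", hi_open = TRUE)
  check_scalar_in(missing_fraction, 0, 1, "missing_fraction", hi_open = TRUE)
  structure(
    list(n_years = as.integer(n_years), n_lat = as.integer(n_lat),
         n_lon = as.integer(n_lon),
         seasonal_ndvi_baseline = seasonal_ndvi_baseline,
         seasonal_ndvi_amplitude = seasonal_ndvi_amplitude,
         seasonal_bt_mean = seasonal_bt_mean,
         seasonal_bt_amplitude = seasonal_bt_amplitude,
         noise_ar1_coeff = noise_ar1_coeff,
         noise_sd_ndvi = noise_sd_ndvi, noise_sd_bt = noise_sd_bt,
         trend_ndvi_per_year = trend_ndvi_per_year,
         trend_bt_per_year = trend_bt_per_year,
         enso_coupling_bt = enso_coupling_bt,
         enso_ar1 = enso_ar1, enso_period_years = enso_period_years,
         enso_amplitude = enso_amplitude,
         missing_fraction = missing_fraction,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_config"
  )
}

#' Specify an embedded drought episode
#'
#' A multi-week episode that depresses NDVI and elevates BT over a
#' contiguous block of global week indices in a fraction of the grid.
#' The affected pixels are the first `round(spatial_extent * n_pixels)`
#' pixels in row-major order, so the selection is deterministic and
#' independent of the noise stream.
#'
#' @param start_week,end_week global week indices (1-based, inclusive).
#' @param ndvi_depression NDVI decrease (>= 0).
#' @param bt_elevation BT increase in degC (>= 0).
#' @param spatial_extent fraction of pixels affected, in [0, 1].
#' @return a `drought_episode` list.
#' @export
drought_episode <- function(start_week, end_week, ndvi_depression = 0.15,
                            bt_elevation = 3, spatial_extent = 1) {
  if (start_week > end_week) stop_arg("episode start must not exceed end")
  if (ndvi_depression < 0 || bt_elevation < 0) {
    stop_arg("episode depression/elevation must be non-negative")
  }
  check_scalar_in(spatial_extent, 0, 1, "spatial_extent")
  structure(list(start_week = as.integer(start_week),
                 end_week = as.integer(end_week),
                 ndvi_depression = ndvi_depression,
                 bt_elevation = bt_elevation,
                 spatial_extent = spatial_extent),
            class = "drought_episode")
}

# marginal-sd-preserving AR(1) noise, one column per pixel
ar1_noise_matrix <- function(n, p, phi, sd) {
  if (sd == 0) return(matrix(0, n, p))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- matrix(stats::rnorm(n * p, sd = innov_sd), n, p)
  if (phi > 0) {
    e <- apply(e, 2, function(col) {
      as.numeric(stats::filter(col, phi, method = "recursive"))
    })
    e <- matrix(e, n, p)
  }
  e
}

seasonal_cycle <- function(weeks, baseline, amplitude, peak_week) {
  baseline + amplitude * cos(2 * pi * (weeks - peak_week) / 52)
}

#' Generate synthetic NDVI and BT cubes plus an ENSO-like index
#'
#' Each pixel series is seasonal harmonic + linear trend + AR(1) noise
#' (+ ENSO coupling for BT) + episode anomalies, with NDVI clipped to
#' \[-1, 1\] after episode injection. NDVI peaks at calendar week 32, BT
#' at week 28.
#'
#' @param config a [synthetic_config()].
#' @param episodes list of [drought_episode()] specs (may be empty).
#' @return a list with elements `ndvi` and `bt` (`weekly_cube`s), `enso`
#'   (a `climate_index` from [generate_enso_like()]), and `n_clipped`
#'   (count of NDVI cells clipped to range).
#' @export
generate_fields <- function(config, episodes = list()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (inherits(episodes, "drought_episode")) episodes <- list(episodes)
  nt <- config$n_years * 52L
  p <- config$n_lat * config$n_lon
  week <- rep(1:52, config$n_years)
  year <- rep(seq_len(config$n_years), each = 52L)
  for (ep in episodes) {
    if (ep$start_week < 1L || ep$end_week > nt) {
      stop_arg("episode weeks [", ep$start_week, ", ", ep$end_week,
               "] fall outside the 1..", nt, " time range")
    }
  }

  t_years <- (seq_len(nt) - 1) / 52
  ndvi_seas <- seasonal_cycle(seq_len(nt), config$seasonal_ndvi_baseline,
                              config$seasonal_ndvi_amplitude, peak_week = 32)
  bt_seas <- seasonal_cycle(seq_len(nt), config$seasonal_bt_mean,
                            config$seasonal_bt_amplitude, peak_week = 28)

  out <- with_seed(config$rng_seed, {
    enso <- generate_enso_like(
      n_weeks = nt, ar1 = config$enso_ar1,
      periodic_component = c(config$enso_period_years, config$enso_amplitude),
      rng_seed = config$rng_seed + 1000L
    )
    ndvi <- matrix(ndvi_seas + config$trend_ndvi_per_year * t_years, nt, p) +
      ar1_noise_matrix(nt, p, config$noise_ar1_coeff, config$noise_sd_ndvi)
    bt <- matrix(bt_seas + config$trend_bt_per_year * t_years +
                   config$enso_coupling_bt * enso$values, nt, p) +
      ar1_noise_matrix(nt, p, config$noise_ar1_coeff, config$noise_sd_bt)
    mask <- matrix(TRUE, nt, p)
    n_missing <- round(config$missing_fraction * nt * p)
    if (n_missing > 0) mask[sample.int(nt * p, n_missing)] <- FALSE
    list(enso = enso, ndvi = ndvi, bt = bt, mask = mask)
  })

  for (ep in episodes) {
    n_aff <- round(ep$spatial_extent * p)
    if (n_aff == 0) next
    rows <- ep$start_week:ep$end_week
    cols <- seq_len(n_aff)
    out$ndvi[rows, cols] <- out$ndvi[rows, cols] - ep$ndvi_depression
    out$bt[rows, cols] <- out$bt[rows, cols] + ep$bt_elevation
  }
  n_clipped <- sum(out$ndvi < -1 | out$ndvi > 1)
  out$ndvi <- pmin(pmax(out$ndvi, -1), 1)

  shape <- c(nt, config$n_lat, config$n_lon)
  mask_arr <- array(out$mask, shape)
  list(
    ndvi = weekly_cube(array(out$ndvi, shape), year, week, mask = mask_arr,
                       tag = "NDVI"),
    bt = weekly_cube(array(out$bt, shape), year, week, mask = mask_arr,
                     tag = "BT"),
    enso = out$enso,
    n_clipped = n_clipped
  )
}

#' Generate an ENSO-like weekly climate index
#'
#' Zero-mean AR(1) noise plus an optional interannual sinusoid, mimicking
#' a sea-surface-temperature anomaly index with 2-7-year band power.
#'
#' @param n_weeks series length (>= 104).
#' @param ar1 AR(1) coefficient in [0, 1).
#' @param periodic_component length-2 numeric `c(period_years, amplitude)`;
#'   amplitude 0 disables the sinusoid.
#' @param rng_seed integer seed.
#' @param noise_sd marginal sd of the AR(1) component (default 0.5).
#' @return a `climate_index` list with `times` (global week index) and
#'   `values`.
#' @export
generate_enso_like <- function(n_weeks, ar1 = 0.9,
                               periodic_component = c(4, 0.8),
                               rng_seed = 1L, noise_sd = 0.5) {
  if (n_weeks < 104) stop_arg("n_weeks must be >= 104 (two years)")
  if (ar1 >= 1) stop_arg("ar1 must be < 1 (stationarity)")
  if (ar1 < 0) stop_arg("ar1 must be >= 0")
  period_years <- periodic_component[1]
  amplitude <- periodic_component[2]
  vals <- with_seed(rng_seed, {
    as.numeric(ar1_noise_matrix(n_weeks, 1L, ar1, noise_sd))
  })
  if (amplitude != 0) {
    vals <- vals + amplitude * sin(2 * pi * seq_len(n_weeks) / (period_years * 52))
  }
  structure(list(times = seq_len(n_weeks), values = vals),
            class = "climate_index")
}

#' @export
print.climate_index <- function(x, ...) {
  cat(sprintf("<climate_index> %d weekly values, mean %.3f, sd %.3f\n",
              length(x$values), mean(x$values), stats::sd(x$values)))
  invisible(x)
}
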