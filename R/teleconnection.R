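#' Per-pixel Pearson correlation map against a climate index
#'
#' Correlates every pixel series of a cube (typically a VHI/VCI/TCI cube
#' restricted to the growing season) with a climate index aligned to the
#' same time steps, and summarizes the share of positively and negatively
#' correlated grid cells.
#'
#' @param cube a `weekly_cube`.
#' @param index a `climate_index` or numeric vector aligned to the cube's
#'   time steps.
#' @param weeks optional calendar weeks to restrict to (e.g. the growing
#'   season); the index must cover the cube's full axis and is subset the
#'   same way.
#' @param min_pairs minimum aligned valid pairs per pixel (default 3).
#' @return a `correlation_map` list: `r` (per-pixel vector, NA where under
#'   `min_pairs`), `fraction_positive`, `fraction_negative` (percent of
#'   valid pixels with r > 0 / r < 0), `n_valid_pixels`.
#' @export
pearson_map <- function(cube, index, weeks = NULL, min_pairs = 3) {
  stopifnot(inherits(cube, "weekly_cube"))
  vals <- if (inherits(index, "climate_index")) index$values else as.numeric(index)
  if (length(vals) != n_time(cube)) {
    stop_arg("index length (", length(vals), ") must match the cube time axis (",
             n_time(cube), ")")
  }
  if (!is.null(weeks)) {
    keep <- cube$week %in% weeks
    cube <- subset_weeks(cube, weeks)
    vals <- vals[keep]
  }
  m <- cube_matrix(cube)
  r <- vapply(seq_len(ncol(m)), function(j) {
    ok <- is.finite(m[, j]) & is.finite(vals)
    if (sum(ok) < min_pairs) return(NA_real_)
    sx <- stats::sd(m[ok, j]); sy <- stats::sd(vals[ok])
    if (sx == 0 || sy == 0) return(NA_real_)
    stats::cor(m[ok, j], vals[ok])
  }, numeric(1))
  valid <- is.finite(r) & r != 0
  nv <- sum(valid)
  structure(list(
    r = r,
    fraction_positive = if (nv) 100 * sum(r[valid] > 0) / nv else NA_real_,
    fraction_negative = if (nv) 100 * sum(r[valid] < 0) / nv else NA_real_,
    n_valid_pixels = nv
  ), class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf(
    "<correlation_map> %d pixels: %.1f%% positive, %.1f%% negative, r in [%.3f, %.3f]\n",
    x$n_valid_pixels, x$fraction_positive, x$fraction_negative,
    min(x$r, na.rm = TRUE), max(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Linear and wavelet teleconnection of a regional index series
#'
#' Convenience wrapper running both halves of the teleconnection analysis
#' for one index cube: the per-pixel Pearson map and the wavelet coherence
#' of the regional-mean series with the climate index.
#'
#' @param cube a `weekly_cube` (VCI/TCI/VHI).
#' @param index a `climate_index` on the cube's full weekly axis.
#' @param weeks optional growing-season calendar weeks for the Pearson map.
#' @param n_surrogates surrogate pairs for the coherence significance.
#' @param seed RNG seed for the surrogates.
#' @return list with `pearson` (a `correlation_map`), `coherence` (a
#'   `coherence_result`), and `dominant_phase` (radians).
#' @export
teleconnection_summary <- function(cube, index, weeks = NULL,
                                   n_surrogates = 100, seed = 1L) {
  pm <- pearson_map(cube, index, weeks = weeks)
  reg <- regional_mean(cube)
  vals <- if (inherits(index, "climate_index")) index$values else as.numeric(index)
  ok <- is.finite(reg)
  res <- wtc(vals[ok], reg[ok], dt = 1 / 52, n_surrogates = n_surrogates,
             seed = seed)
  list(pearson = pm, coherence = res, dominant_phase = dominant_phase(res))
}
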