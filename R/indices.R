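#' Temporal smoothing of weekly NDVI/BT (SMN / SMT)
#'
#' The operational vegetation-health product removes high-frequency noise
#' from NDVI and BT before any index is computed; the exact operational
#' procedure is empirical, so this package provides a documented stand-in:
#' per-pixel median-of-3 despiking followed by a centered moving average
#' with triangular weights. Masked cells are skipped and the kernel is
#' renormalized over the valid support; the mask is propagated.
#'
#' @param raw a `weekly_cube` tagged "NDVI" or "BT".
#' @param window_weeks odd window length >= 3 (default 5).
#' @return a `weekly_cube` tagged "SMN" (from NDVI) or "SMT" (from BT).
#' @export
smooth_series <- function(raw, window_weeks = 5) {
  stopifnot(inherits(raw, "weekly_cube"))
  if (!(raw$tag %in% c("NDVI", "BT"))) {
    stop_arg("smooth_series expects a raw NDVI or BT cube")
  }
  if (window_weeks < 3 || window_weeks %% 2 == 0) {
    stop_arg("window_weeks must be odd and >= 3")
  }
  m <- cube_matrix(raw)
  half <- (window_weeks - 1) / 2
  w <- half + 1 - abs(seq(-half, half))   # triangular weights 1..half+1..1
  sm <- apply(m, 2, smooth_one_series, w = w, half = half)
  sm <- matrix(sm, nrow(m), ncol(m))
  n_all_missing <- sum(colSums(is.finite(m)) == 0)
  if (n_all_missing > 0) {
    warning(n_all_missing, " fully-masked pixel(s) remain masked after smoothing")
  }
  cube_from_matrix(sm, raw, tag = if (raw$tag == "NDVI") "SMN" else "SMT",
                   units = raw$units)
}

smooth_one_series <- function(x, w, half) {
  ok <- is.finite(x)
  if (!any(ok)) return(rep(NA_real_, length(x)))
  # median-of-3 despiking on the valid values, in place
  v <- x[ok]
  if (length(v) >= 3) v <- stats::runmed(v, 3, endrule = "keep")
  d <- x
  d[ok] <- v
  n <- length(d)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    j <- max(1, i - half):min(n, i + half)
    wj <- w[j - i + half + 1]
    keep <- is.finite(d[j])
    out[i] <- sum(wj[keep] * d[j][keep]) / sum(wj[keep])
  }
  out
}

#' Per-pixel, per-calendar-week climatology extrema
#'
#' For each pixel and calendar week, the multi-year maximum and minimum of
#' the smoothed field — the envelope against which VCI/TCI normalize.
#' With `per_week = FALSE` the extrema are instead taken over the whole
#' record (one envelope per pixel, the "absolute" reading).
#'
#' @param smoothed a `weekly_cube` tagged "SMN" or "SMT".
#' @param per_week key extrema to the calendar week (default) or to the
#'   whole record.
#' @return a `climatology_extrema` list with `vmax`, `vmin` (52 x n_pix
#'   matrices; rows recycled when `per_week = FALSE`), `degenerate`
#'   (logical, max == min), and `tag`.
#' @export
climatology_extrema <- function(smoothed, per_week = TRUE) {
  stopifnot(inherits(smoothed, "weekly_cube"))
  if (length(unique(smoothed$year)) < 3) {
    stop_arg("climatology extrema need at least 3 distinct years")
  }
  m <- cube_matrix(smoothed)
  p <- ncol(m)
  vmax <- matrix(NA_real_, 52, p)
  vmin <- matrix(NA_real_, 52, p)
  if (per_week) {
    for (w in 1:52) {
      rows <- which(smoothed$week == w)
      if (!length(rows)) next
      sub <- m[rows, , drop = FALSE]
      vmax[w, ] <- suppressWarnings(apply(sub, 2, max, na.rm = TRUE))
      vmin[w, ] <- suppressWarnings(apply(sub, 2, min, na.rm = TRUE))
    }
    vmax[!is.finite(vmax)] <- NA_real_
    vmin[!is.finite(vmin)] <- NA_real_
  } else {
    gmax <- suppressWarnings(apply(m, 2, max, na.rm = TRUE))
    gmin <- suppressWarnings(apply(m, 2, min, na.rm = TRUE))
    gmax[!is.finite(gmax)] <- NA_real_
    gmin[!is.finite(gmin)] <- NA_real_
    vmax <- matrix(gmax, 52, p, byrow = TRUE)
    vmin <- matrix(gmin, 52, p, byrow = TRUE)
  }
  structure(list(vmax = vmax, vmin = vmin,
                 degenerate = vmax == vmin, tag = smoothed$tag,
                 per_week = per_week),
            class = "climatology_extrema")
}

# shared normalization core: 100 * (x - lo) / (hi - lo), clipped to [0,100]
normalize_index <- function(cube, extrema, reverse, tag) {
  stopifnot(inherits(cube, "weekly_cube"),
            inherits(extrema, "climatology_extrema"))
  m <- cube_matrix(cube)
  hi <- extrema$vmax[cube$week, , drop = FALSE]
  lo <- extrema$vmin[cube$week, , drop = FALSE]
  rng <- hi - lo
  rng[rng <= 0] <- NA_real_   # degenerate pixels are masked, never divided
  idx <- if (reverse) 100 * ((hi - m) / rng) else 100 * ((m - lo) / rng)
  n_clipped <- sum(idx < -1e-9 | idx > 100 + 1e-9, na.rm = TRUE)
  idx <- pmin(pmax(idx, 0), 100)
  out <- cube_from_matrix(idx, cube, tag = tag, units = "index [0,100]")
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Vegetation Condition Index
#'
#' VCI = 100 (SMN - SMN_min) / (SMN_max - SMN_min), the smoothed-NDVI
#' anomaly rescaled to \[0, 100\] between the multi-year extrema; a proxy
#' for moisture condition. Values outside the envelope (a record applied
#' to an older climatology) are clipped to \[0, 100\] and counted in the
#' `n_clipped` attribute.
#'
#' @param smn a `weekly_cube` tagged "SMN".
#' @param extrema [climatology_extrema()] of the same (or a superset) record.
#' @return a `weekly_cube` tagged "VCI".
#' @export
compute_vci <- function(smn, extrema) {
  if (smn$tag != "SMN" || extrema$tag != "SMN") {
    stop_arg("compute_vci expects an SMN cube and SMN extrema")
  }
  normalize_index(smn, extrema, reverse = FALSE, tag = "VCI")
}

#' Temperature Condition Index
#'
#' TCI = 100 (SMT_max - SMT) / (SMT_max - SMT_min): hot conditions map to
#' low TCI (thermal stress), cold to high.
#'
#' @param smt a `weekly_cube` tagged "SMT".
#' @param extrema [climatology_extrema()] of the SMT record.
#' @return a `weekly_cube` tagged "TCI".
#' @export
compute_tci <- function(smt, extrema) {
  if (smt$tag != "SMT" || extrema$tag != "SMT") {
    stop_arg("compute_tci expects an SMT cube and SMT extrema")
  }
  normalize_index(smt, extrema, reverse = TRUE, tag = "TCI")
}

#' Vegetation Health Index
#'
#' VHI = a * VCI + (1 - a) * TCI. The share of moisture (VCI) and thermal
#' (TCI) condition in total vegetation health is unknown for a given place
#' and time, so equal weights a = 0.5 are the default.
#'
#' @param vci,tci aligned `weekly_cube`s tagged "VCI"/"TCI".
#' @param a VCI weight in \[0, 1\] (default 0.5).
#' @return a `weekly_cube` tagged "VHI"; mask is the union of input masks.
#' @export
compute_vhi <- function(vci, tci, a = 0.5) {
  stopifnot(inherits(vci, "weekly_cube"), inherits(tci, "weekly_cube"))
  if (vci$tag != "VCI" || tci$tag != "TCI") {
    stop_arg("compute_vhi expects a VCI cube and a TCI cube")
  }
  if (!identical(dim(vci$values), dim(tci$values))) {
    stop_arg("VCI/TCI cube shape mismatch")
  }
  check_scalar_in(a, 0, 1, "a")
  v <- a * cube_matrix(vci) + (1 - a) * cube_matrix(tci)
  cube_from_matrix(v, vci, tag = "VHI", units = "index [0,100]")
}
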