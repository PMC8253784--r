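#' Vegetation/drought condition bands
#'
#' The VHI bands used to classify drought intensity and vegetation
#' condition. The drought classes are cumulative (nested) upper-bound
#' intervals: D4 (exceptional) VHI < 5, D3-D4 < 15, D2-D4 < 25,
#' D1-D4 < 35, stress < 40. The three top-level condition bands are
#' closed so they partition \[0, 100\]: stress \[0, 40), normal \[40, 60\],
#' favorable (60, 100\].
#'
#' @return a data.frame with columns `label`, `lo`, `hi`, `lo_closed`,
#'   `hi_closed`.
#' @export
condition_bands <- function() {
  data.frame(
    label = c("D4", "D3-D4", "D2-D4", "D1-D4", "stress", "normal", "favorable"),
    lo = c(0, 0, 0, 0, 0, 40, 60),
    hi = c(5, 15, 25, 35, 40, 60, 100),
    lo_closed = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    hi_closed = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

band_row <- function(label) {
  b <- condition_bands()
  row <- b[b$label == label, ]
  if (nrow(row) != 1) stop_arg("unknown band label: ", label)
  row
}

in_band <- function(x, band) {
  lo_ok <- if (band$lo_closed) x >= band$lo else x > band$lo
  hi_ok <- if (band$hi_closed) x <= band$hi else x < band$hi
  lo_ok & hi_ok
}

#' Classify a VHI value into condition bands
#'
#' Returns every band containing the value; the D-classes nest, so a VHI
#' of 4 belongs to D4, D3-D4, D2-D4, D1-D4 and stress simultaneously.
#'
#' @param vhi_value a single VHI in \[0, 100\].
#' @return character vector of band labels.
#' @export
classify_vhi <- function(vhi_value) {
  check_scalar_in(vhi_value, 0, 100, "vhi_value")
  b <- condition_bands()
  hits <- vapply(seq_len(nrow(b)), function(i) in_band(vhi_value, b[i, ]),
                 logical(1))
  b$label[hits]
}

#' Percent of area in a condition band, week by week
#'
#' For each time step, 100 x (valid pixels whose VHI falls in the band) /
#' (valid pixels that week). Weeks with no valid pixel get NA with a
#' warning.
#'
#' @param vhi a `weekly_cube` tagged "VHI".
#' @param band band label (see [condition_bands()]).
#' @return a data.frame with `time` (global week index), `year`, `week`,
#'   `percent_area`.
#' @export
percent_area <- function(vhi, band) {
  stopifnot(inherits(vhi, "weekly_cube"))
  if (vhi$tag != "VHI") stop_arg("percent_area expects a VHI cube")
  bd <- band_row(band)
  m <- cube_matrix(vhi)
  n_valid <- rowSums(is.finite(m))
  n_in <- rowSums(in_band(m, bd), na.rm = TRUE)
  pct <- ifelse(n_valid > 0, 100 * n_in / n_valid, NA_real_)
  if (any(n_valid == 0)) {
    warning(sum(n_valid == 0), " week(s) have zero valid pixels; percent area is NA there")
  }
  data.frame(time = seq_len(n_time(vhi)), year = vhi$year, week = vhi$week,
             percent_area = pct)
}

#' Detect regional drought events as runs below a VHI threshold
#'
#' Maximal runs of consecutive weeks with regional VHI strictly below the
#' threshold; duration is inclusive (a drought entered at week 23 and left
#' after week 32 lasted 10 weeks).
#'
#' @param regional_vhi numeric weekly regional-mean VHI series.
#' @param threshold onset threshold (default 40, the stress boundary).
#' @return a data.frame with `onset`, `end`, `duration` (zero rows when no
#'   event).
#' @export
detect_events <- function(regional_vhi, threshold = 40) {
  x <- as.numeric(regional_vhi)
  below <- !is.na(x) & x < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(onset = starts[keep], end = ends[keep],
             duration = ends[keep] - starts[keep] + 1L)
}

#' Mean value and duration of VHI inside a band
#'
#' Per pixel: the mean of the VHI values falling in the band and the count
#' of weeks spent in it; plus the regional averages of both (mean over
#' pixels that ever enter the band for the value, mean over all valid
#' pixels for the duration). Accepts a cube or a plain regional series.
#'
#' @param vhi a `weekly_cube` tagged "VHI", or a numeric series.
#' @param band band label.
#' @return a `category_stats` list with `mean_vhi`, `duration_weeks`
#'   (regional scalars; mean is NA with `occupied = FALSE` when the band
#'   is never entered) and, for cubes, per-pixel vectors `pixel_mean`,
#'   `pixel_duration`.
#' @export
category_stats <- function(vhi, band) {
  bd <- band_row(band)
  if (inherits(vhi, "weekly_cube")) {
    if (vhi$tag != "VHI") stop_arg("category_stats expects a VHI cube")
    m <- cube_matrix(vhi)
    inb <- in_band(m, bd) & is.finite(m)
    pixel_duration <- colSums(inb)
    sums <- colSums(m * inb, na.rm = TRUE)
    pixel_mean <- ifelse(pixel_duration > 0, sums / pixel_duration, NA_real_)
    occupied <- any(pixel_duration > 0)
    structure(list(
      band = bd$label, occupied = occupied,
      mean_vhi = if (occupied) mean(pixel_mean, na.rm = TRUE) else NA_real_,
      duration_weeks = mean(pixel_duration),
      pixel_mean = pixel_mean, pixel_duration = pixel_duration
    ), class = "category_stats")
  } else {
    x <- as.numeric(vhi)
    inb <- in_band(x, bd) & is.finite(x)
    dur <- sum(inb)
    structure(list(
      band = bd$label, occupied = dur > 0,
      mean_vhi = if (dur > 0) mean(x[inb]) else NA_real_,
      duration_weeks = dur
    ), class = "category_stats")
  }
}

#' @export
print.category_stats <- function(x, ...) {
  cat(sprintf("<category_stats> %s: mean VHI %.2f, duration %.1f weeks%s\n",
              x$band, x$mean_vhi, x$duration_weeks,
              if (!x$occupied) " (band never occupied)" else ""))
  invisible(x)
}

#' Early-warning weeks from a sustained TCI decline
#'
#' Thermal stress often builds before the composite VHI crosses into
#' drought; flag weeks where regional TCI has declined strictly
#' monotonically over the previous `decline_weeks` steps while regional
#' VHI is still at or above the drought threshold (i.e. before onset).
#'
#' @param tci_regional,vhi_regional aligned weekly regional series.
#' @param decline_weeks required length of the monotone decline (default 4).
#' @param vhi_threshold drought onset threshold (default 40).
#' @return integer vector of flagged week indices (possibly empty).
#' @export
early_warning <- function(tci_regional, vhi_regional, decline_weeks = 4,
                          vhi_threshold = 40) {
  tci <- as.numeric(tci_regional)
  vhi <- as.numeric(vhi_regional)
  if (length(tci) != length(vhi)) stop_arg("series must be aligned")
  n <- length(tci)
  if (n <= decline_weeks) return(integer(0))
  flags <- logical(n)
  d <- diff(tci)
  for (i in (decline_weeks + 1):n) {
    flags[i] <- all(d[(i - decline_weeks):(i - 1)] < 0) && vhi[i] >= vhi_threshold
  }
  which(flags)
}
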