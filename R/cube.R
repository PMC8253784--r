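#' Weekly gridded cube
#'
#' The central container of the package: a (time x lat x lon) array on a
#' 52-week-per-year calendar with a validity mask. A cube carries one
#' variable at a time — raw NDVI or brightness temperature (BT), their
#' smoothed versions (SMN, SMT), or one of the normalized indices
#' (VCI, TCI, VHI).
#'
#' @param values numeric array, dim = c(n_time, n_lat, n_lon).
#' @param year integer vector of calendar years, one per time step.
#' @param week integer vector of calendar weeks (1-52), one per time step.
#' @param mask logical array of the same dim as `values`; TRUE marks a
#'   valid cell. Defaults to `is.finite(values)`.
#' @param tag variable tag, one of "NDVI", "BT", "SMN", "SMT", "VCI",
#'   "TCI", "VHI".
#' @param units unit string; defaults are filled from the tag.
#' @return an object of class `weekly_cube`.
#' @export
weekly_cube <- function(values, year, week, mask = NULL,
                        tag = c("NDVI", "BT", "SMN", "SMT", "VCI", "TCI", "VHI"),
                        units = NULL) {
  tag <- match.arg(tag)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_arg("values must be a 3-d array (time x lat x lon)")
  }
  nt <- dim(values)[1]
  if (nt == 0L || prod(dim(values)[2:3]) == 0L) {
    stop_arg("degenerate cube: zero time steps or zero pixels")
  }
  if (length(year) != nt || length(week) != nt) {
    stop_arg("year and week must have one entry per time step")
  }
  if (any(week < 1L | week > 52L)) stop_arg("calendar weeks must lie in 1..52")
  if (is.null(mask)) mask <- is.finite(values) else {
    if (!identical(dim(mask), dim(values))) stop_arg("mask dim mismatch")
    mask <- mask & is.finite(values)
  }
  if (is.null(units)) {
    units <- switch(tag, NDVI = , SMN = "unitless", BT = , SMT = "degC",
                    "index [0,100]")
  }
  structure(
    list(values = values, year = as.integer(year), week = as.integer(week),
         mask = mask, tag = tag, units = units),
    class = "weekly_cube"
  )
}

#' @export
print.weekly_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<weekly_cube> %s [%s]: %d weeks x %d x %d grid, %.1f%% valid\n",
              x$tag, x$units, d[1], d[2], d[3], 100 * mean(x$mask)))
  cat(sprintf("  years %d-%d, calendar weeks %d-%d\n",
              min(x$year), max(x$year), min(x$week), max(x$week)))
  invisible(x)
}

#' @export
dim.weekly_cube <- function(x) dim(x$values)

n_time <- function(cube) dim(cube$values)[1]
n_pix <- function(cube) prod(dim(cube$values)[2:3])

# cube values as an (n_time x n_pix) matrix with NA at masked cells
cube_matrix <- function(cube) {
  v <- cube$values
  v[!cube$mask] <- NA_real_
  dim(v) <- c(dim(cube$values)[1], n_pix(cube))
  v
}

# rebuild a cube from an (n_time x n_pix) matrix, inheriting calendar
cube_from_matrix <- function(m, template, tag, units = NULL) {
  dim(m) <- dim(template$values)
  weekly_cube(m, template$year, template$week, mask = is.finite(m),
              tag = tag, units = units)
}

#' Regional mean series of a cube
#'
#' Averages all valid pixels at each time step — the "regional average"
#' series the drought and teleconnection analyses run on.
#'
#' @param cube a `weekly_cube`.
#' @return numeric vector of length `n_time` (NA where no pixel is valid).
#' @export
regional_mean <- function(cube) {
  stopifnot(inherits(cube, "weekly_cube"))
  rowMeans(cube_matrix(cube), na.rm = TRUE)
}

#' Restrict a cube to a set of calendar weeks
#'
#' Used to subset index cubes to the growing season (weeks kept across
#' every year, concatenated in time order).
#'
#' @param cube a `weekly_cube`.
#' @param weeks integer vector of calendar weeks (1-52) to keep.
#' @return a `weekly_cube` with only the selected time steps.
#' @export
subset_weeks <- function(cube, weeks) {
  stopifnot(inherits(cube, "weekly_cube"))
  keep <- cube$week %in% weeks
  if (!any(keep)) stop_arg("no time steps fall in the requested weeks")
  weekly_cube(cube$values[keep, , , drop = FALSE], cube$year[keep],
              cube$week[keep], mask = cube$mask[keep, , , drop = FALSE],
              tag = cube$tag, units = cube$units)
}

# global week index (1-based) -> fractional year offsets used by trend fits
time_in_years <- function(cube) (seq_len(n_time(cube)) - 1) / 52
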