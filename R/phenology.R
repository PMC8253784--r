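#' Detect the growing season from a regional smoothed-NDVI cycle
#'
#' Fixed-threshold phenology on one seasonal cycle of regional-mean SMN:
#' the season starts at the first step where SMN rises to at least
#' `start_threshold` and stays there for at least `persistence` steps
#' (guarding against single-step false starts), and ends at the last step
#' at or after the seasonal peak where SMN is still at least
#' `end_threshold` (so a mid-winter blip cannot terminate it). Works on
#' monthly (length 12) or weekly (length 52) series alike.
#'
#' @param smn_regional numeric vector, one seasonal cycle of regional SMN.
#' @param start_threshold SMN at green-up (default 0.20).
#' @param end_threshold SMN at senescence (default 0.25).
#' @param persistence steps SMN must stay above `start_threshold` at onset
#'   (default 2).
#' @return a `growing_season` list with `start`, `end`, `duration`
#'   (inclusive steps) and `found`; when SMN never reaches the start
#'   threshold, `found` is FALSE and the other fields are NA.
#' @export
detect_growing_season <- function(smn_regional, start_threshold = 0.20,
                                  end_threshold = 0.25, persistence = 2) {
  x <- as.numeric(smn_regional)
  n <- length(x)
  if (n < 4 || anyNA(x)) stop_arg("need a complete seasonal cycle of SMN")

  above <- x >= start_threshold
  start <- NA_integer_
  for (i in seq_len(n - persistence + 1)) {
    if (all(above[i:(i + persistence - 1)])) { start <- i; break }
  }
  if (is.na(start)) {
    return(structure(list(start = NA_integer_, end = NA_integer_,
                          duration = NA_integer_, found = FALSE),
                     class = "growing_season"))
  }
  peak <- which.max(x)
  tail_idx <- max(peak, start):n
  ge_end <- tail_idx[x[tail_idx] >= end_threshold]
  end <- if (length(ge_end)) max(ge_end) else start
  structure(list(start = as.integer(start), end = as.integer(end),
                 duration = as.integer(end - start + 1), found = TRUE),
            class = "growing_season")
}

#' @export
print.growing_season <- function(x, ...) {
  if (!x$found) cat("<growing_season> none detected\n")
  else cat(sprintf("<growing_season> steps %d-%d (duration %d)\n",
                   x$start, x$end, x$duration))
  invisible(x)
}

#' Calendar weeks covered by a growing season detected on a weekly cycle
#'
#' @param season a `growing_season` from a 52-step weekly cycle.
#' @return integer vector of calendar weeks, empty if none found.
#' @export
season_weeks <- function(season) {
  stopifnot(inherits(season, "growing_season"))
  if (!season$found) return(integer(0))
  season$start:season$end
}
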