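#' Ordinary least-squares linear trend
#'
#' Fits y_t = a + b t + e_t; `b` is the linear slope per unit of `t`
#' (pass `t` in years to get slopes per year).
#'
#' @param y numeric series.
#' @param t times (default `seq_along(y)`); needs >= 2 distinct values.
#' @return list with `slope`, `intercept`, `residuals_sd`.
#' @export
linear_trend <- function(y, t = seq_along(y)) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  if (length(y) < 3) stop_arg("need at least 3 points for a linear trend")
  if (length(unique(t)) < 2) stop_arg("all times identical")
  fit <- stats::lm.fit(cbind(1, t), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       residuals_sd = stats::sd(fit$residuals))
}

#' Mann-Kendall monotonic-trend test
#'
#' Rank-based test on S = sum over pairs i < j of sign(y_j - y_i), with
#' tie-corrected variance, a +/-1 continuity correction on the normal
#' approximation, and a two-sided p-value. `significant` flags p < alpha.
#'
#' @param y numeric series (n >= `min_n`).
#' @param alpha significance level (default 0.05).
#' @param min_n smallest n accepted for the normal approximation
#'   (default 8).
#' @return list with `s`, `var_s`, `z`, `p`, `significant`.
#' @export
mann_kendall <- function(y, alpha = 0.05, min_n = 8) {
  y <- as.numeric(y)
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < min_n) {
    stop_arg("Mann-Kendall normal approximation needs n >= ", min_n)
  }
  s <- mk_s_statistic(y)
  # tie correction: sum over tied groups of t(t-1)(2t+5)
  ties <- table(y)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (var_s == 0) 0 else (s - sign(s)) / sqrt(var_s)
  p <- 2 * stats::pnorm(-abs(z))
  list(s = s, var_s = var_s, z = z, p = p, significant = p < alpha)
}

mk_s_statistic <- function(y) {
  n <- length(y)
  s <- 0L
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(y[(i + 1):n] - y[i]))
  }
  as.integer(s)
}

#' Sen's slope (Theil-Sen estimator)
#'
#' The median of all pairwise slopes (y_j - y_i)/(t_j - t_i), i < j; a
#' robust nonparametric trend magnitude.
#'
#' @param y numeric series.
#' @param t times (default `seq_along(y)`).
#' @return the median pairwise slope.
#' @export
sens_slope <- function(y, t = seq_along(y)) {
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  n <- length(y)
  if (n < 2) stop_arg("need at least 2 points for Sen's slope")
  pairs <- utils::combn(n, 2)
  dt <- t[pairs[2, ]] - t[pairs[1, ]]
  slopes <- (y[pairs[2, ]] - y[pairs[1, ]]) / dt
  stats::median(slopes[dt != 0])
}

#' Full trend summary for one series
#'
#' Bundles the OLS fit, the Mann-Kendall test and Sen's slope, with time
#' expressed in years so both slopes are per year.
#'
#' @param y numeric series.
#' @param t_years times in (fractional) years; defaults to a weekly axis,
#'   `(seq_along(y) - 1)/52`.
#' @param alpha Mann-Kendall significance level (default 0.05).
#' @return a `trend_result` list with fields `ols_slope`, `ols_intercept`,
#'   `residuals_sd`, `mk_s`, `mk_z`, `mk_p`, `significant_5pct`,
#'   `sens_slope`.
#' @export
trend_summary <- function(y, t_years = (seq_along(y) - 1) / 52, alpha = 0.05) {
  ols <- linear_trend(y, t_years)
  mk <- mann_kendall(y, alpha = alpha)
  structure(list(
    ols_slope = ols$slope, ols_intercept = ols$intercept,
    residuals_sd = ols$residuals_sd,
    mk_s = mk$s, mk_z = mk$z, mk_p = mk$p,
    significant_5pct = mk$significant,
    sens_slope = sens_slope(y, t_years)
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "<trend_result> OLS slope %.4f/yr, Sen's slope %.4f/yr, MK S=%d z=%.2f p=%.4f%s\n",
    x$ols_slope, x$sens_slope, x$mk_s, x$mk_z, x$mk_p,
    if (x$significant_5pct) " *" else ""))
  invisible(x)
}

#' Per-pixel trend maps for a cube
#'
#' Runs [trend_summary()] on every pixel with enough valid data. No
#' multiple-testing correction is applied by default (per-grid 5% maps);
#' set `fdr = TRUE` for Benjamini-Hochberg adjusted significance.
#'
#' @param cube a `weekly_cube`.
#' @param min_obs minimum valid time steps per pixel (default 8).
#' @param fdr apply BH correction to the MK p-values (default FALSE).
#' @return a data.frame with one row per pixel: `pixel`, `ols_slope`,
#'   `sens_slope`, `mk_p`, `significant`.
#' @export
trend_map <- function(cube, min_obs = 8, fdr = FALSE) {
  stopifnot(inherits(cube, "weekly_cube"))
  m <- cube_matrix(cube)
  t_years <- time_in_years(cube)
  res <- lapply(seq_len(ncol(m)), function(j) {
    y <- m[, j]
    ok <- is.finite(y)
    if (sum(ok) < min_obs) {
      return(data.frame(pixel = j, ols_slope = NA_real_, sens_slope = NA_real_,
                        mk_p = NA_real_))
    }
    ts <- trend_summary(y[ok], t_years[ok])
    data.frame(pixel = j, ols_slope = ts$ols_slope, sens_slope = ts$sens_slope,
               mk_p = ts$mk_p)
  })
  out <- do.call(rbind, res)
  p <- if (fdr) stats::p.adjust(out$mk_p, "BH") else out$mk_p
  out$significant <- !is.na(p) & p < 0.05
  out
}
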