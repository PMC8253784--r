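test_that("smoothing preserves constants and removes isolated spikes", {
  const <- make_cube(matrix(0.3, 60, 2))
  sm <- smooth_series(const)
  expect_equal(sm$values, const$values, tolerance = 1e-12)
  expect_identical(sm$tag, "SMN")

  spike <- rep(0, 60); spike[30] <- 5
  sm2 <- smooth_series(make_cube(cbind(spike)), window_weeks = 5)
  expect_equal(sm2$values[30, 1, 1], 0, tolerance = 1e-12)
})

test_that("a linear ramp passes through the symmetric kernel unchanged in the interior", {
  ramp <- seq(0, 1, length.out = 80)
  sm <- smooth_series(make_cube(cbind(ramp)), window_weeks = 5)
  interior <- 3:78
  expect_equal(sm$values[interior, 1, 1], ramp[interior], tolerance = 1e-12)
})

test_that("smoothing propagates the mask and warns on fully-masked pixels", {
  m <- matrix(0.2, 60, 2)
  mask <- matrix(TRUE, 60, 2)
  mask[, 2] <- FALSE      # pixel 2 entirely missing
  mask[10, 1] <- FALSE    # one missing week in pixel 1
  cube <- make_cube(m, mask = mask)
  expect_warning(sm <- smooth_series(cube), "fully-masked")
  expect_false(any(sm$mask[, 2, 1]))
  expect_false(sm$mask[10, 1, 1])
  expect_true(all(sm$mask[-10, 1, 1]))
  expect_error(smooth_series(cube, window_weeks = 4), "odd")
  expect_error(smooth_series(sm), "raw NDVI or BT")
})

test_that("climatology extrema are per-pixel per-calendar-week max/min across years", {
  # week 5 takes values 0.1 / 0.2 / 0.3 over three years
  m <- matrix(0.5, 3 * 52, 1)
  m[5 + 52 * (0:2), 1] <- c(0.1, 0.2, 0.3)
  smn <- make_cube(m, tag = "NDVI")
  smn$tag <- "SMN"
  ex <- climatology_extrema(smn)
  expect_equal(ex$vmax[5, 1], 0.3)
  expect_equal(ex$vmin[5, 1], 0.1)
  expect_true(all(ex$vmax >= ex$vmin))
  # constant field: degenerate everywhere else
  expect_true(ex$degenerate[6, 1])
  expect_error(climatology_extrema(make_cube(matrix(0.1, 52, 1))), "3 distinct years")
  # whole-record option gives one envelope per pixel
  exg <- climatology_extrema(smn, per_week = FALSE)
  expect_equal(unique(exg$vmax[, 1]), 0.5)
  expect_equal(unique(exg$vmin[, 1]), 0.1)
})

test_that("a noise-free run has max = min = climatology at every week", {
  f <- generate_fields(quiet_config())
  smn <- smooth_series(f$ndvi)
  ex <- climatology_extrema(smn)
  # record edges see a truncated smoothing kernel, so the first/last two
  # calendar weeks differ between the edge year and interior years
  interior <- 3:50
  expect_true(all(abs(ex$vmax[interior, ] - ex$vmin[interior, ]) < 1e-12,
                  na.rm = TRUE))
  raw_ex <- climatology_extrema(
    weekly_cube(f$ndvi$values, f$ndvi$year, f$ndvi$week, tag = "SMN"))
  expect_true(all(abs(raw_ex$vmax - raw_ex$vmin) < 1e-12, na.rm = TRUE))
})

test_that("VCI/TCI hit the formula endpoints and midpoint", {
  m <- matrix(0.5, 3 * 52, 1)
  m[1 + 52 * (0:2), 1] <- c(0.1, 0.2, 0.3)   # week 1: min 0.1, mid 0.2, max 0.3
  smn <- make_cube(m); smn$tag <- "SMN"
  ex <- climatology_extrema(smn)
  vci <- compute_vci(smn, ex)
  wk1 <- vci$values[1 + 52 * (0:2), 1, 1]
  expect_equal(wk1, c(0, 50, 100), tolerance = 1e-12)
  # degenerate weeks (constant 0.5 across years) are masked, never divided
  expect_false(any(vci$mask[2, , ]))

  smt <- make_cube(m, tag = "BT", units = "degC"); smt$tag <- "SMT"
  tci <- compute_tci(smt, climatology_extrema(smt))
  expect_equal(tci$values[1 + 52 * (0:2), 1, 1], c(100, 50, 0), tolerance = 1e-12)
})

test_that("VHI is the stated convex combination and validates inputs", {
  mk_idx <- function(x, tag) {
    cube <- make_cube(matrix(x, 52, 1), units = "index [0,100]")
    cube$tag <- tag
    cube
  }
  vci <- mk_idx(30, "VCI"); tci <- mk_idx(50, "TCI")
  expect_equal(compute_vhi(vci, tci, a = 0.5)$values[1, 1, 1], 40)
  expect_equal(compute_vhi(vci, tci, a = 1)$values, vci$values)
  expect_equal(compute_vhi(mk_idx(33, "VCI"), mk_idx(33, "TCI"), a = 0.3)$values[1, 1, 1], 33)
  expect_error(compute_vhi(tci, vci), "VCI cube")
  big <- make_cube(matrix(10, 104, 1)); big$tag <- "TCI"
  expect_error(compute_vhi(vci, big), "mismatch")
  expect_error(compute_vhi(vci, tci, a = 1.5), "a must lie")
})

test_that("indices stay in [0,100], are monotone in the input, and span the record", {
  cfg <- synthetic_config(n_years = 5, n_lat = 4, n_lon = 4, rng_seed = 9)
  f <- generate_fields(cfg)
  smn <- smooth_series(f$ndvi)
  ex <- climatology_extrema(smn)
  vci <- compute_vci(smn, ex)
  v <- vci$values[vci$mask]
  expect_true(all(v >= 0 & v <= 100))

  # self-consistency: at each pixel/week, some year attains 0 and some 100
  m <- matrix(vci$values, nrow = 5 * 52)
  msk <- matrix(vci$mask, nrow = 5 * 52)
  for (w in c(3, 27)) {
    rows <- which(smn$week == w)
    for (p in 1:16) {
      vals <- m[rows, p][msk[rows, p]]
      if (length(vals)) {
        expect_equal(min(vals), 0, tolerance = 1e-9)
        expect_equal(max(vals), 100, tolerance = 1e-9)
      }
    }
  }

  # orientation: raising SMN (same extrema) never lowers VCI
  smn_up <- smn
  smn_up$values <- pmin(smn$values + 0.01, 1)
  vci_up <- compute_vci(smn_up, ex)
  both <- vci$mask & vci_up$mask
  expect_true(all(vci_up$values[both] >= vci$values[both] - 1e-9))
})

test_that("out-of-envelope values are clipped and counted", {
  m <- matrix(0.5, 3 * 52, 1)
  m[1 + 52 * (0:2), 1] <- c(0.1, 0.2, 0.3)
  smn <- make_cube(m); smn$tag <- "SMN"
  ex <- climatology_extrema(smn)
  smn_new <- smn
  smn_new$values[1, 1, 1] <- 0.05   # below the week-1 envelope
  vci <- compute_vci(smn_new, ex)
  expect_equal(vci$values[1, 1, 1], 0)
  expect_identical(attr(vci, "n_clipped"), 1L)
})
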