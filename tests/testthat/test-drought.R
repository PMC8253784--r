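test_that("classification returns every nested band containing the value", {
  expect_setequal(classify_vhi(4), c("D4", "D3-D4", "D2-D4", "D1-D4", "stress"))
  expect_setequal(classify_vhi(50), "normal")
  expect_setequal(classify_vhi(37), "stress")   # >= 35, so no D-class
  expect_setequal(classify_vhi(40), "normal")   # boundary closure convention
  expect_setequal(classify_vhi(60), "normal")
  expect_setequal(classify_vhi(60.01), "favorable")
  expect_error(classify_vhi(101), "must lie")
  expect_error(classify_vhi(-1), "must lie")
})

test_that("percent area counts valid pixels in band per week", {
  vals <- matrix(50, 4, 10)
  vals[2, 1:3] <- 20          # week 2: 3 of 10 pixels below 35
  cube <- make_cube(vals, units = "index [0,100]")
  cube$tag <- "VHI"
  pa <- percent_area(cube, "D1-D4")
  expect_equal(pa$percent_area, c(0, 30, 0, 0))
  expect_equal(percent_area(cube, "normal")$percent_area, c(100, 70, 100, 100))
  # all-masked week yields NA with a warning
  mask <- matrix(TRUE, 4, 10); mask[3, ] <- FALSE
  cube2 <- make_cube(vals, mask = mask, units = "index [0,100]")
  cube2$tag <- "VHI"
  expect_warning(pa2 <- percent_area(cube2, "stress"), "zero valid")
  expect_true(is.na(pa2$percent_area[3]))
  expect_error(percent_area(make_cube(vals), "stress"), "VHI cube")
})

test_that("percent-area bands nest and the top-level bands partition fully-valid weeks", {
  cfg <- synthetic_config(n_years = 5, n_lat = 4, n_lon = 4, rng_seed = 13)
  f <- generate_fields(cfg, list(drought_episode(80, 95, 0.25, 6)))
  smn <- smooth_series(f$ndvi); smt <- smooth_series(f$bt)
  vhi <- compute_vhi(compute_vci(smn, climatology_extrema(smn)),
                     compute_tci(smt, climatology_extrema(smt)))
  pa <- sapply(condition_bands()$label, function(b) percent_area(vhi, b)$percent_area)
  expect_true(all(pa[, "D4"] <= pa[, "D3-D4"]))
  expect_true(all(pa[, "D3-D4"] <= pa[, "D2-D4"]))
  expect_true(all(pa[, "D2-D4"] <= pa[, "D1-D4"]))
  expect_true(all(pa[, "D1-D4"] <= pa[, "stress"]))
  full <- rowSums(matrix(vhi$mask, nrow = 5 * 52)) == 16
  tot <- pa[, "stress"] + pa[, "normal"] + pa[, "favorable"]
  expect_equal(tot[full], rep(100, sum(full)), tolerance = 1e-9)
})

test_that("an episode over 40% of the grid adds exactly its pixel block to the D1-D4 area", {
  cfg <- synthetic_config(n_years = 5, n_lat = 5, n_lon = 4,
                          noise_sd_ndvi = 0.01, noise_sd_bt = 0.4, rng_seed = 17)
  ep <- drought_episode(120, 135, ndvi_depression = 0.3, bt_elevation = 10,
                        spatial_extent = 0.4)
  f <- generate_fields(cfg, list(ep))
  smn <- smooth_series(f$ndvi); smt <- smooth_series(f$bt)
  vhi <- compute_vhi(compute_vci(smn, climatology_extrema(smn)),
                     compute_tci(smt, climatology_extrema(smt)))
  m <- matrix(vhi$values, nrow = 5 * 52)    # time x pixel, affected = 1:8
  core <- 124:131   # clear of the smoother window at the episode edges
  # generator ground truth: every affected pixel sits in D1-D4 in the core
  expect_true(all(m[core, 1:8] < 35))
  # and the area series decomposes into the 40% block plus the measured
  # climatological background rate of the unaffected pixels
  pa <- percent_area(vhi, "D1-D4")
  bg <- 100 * rowMeans(m[core, 9:20] < 35)
  expect_equal(pa$percent_area[core], 40 + 0.6 * bg, tolerance = 1e-9)
  expect_true(all(pa$percent_area[core] >= 40))
})

test_that("events are maximal runs below threshold with inclusive duration", {
  x <- rep(60, 52)
  x[23:32] <- 30
  ev <- detect_events(x, threshold = 40)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$onset, 23L)
  expect_identical(ev$end, 32L)
  expect_identical(ev$duration, 10L)

  expect_identical(nrow(detect_events(rep(45, 30))), 0L)

  y <- rep(50, 25); y[5:6] <- 10; y[20] <- 39.9
  ev2 <- detect_events(y)
  expect_equal(ev2$onset, c(5L, 20L))
  expect_equal(ev2$duration, c(2L, 1L))
})

test_that("category stats give in-band mean and inclusive duration", {
  cs <- category_stats(c(10, 20, 50), "D1-D4")
  expect_equal(cs$mean_vhi, 15)
  expect_identical(cs$duration_weeks, 2L)
  cs2 <- category_stats(c(50, 55), "D4")
  expect_false(cs2$occupied)
  expect_identical(cs2$duration_weeks, 0L)
  expect_true(is.na(cs2$mean_vhi))
})

test_that("stress duration at fully-affected pixels matches the injected episode length", {
  cfg <- synthetic_config(n_years = 4, n_lat = 3, n_lon = 3,
                          noise_sd_ndvi = 0.005, noise_sd_bt = 0.2, rng_seed = 19)
  ep <- drought_episode(100, 111, ndvi_depression = 0.35, bt_elevation = 12,
                        spatial_extent = 1)
  f <- generate_fields(cfg, list(ep))
  smn <- smooth_series(f$ndvi); smt <- smooth_series(f$bt)
  vhi <- compute_vhi(compute_vci(smn, climatology_extrema(smn)),
                     compute_tci(smt, climatology_extrema(smt)))
  m <- matrix(vhi$values, nrow = 4 * 52)
  # within the episode window every pixel spends all 12 weeks in stress
  for (p in c(1, 5, 9)) {
    cs <- category_stats(m[100:111, p], "stress")
    expect_identical(cs$duration_weeks, 12L)
  }
  # and the cube-level per-pixel duration includes at least those weeks
  cs_cube <- category_stats(vhi, "stress")
  expect_true(all(cs_cube$pixel_duration >= 12))
})

test_that("early warnings require a sustained TCI decline before onset", {
  n <- 30
  tci <- c(rep(70, 13), 70 - 3 * (1:17))           # strict decline from week 14
  vhi <- c(rep(60, 22), rep(30, 8))                # crosses 40 at week 23
  w <- early_warning(tci, vhi, decline_weeks = 4)
  expect_true(length(w) > 0)
  expect_lte(min(w), 18)
  expect_true(all(w < 23))                          # no warning once VHI < 40
  expect_identical(early_warning(rep(50, n), rep(60, n)), integer(0))
  tci2 <- 60 - (1:n)                                # declining throughout
  vhi2 <- rep(30, n)                                # but drought already begun
  expect_identical(early_warning(tci2, vhi2), integer(0))
  expect_error(early_warning(1:5, 1:6), "aligned")
})
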