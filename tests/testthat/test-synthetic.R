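test_that("noise-free, trend-free generator repeats the same annual cycle", {
  f <- generate_fields(quiet_config())
  m <- matrix(f$ndvi$values, nrow = 4 * 52)
  yearly <- array(m, c(52, 4, ncol(m)))
  for (k in 2:4) {
    expect_equal(yearly[, k, ], yearly[, 1, ], tolerance = 1e-12)
  }
  expect_true(all(f$ndvi$values >= -1 & f$ndvi$values <= 1))
})

test_that("a pure linear trend adds exactly trend/year between same weeks of consecutive years", {
  f <- generate_fields(quiet_config(trend_ndvi_per_year = 0.001))
  v <- f$ndvi$values[, 1, 1]
  for (w in c(1, 20, 52)) {
    diffs <- diff(v[w + 52 * (0:3)])
    expect_equal(diffs, rep(0.001, 3), tolerance = 1e-12)
  }
})

test_that("an injected episode lowers NDVI by exactly its depression (same seed)", {
  cfg <- synthetic_config(n_years = 4, n_lat = 3, n_lon = 3, rng_seed = 42)
  ep <- drought_episode(60, 75, ndvi_depression = 0.2, bt_elevation = 4,
                        spatial_extent = 1)
  base <- generate_fields(cfg)
  hit <- generate_fields(cfg, list(ep))
  weeks <- 60:75
  expect_equal(mean(base$ndvi$values[weeks, , ]) - mean(hit$ndvi$values[weeks, , ]),
               0.2, tolerance = 1e-10)
  expect_equal(mean(hit$bt$values[weeks, , ]) - mean(base$bt$values[weeks, , ]),
               4, tolerance = 1e-10)
  # outside the episode the runs are identical
  expect_identical(base$ndvi$values[-weeks, , ], hit$ndvi$values[-weeks, , ])
})

test_that("same config and seed give bit-identical cubes and index", {
  cfg <- synthetic_config(n_years = 3, n_lat = 4, n_lon = 2,
                          missing_fraction = 0.1, rng_seed = 7)
  a <- generate_fields(cfg)
  b <- generate_fields(cfg)
  expect_identical(a$ndvi$values, b$ndvi$values)
  expect_identical(a$bt$values, b$bt$values)
  expect_identical(a$ndvi$mask, b$ndvi$mask)
  expect_identical(a$enso$values, b$enso$values)
})

test_that("missing_fraction masks exactly round(fraction * n_cells) cells", {
  cfg <- synthetic_config(n_years = 3, n_lat = 5, n_lon = 4,
                          missing_fraction = 0.13, rng_seed = 3)
  f <- generate_fields(cfg)
  n_cells <- 3 * 52 * 5 * 4
  expect_identical(sum(!f$ndvi$mask), as.integer(round(0.13 * n_cells)))
  expect_identical(f$ndvi$mask, f$bt$mask)
})

test_that("invalid configs and out-of-range episodes are rejected", {
  expect_error(synthetic_config(n_years = 2), "n_years")
  expect_error(synthetic_config(noise_ar1_coeff = 1), "noise_ar1_coeff")
  expect_error(synthetic_config(missing_fraction = 1), "missing_fraction")
  expect_error(synthetic_config(n_lat = 0), "degenerate")
  expect_error(drought_episode(10, 5), "start")
  expect_error(drought_episode(1, 5, ndvi_depression = -0.1), "non-negative")
  cfg <- quiet_config()
  expect_error(generate_fields(cfg, list(drought_episode(200, 250))),
               "outside the .* time range")
})

test_that("ENSO-like generator: sinusoid limit and AR(1) autocorrelation", {
  # exact sinusoid: period 4 years, no noise -> lag-208 autocorrelation 1
  e <- generate_enso_like(520, ar1 = 0, periodic_component = c(4, 1),
                          rng_seed = 1, noise_sd = 0)
  x <- e$values
  expect_equal(cor(x[1:(520 - 208)], x[209:520]), 1, tolerance = 1e-12)
  # white-noise limit: sample mean near zero
  w <- generate_enso_like(5000, ar1 = 0, periodic_component = c(4, 0),
                          rng_seed = 2)
  expect_lt(abs(mean(w$values)), 3 * sd(w$values) / sqrt(5000))
  # AR(1) 0.9: lag-1 sample autocorrelation 0.9 +/- 0.05 at n = 5000
  a <- generate_enso_like(5000, ar1 = 0.9, periodic_component = c(4, 0),
                          rng_seed = 3)
  r1 <- cor(a$values[-1], a$values[-5000])
  expect_lt(abs(r1 - 0.9), 0.05)
  expect_error(generate_enso_like(520, ar1 = 1), "ar1")
  expect_error(generate_enso_like(52), "104")
})

test_that("ENSO coupling to BT is recoverable at nearly every pixel", {
  # zero seasonal amplitude isolates the coupling channel: the annual BT
  # harmonic otherwise dominates the raw covariance at every pixel alike
  cfg <- synthetic_config(n_years = 8, n_lat = 5, n_lon = 5,
                          seasonal_bt_amplitude = 0,
                          enso_coupling_bt = 1, noise_sd_bt = 0.5,
                          rng_seed = 11)
  f <- generate_fields(cfg)
  pm <- pearson_map(f$bt, f$enso)
  expect_gte(pm$fraction_positive, 95)
})
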