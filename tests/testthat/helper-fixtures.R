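# Shared fixture builders for the test suite.

# A minimal cube from an (n_time x n_pix) matrix on a square-ish grid,
# defaulting to a 1x1 grid per column.
make_cube <- function(m, tag = "NDVI", n_lat = NULL, n_lon = NULL,
                      mask = NULL, units = NULL) {
  m <- as.matrix(m)
  p <- ncol(m)
  if (is.null(n_lat)) { n_lat <- p; n_lon <- 1L }
  nt <- nrow(m)
  arr <- array(m, c(nt, n_lat, n_lon))
  msk <- if (is.null(mask)) NULL else array(mask, c(nt, n_lat, n_lon))
  weekly_cube(arr, year = rep(seq_len(ceiling(nt / 52)), each = 52)[seq_len(nt)],
              week = rep(1:52, length.out = nt), mask = msk, tag = tag,
              units = units)
}

# A small quiet synthetic run used by several files.
quiet_config <- function(...) {
  synthetic_config(n_years = 4, n_lat = 3, n_lon = 3, noise_sd_ndvi = 0,
                   noise_sd_bt = 0, noise_ar1_coeff = 0, rng_seed = 1, ...)
}

# Monthly regional SMN cycle shaped like the regional climatology: winter
# about 0.11, August peak about 0.40.
monthly_smn_cycle <- function() {
  c(0.11, 0.12, 0.15, 0.22, 0.30, 0.37, 0.37, 0.40, 0.37, 0.27, 0.18, 0.12)
}

in_coi <- function(res) outer(res$periods, res$coi, "<=")
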