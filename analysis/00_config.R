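# Shared study conditions for the analysis stages. Each numbered script
# sources this file and regenerates the (deterministic, seeded) inputs it
# needs, so no binary intermediates are kept.
#
# Conditions: a 10-year, 8x8 grid on a 52-week calendar; NDVI follows an
# annual harmonic (winter ~0.11, early-August peak ~0.40) and BT a
# summer-peaked cycle; weekly AR(1) noise; the ENSO-like index couples
# positively into BT (warm events heat the surface); two multi-week drought
# episodes are embedded, one basin-wide and one over 40% of the grid; 2% of
# cells are masked as missing.

library(vhitools)

study_config <- function() {
  synthetic_config(
    n_years = 10, n_lat = 8, n_lon = 8,
    enso_coupling_bt = 0.8,
    missing_fraction = 0.02,
    rng_seed = 20210702
  )
}

study_episodes <- function() {
  list(
    drought_episode(start_week = 126, end_week = 140,   # summer, year 3
                    ndvi_depression = 0.12, bt_elevation = 4,
                    spatial_extent = 1),
    drought_episode(start_week = 380, end_week = 391,   # spring, year 8
                    ndvi_depression = 0.15, bt_elevation = 5,
                    spatial_extent = 0.4)
  )
}

study_fields <- function() generate_fields(study_config(), study_episodes())

# SMN/SMT and the three indices, computed once per stage that needs them
study_indices <- function(fields = study_fields()) {
  smn <- smooth_series(fields$ndvi)
  smt <- smooth_series(fields$bt)
  vci <- compute_vci(smn, climatology_extrema(smn))
  tci <- compute_tci(smt, climatology_extrema(smt))
  list(smn = smn, smt = smt, vci = vci, tci = tci,
       vhi = compute_vhi(vci, tci, a = 0.5))
}
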