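#!/usr/bin/env Rscript
# Stage 2: smooth the raw fields (SMN/SMT), build the per-calendar-week
# climatology envelope, and compute VCI, TCI and VHI. Also derives the
# growing season from the regional SMN climatology.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

dir.create("results", showWarnings = FALSE)
idx <- study_indices()

cat(sprintf("VCI clipped cells: %d; TCI clipped cells: %d\n",
            attr(idx$vci, "n_clipped"), attr(idx$tci, "n_clipped")))
for (nm in c("vci", "tci", "vhi")) {
  cube <- idx[[nm]]
  v <- cube$values[cube$mask]
  cat(sprintf("%s: range [%.1f, %.1f], mean %.1f\n", toupper(nm),
              min(v), max(v), mean(v)))
}
write_cube(idx$vhi, "results/vhi_cube.csv")

# regional SMN climatology and the fixed-threshold growing season
reg_smn <- regional_mean(idx$smn)
clim <- vapply(1:52, function(w) mean(reg_smn[idx$smn$week == w], na.rm = TRUE),
               numeric(1))
season <- detect_growing_season(clim)
cat(sprintf("growing season: weeks %d-%d (%d weeks; thresholds 0.20/0.25)\n",
            season$start, season$end, season$duration))
write.csv(data.frame(week = 1:52, smn = clim,
                     in_season = 1:52 %in% season_weeks(season)),
          "results/smn_climatology.csv", row.names = FALSE)
jsonlite::write_json(unclass(season), "results/growing_season.json",
                     auto_unbox = TRUE)
cat("wrote results/vhi_cube.csv, results/smn_climatology.csv, results/growing_season.json\n")
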