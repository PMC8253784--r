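#!/usr/bin/env Rscript
# Stage 1: generate the synthetic weekly NDVI/BT cubes and the ENSO-like
# index used by every later stage, and write them out.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

dir.create("results", showWarnings = FALSE)
fields <- study_fields()
cat(sprintf("generated %d-week cubes on a %dx%d grid (%d NDVI cells clipped to range)\n",
            dim(fields$ndvi)[1], dim(fields$ndvi)[2], dim(fields$ndvi)[3],
            fields$n_clipped))
cat(sprintf("missing cells: %d of %d\n", sum(!fields$ndvi$mask),
            length(fields$ndvi$mask)))
cat(sprintf("ENSO-like index: sd %.2f, lag-1 autocorrelation %.2f\n",
            sd(fields$enso$values),
            cor(fields$enso$values[-1], fields$enso$values[-520])))

write_cube(fields$ndvi, "results/ndvi_raw.csv")
write_cube(fields$bt, "results/bt_raw.csv")
write_index_csv(fields$enso, "results/enso_index.csv")
cat("wrote results/ndvi_raw.csv, results/bt_raw.csv, results/enso_index.csv\n")
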