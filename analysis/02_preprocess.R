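#!/usr/bin/env Rscript
# Preprocess every simulated array: TIC normalization, peak picking, the
# 0.5%-of-base-peak filter, cross-pixel alignment (20 ppm) and assembly of
# the pixel x m/z-bin matrix. Matrices are written as CSV with a JSON
# sidecar of bin centres and parameters.

library(spotMSI)

out_dir <- "results/matrices"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (name in c("experiment_1", "experiment_2", "segmentation_array")) {
  ds <- read_dataset(file.path("results/data", name))
  pm <- suppressWarnings(preprocess_dataset(ds, tolerance_ppm = 20,
                                            min_snr = 3,
                                            filter_fraction = 0.005))
  tab <- cbind(pm$pixels[, c("pixel_id", "row", "col", "x", "y")],
               as.data.frame(pm$values))
  write.csv(tab, file.path(out_dir, paste0(name, "_matrix.csv")),
            row.names = FALSE)
  jsonlite::write_json(list(mz = pm$mz, params = pm$params),
                       file.path(out_dir, paste0(name, "_bins.json")),
                       digits = NA)
  cat(sprintf("%s: %d pixels x %d bins (%d species-matched)\n", name,
              nrow(pm$values), ncol(pm$values),
              sum(match_bins_to_species(pm$mz, rep("", length(pm$mz)),
                                        ds$panel) != "")))
}
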