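#!/usr/bin/env Rscript
# Simulate the study's array datasets: two independent replicate experiments
# of the wt vs CD9-KO EV design (2 samples x 4 replicate spots, 450-um spots
# on a 150-um raster), plus one spectrally-disjoint three-region array used
# to benchmark the spatial segmentation.

library(spotMSI)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
master_seed <- 20260922

panel <- default_species_panel()
cat("Lipid panel:", nrow(panel), "species;",
    sum(panel$fold_cd9ko != 1), "planted differential (SM up 1.5x, PC down 0.7x)\n")

for (e in 1:2) {
  lay <- make_layout(n_samples = 2, spots_per_sample = 4,
                     conditions = c("wt", "cd9ko"),
                     experiment_id = paste0("exp", e))
  ds <- generate_dataset(lay, panel = panel, seed = master_seed + e)
  write_dataset(ds, file.path(out_dir, paste0("experiment_", e)))
  cat(sprintf("experiment %d: %d pixels (%d on-spot) -> %s\n", e,
              nrow(ds$pixels), sum(!is.na(ds$pixels$spot_id)),
              file.path(out_dir, paste0("experiment_", e))))
}

lay_seg <- make_layout(n_samples = 3, spots_per_sample = 3,
                       conditions = paste0("region", 1:3),
                       experiment_id = "segmentation")
ds_seg <- generate_dataset(lay_seg, panel = disjoint_region_panel(3),
                           seed = master_seed + 10)
write_dataset(ds_seg, file.path(out_dir, "segmentation_array"))
cat(sprintf("segmentation array: %d pixels, truth segments: %s\n",
            nrow(ds_seg$pixels),
            paste(unique(ds_seg$pixels$truth_segment), collapse = ", ")))
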