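#' Match m/z bins to panel species names
#'
#' Renames consensus m/z bins after the closest panel species within
#' `tolerance_ppm`; unmatched bins keep their `mz_<value>` name.
#'
#' @param mz numeric bin centres.
#' @param names current bin names.
#' @param panel a [species_panel()].
#' @param tolerance_ppm match tolerance.
#' @return character vector of names.
#' @export
match_bins_to_species <- function(mz, names, panel, tolerance_ppm = 20) {
  out <- names
  for (i in seq_along(mz)) {
    d <- abs(panel$mz - mz[i])
    j <- which.min(d)
    if (d[j] <= tolerance_ppm * 1e-6 * mz[i]) out[i] <- panel$name[j]
  }
  out
}

#' End-to-end differential lipidomics run over two replicate experiments
#'
#' Simulates two independent replicate arrays (same design, independent
#' seeds), runs the full preprocessing and spot-aggregation pipeline on
#' each, tests every species per experiment with the Student t-test over
#' spot replicates, and applies the dual-replicate AND rule. Sensitivity and
#' false positives are scored against the generator's planted truth: a
#' planted species counts as detected only when its direction matches the
#' planted fold change; a false positive is an unchanged (fold 1) panel
#' species passing the dual-replicate rule.
#'
#' @param seed master seed; the two experiments use child streams.
#' @param spots_per_sample replicate spots per sample (default 4, the
#'   quadruplicate design).
#' @param panel a [species_panel()] with conditions `wt` and `cd9ko`.
#' @param noise a [noise_model()].
#' @param alpha per-experiment significance level.
#' @param tolerance_ppm preprocessing alignment tolerance.
#' @return list with `tests` (per-experiment test tables), `hits` (the
#'   dual-replicate species table), `truth`, `sensitivity`, `n_planted`,
#'   `n_detected`, `false_positives` (count among fold-1 panel species) and
#'   `background_hits` (bins passing the rule that match no panel species).
#' @export
lipid_benchmark <- function(seed = 1, spots_per_sample = 4,
                            panel = default_species_panel(),
                            noise = noise_model(), alpha = 0.05,
                            tolerance_ppm = 20) {
  run_experiment <- function(exp_id, exp_seed) {
    lay <- make_layout(n_samples = 2, spots_per_sample = spots_per_sample,
                       conditions = c("wt", "cd9ko"), experiment_id = exp_id)
    ds <- generate_dataset(lay, panel = panel, noise = noise, seed = exp_seed)
    pm <- suppressWarnings(preprocess_dataset(ds, tolerance_ppm = tolerance_ppm))
    assign <- map_pixels_to_spots(lay, pm$pixels)
    spots <- aggregate_spot_intensities(pm, assign, lay)
    spots$species <- match_bins_to_species(spots$mz, spots$species, panel,
                                           tolerance_ppm)
    list(dataset = ds,
         tests = suppressMessages(
           test_lipid_differences(spots, "wt", "cd9ko", alpha = alpha)))
  }
  e1 <- run_experiment("exp1", child_seed(seed, 1))
  e2 <- run_experiment("exp2", child_seed(seed, 2))
  hits <- suppressWarnings(
    dual_replicate_filter(e1$tests, e2$tests, alpha = alpha))
  truth <- e1$dataset$truth_differential
  detected <- vapply(seq_len(nrow(truth)), function(i) {
    j <- match(truth$species[i], hits$species)
    !is.na(j) && sign(truth$true_fold[i] - 1) == hits$direction[j]
  }, logical(1))
  null_species <- setdiff(panel$name, truth$species)
  fp <- sum(hits$species %in% null_species)
  bg <- sum(!hits$species %in% panel$name)
  list(tests = list(e1$tests, e2$tests), hits = hits, truth = truth,
       n_planted = nrow(truth), n_detected = sum(detected),
       sensitivity = mean(detected), false_positives = fp,
       background_hits = bg)
}

#' Planted-partition segmentation benchmark
#'
#' Simulates an array whose samples express spectrally disjoint lipid
#' panels (one "region" per condition), runs preprocessing and the divisive
#' random-walker segmentation, and scores recovery of the planted partition
#' (conditions plus background) with the adjusted Rand index.
#'
#' @param seed master seed.
#' @param noise a [noise_model()]; [zero_noise()] gives the
#'   zero-cross-similarity setting where recovery must be exact.
#' @param n_regions number of spectrally disjoint sample classes.
#' @param spots_per_sample replicate spots per sample.
#' @param max_segments segmentation cap; default `n_regions + 1` (the
#'   background is one more segment).
#' @param ... further arguments passed to [diana_rankcompete()].
#' @return list with `ari`, `result` (the [diana_rankcompete()] output),
#'   `truth` (segment label per pixel) and `dataset`.
#' @export
segmentation_benchmark <- function(seed = 1, noise = noise_model(),
                                   n_regions = 3, spots_per_sample = 3,
                                   max_segments = n_regions + 1, ...) {
  if (!requireNamespace("mclust", quietly = TRUE)) {
    stop("segmentation_benchmark needs the mclust package for the adjusted Rand index")
  }
  panel <- disjoint_region_panel(n_regions)
  lay <- make_layout(n_samples = n_regions,
                     spots_per_sample = spots_per_sample,
                     conditions = paste0("region", seq_len(n_regions)),
                     experiment_id = "seg")
  ds <- generate_dataset(lay, panel = panel, noise = noise, seed = seed)
  pm <- suppressWarnings(preprocess_dataset(ds))
  seg <- diana_rankcompete(pm, max_segments = max_segments, ...)
  truth_by_coord <- ds$pixels$truth_segment[
    match(paste(pm$pixels$x, pm$pixels$y),
          paste(ds$pixels$x, ds$pixels$y))]
  ari <- mclust::adjustedRandIndex(seg$labels, truth_by_coord)
  list(ari = ari, result = seg, truth = truth_by_coord, dataset = ds)
}
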