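#' Define a lipid species panel
#'
#' A panel is a data frame with one row per molecular species: `name`, `mz`
#' (negative-ion m/z inside the 550-2000 observation window), `base_intensity`
#' (expected raw peak intensity in the reference condition) and one
#' `fold_<condition>` column per condition giving the multiplicative change of
#' that species under the condition. A fold of 1 means unchanged; 0 means the
#' species is absent in that condition (used by the spectrally-disjoint
#' segmentation benchmarks).
#'
#' @param name character vector of species names.
#' @param mz numeric m/z values.
#' @param base_intensity non-negative expected intensities.
#' @param ... named fold vectors, one per condition, e.g.
#'   `wt = 1, cd9ko = c(1.5, ...)` (recycled to the panel length).
#' @return data frame of class `species_panel`.
#' @export
species_panel <- function(name, mz, base_intensity, ...) {
  stopifnot(length(name) == length(mz), length(mz) == length(base_intensity))
  if (any(base_intensity < 0)) stop("base_intensity must be >= 0")
  folds <- list(...)
  panel <- data.frame(name = name, mz = mz, base_intensity = base_intensity,
                      stringsAsFactors = FALSE)
  for (cond in names(folds)) {
    f <- rep_len(folds[[cond]], nrow(panel))
    if (any(f < 0)) stop("fold changes must be >= 0")
    panel[[paste0("fold_", cond)]] <- f
  }
  class(panel) <- c("species_panel", "data.frame")
  panel
}

#' Default lipid panel: sphingomyelin up, phosphatidylcholine down
#'
#' Twelve negative-ion lipid forms emulating the differential readout of the
#' EV arrays: three sphingomyelin (SM) forms up-regulated 1.5-fold and three
#' phosphatidylcholine (PC) forms down-regulated to 0.7-fold in the `cd9ko`
#' condition, plus six unchanged membrane lipids. Base intensities are chosen
#' so the panel is TIC-balanced across conditions (the summed intensity gained
#' by SM equals that lost by PC), keeping the configured fold changes
#' identifiable after total-ion-current normalization.
#'
#' @return a [species_panel()] with conditions `wt` and `cd9ko`.
#' @export
default_species_panel <- function() {
  species_panel(
    name = c("SM(d34:1)", "SM(d36:1)", "SM(d42:2)",
             "PC(32:0)", "PC(34:1)", "PC(36:2)",
             "PE(34:1)", "PE(36:2)", "PI(38:4)",
             "PS(36:1)", "PG(34:1)", "ST(42:2)"),
    mz = c(687.545, 715.576, 797.653,
           718.539, 744.555, 770.570,
           716.523, 742.539, 885.550,
           788.544, 747.518, 888.624),
    # SM gain 3 * 60 * 0.5 = 90 balances PC loss 3 * 100 * 0.3 = 90
    base_intensity = c(60, 60, 60, 100, 100, 100, 80, 70, 90, 60, 40, 50),
    wt = 1,
    cd9ko = c(1.5, 1.5, 1.5, 0.7, 0.7, 0.7, 1, 1, 1, 1, 1, 1)
  )
}

#' Panel with spectrally disjoint regions
#'
#' Builds a panel in which each condition ("region") expresses its own
#' disjoint set of species, the planted-partition setting used to benchmark
#' the spatial segmentation.
#'
#' @param n_regions number of disjoint regions/conditions.
#' @param species_per_region species expressed per region.
#' @return a [species_panel()] with conditions `region1..regionN`.
#' @export
disjoint_region_panel <- function(n_regions = 3, species_per_region = 4) {
  n <- n_regions * species_per_region
  mz <- seq(650, 650 + 10 * (n - 1), by = 10)
  base <- rep(c(100, 80, 60, 40), length.out = n)
  region_of <- rep(seq_len(n_regions), each = species_per_region)
  folds <- stats::setNames(
    lapply(seq_len(n_regions), function(r) as.numeric(region_of == r)),
    paste0("region", seq_len(n_regions))
  )
  do.call(species_panel,
          c(list(name = sprintf("L%02d", seq_len(n)), mz = mz,
                 base_intensity = base), folds))
}

fold_for <- function(panel, condition) {
  col <- paste0("fold_", condition)
  if (col %in% names(panel)) panel[[col]] else rep(1, nrow(panel))
}

#' Noise model for synthetic spectra
#'
#' Parameters of the generative noise structure: log-normal per-pixel global
#' intensity scaling (`tic_scale_cv`), Gaussian m/z jitter, Gaussian additive
#' intensity noise, a flat chemical baseline, and per-species dropout.
#'
#' @param tic_scale_cv coefficient of variation of the per-pixel
#'   total-ion-current scale factor (log-normal with mean 1).
#' @param mz_jitter_sd standard deviation of per-peak m/z jitter, in Da.
#' @param additive_noise_sd standard deviation of additive intensity noise.
#' @param baseline_level flat chemical-noise baseline intensity.
#' @param dropout_prob probability a species is absent from a pixel.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(tic_scale_cv = 0.15, mz_jitter_sd = 0.0035,
                        additive_noise_sd = 5, baseline_level = 0.5,
                        dropout_prob = 0) {
  vals <- c(tic_scale_cv, mz_jitter_sd, additive_noise_sd, baseline_level)
  if (any(vals < 0)) stop("noise parameters must be >= 0")
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must be in [0, 1]")
  structure(list(tic_scale_cv = tic_scale_cv, mz_jitter_sd = mz_jitter_sd,
                 additive_noise_sd = additive_noise_sd,
                 baseline_level = baseline_level, dropout_prob = dropout_prob),
            class = "noise_model")
}

#' Zero-noise model
#'
#' Convenience: all noise parameters zero, so spectra are exact deterministic
#' functions of the species panel and condition.
#' @return a [noise_model()] with every parameter 0.
#' @export
zero_noise <- function() {
  noise_model(tic_scale_cv = 0, mz_jitter_sd = 0, additive_noise_sd = 0,
              baseline_level = 0, dropout_prob = 0)
}
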