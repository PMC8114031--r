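#' Construct a single-pixel mass spectrum
#'
#' @param mz strictly increasing m/z values.
#' @param intensity non-negative intensities, same length as `mz`.
#' @param x,y physical pixel coordinates in um.
#' @param row,col 0-based raster grid indices.
#' @param polarity ionization polarity; the arrays modelled here are acquired
#'   in negative-ion mode.
#' @return object of class `msi_spectrum`.
#' @export
msi_spectrum <- function(mz, intensity, x = NA_real_, y = NA_real_,
                         row = NA_integer_, col = NA_integer_,
                         polarity = "negative") {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (length(mz) > 1 && any(diff(mz) <= 0)) stop("mz must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 x = x, y = y, row = row, col = col, polarity = polarity),
            class = "msi_spectrum")
}

#' @export
print.msi_spectrum <- function(x, ...) {
  cat(sprintf("msi_spectrum: %d points, m/z [%.3f, %.3f], TIC %.4g, pixel (%s, %s)\n",
              length(x$mz), min(x$mz), max(x$mz), sum(x$intensity),
              format(x$x), format(x$y)))
  invisible(x)
}

#' Matrix-background species panel
#'
#' Cluster ions of the MALDI matrix observed on off-spot (background) pixels.
#' Background pixels emit only these peaks plus baseline, giving the
#' segmenter a spatially structured background signal distinct from any
#' printed sample.
#' @return a [species_panel()] with a single condition `background`.
#' @export
matrix_background_panel <- function() {
  species_panel(
    name = c("matrix1", "matrix2", "matrix3"),
    mz = c(560.12, 580.23, 620.35),
    base_intensity = c(40, 30, 25),
    background = 1
  )
}

#' Simulate one pixel spectrum
#'
#' Generates a quasi-profile negative-ion spectrum for one raster pixel.
#' Each retained species contributes one peak at jittered m/z whose apex
#' intensity is `base_intensity * fold(condition) * pixel_scale + noise`;
#' the peak is sampled as a narrow Gaussian shape (apex plus two shoulder
#' points per side, width `peak_sigma`, emulating high mass resolution).
#' A chemical-noise baseline is sampled every `baseline_step` Da across the
#' whole observation window at `baseline_level * pixel_scale` plus additive
#' noise, so local-maximum peak detection and MAD noise estimation see a
#' realistic floor. Fully deterministic given `rng_seed`; the caller's RNG
#' state is left untouched.
#'
#' @param panel a [species_panel()].
#' @param condition condition label selecting the panel's fold column; a
#'   missing fold column means fold 1 for every species.
#' @param noise a [noise_model()].
#' @param rng_seed integer seed for this pixel.
#' @param mz_window observation window in m/z (default 550-2000).
#' @param baseline_step spacing of baseline sampling points in Da.
#' @param peak_sigma Gaussian peak width in Da (0 = centroid-only peaks).
#' @return an [msi_spectrum()].
#' @export
simulate_spectrum <- function(panel, condition, noise = noise_model(),
                              rng_seed = 1, mz_window = c(550, 2000),
                              baseline_step = 5, peak_sigma = 0.005) {
  if (nrow(panel) == 0) stop("species panel is empty")
  if (any(panel$mz < mz_window[1] | panel$mz > mz_window[2])) {
    stop("species m/z outside the observation window [",
         mz_window[1], ", ", mz_window[2], "]")
  }
  fold <- fold_for(panel, condition)
  offs <- if (peak_sigma > 0) peak_sigma * (-2:2) else 0
  shape <- if (peak_sigma > 0) exp(-(-2:2)^2 / 2) else 1
  with_local_seed(rng_seed, {
    scale <- if (noise$tic_scale_cv > 0) {
      sdlog <- sqrt(log(1 + noise$tic_scale_cv^2))
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    keep <- if (noise$dropout_prob > 0) {
      stats::runif(nrow(panel)) >= noise$dropout_prob
    } else rep(TRUE, nrow(panel))
    apex_mz <- panel$mz
    if (noise$mz_jitter_sd > 0) {
      apex_mz <- apex_mz + stats::rnorm(length(apex_mz), sd = noise$mz_jitter_sd)
    }
    apex_clean <- panel$base_intensity * fold * scale
    mzs <- as.numeric(outer(offs, apex_mz, "+"))
    ints <- as.numeric(outer(shape, apex_clean, "*"))
    keep_pts <- rep(keep, each = length(offs))
    if (noise$additive_noise_sd > 0) {
      ints <- ints + stats::rnorm(length(ints), sd = noise$additive_noise_sd)
    }
    mzs <- mzs[keep_pts]
    ints <- pmax(ints[keep_pts], 0)
    grid <- seq(mz_window[1], mz_window[2], by = baseline_step)
    base_int <- rep(noise$baseline_level * scale, length(grid))
    if (noise$additive_noise_sd > 0) {
      base_int <- base_int + stats::rnorm(length(grid), sd = noise$additive_noise_sd)
    }
    mzs <- c(mzs, grid)
    ints <- c(ints, pmax(base_int, 0))
    o <- order(mzs)
    mzs <- mzs[o]; ints <- ints[o]
    if (anyDuplicated(mzs)) {
      ints <- as.numeric(tapply(ints, match(mzs, unique(mzs)), sum))
      mzs <- unique(mzs)
    }
    msi_spectrum(mzs, ints)
  })
}

#' Generate a full synthetic array-imaging dataset
#'
#' Simulates one spectrum per raster pixel of `layout`. Pixels inside a spot
#' carry that spot's condition-specific lipid panel; off-spot pixels carry
#' matrix-only background spectra. Ground-truth segment membership (one
#' segment per condition, plus `"background"`) and the planted differential
#' species are returned alongside the spectra. A single integer seed drives
#' one child RNG stream per pixel, so per-pixel reproducibility does not
#' depend on iteration order.
#'
#' @param layout an [make_layout()] object.
#' @param panel a [species_panel()]; default [default_species_panel()].
#' @param noise a [noise_model()].
#' @param seed integer master seed.
#' @param mz_window observation window.
#' @return object of class `msi_dataset`: list with `layout`, `spectra`
#'   (list of [msi_spectrum()]), `pixels` (data frame with coordinates, spot
#'   assignment and `truth_segment`), `truth_differential`, `panel`, `noise`,
#'   `seed`.
#' @export
generate_dataset <- function(layout, panel = default_species_panel(),
                             noise = noise_model(), seed = 1,
                             mz_window = c(550, 2000)) {
  stopifnot(inherits(layout, "array_layout"))
  px <- raster_pixels(layout)
  assign <- map_pixels_to_spots(layout, px)
  px <- merge(px, assign, by = "pixel_id", sort = FALSE)
  px <- px[order(px$pixel_id), , drop = FALSE]
  px$truth_segment <- ifelse(is.na(px$spot_id), "background", px$condition)
  bg_panel <- matrix_background_panel()
  spectra <- lapply(seq_len(nrow(px)), function(i) {
    s_i <- child_seed(seed, px$pixel_id[i])
    sp <- if (is.na(px$spot_id[i])) {
      simulate_spectrum(bg_panel, "background", noise, s_i, mz_window)
    } else {
      simulate_spectrum(panel, px$condition[i], noise, s_i, mz_window)
    }
    sp$x <- px$x[i]; sp$y <- px$y[i]; sp$row <- px$row[i]; sp$col <- px$col[i]
    sp
  })
  conds <- unique(layout$spots$condition)
  truth_diff <- NULL
  if (length(conds) >= 2) {
    ref <- conds[1]
    truth_diff <- do.call(rbind, lapply(conds[-1], function(cond) {
      fc <- fold_for(panel, cond) / fold_for(panel, ref)
      diffd <- is.finite(fc) & fc != 1
      if (!any(diffd)) return(NULL)
      data.frame(species = panel$name[diffd], mz = panel$mz[diffd],
                 condition_ref = ref, condition_alt = cond,
                 true_fold = fc[diffd], stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(layout = layout, spectra = spectra, pixels = px,
         truth_differential = truth_diff, panel = panel, noise = noise,
         seed = seed, mz_window = mz_window),
    class = "msi_dataset"
  )
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("msi_dataset: %d pixels (%d on-spot), %d species, seed %d\n",
              nrow(x$pixels), sum(!is.na(x$pixels$spot_id)), nrow(x$panel),
              x$seed))
  invisible(x)
}

#' Serialize / load a synthetic dataset
#'
#' `write_dataset()` writes a directory with `manifest.json` (layout, panel,
#' noise, seed) and `spectra.csv` (columns `pixel_x`, `pixel_y`, `mz`,
#' `intensity`), the package's tabular spectra dialect. `read_dataset()`
#' rebuilds the dataset; ground-truth pixel labels are recomputed from the
#' layout geometry.
#'
#' @param dataset an [generate_dataset()] object.
#' @param dir output directory (created if absent).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns an `msi_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    layout = list(
      spots = dataset$layout$spots,
      spot_diameter = dataset$layout$spot_diameter,
      raster_spacing = dataset$layout$raster_spacing,
      spot_pitch = dataset$layout$spot_pitch,
      spots_per_sample = dataset$layout$spots_per_sample,
      experiment_id = dataset$layout$experiment_id
    ),
    panel = as.data.frame(dataset$panel),
    noise = unclass(dataset$noise),
    seed = dataset$seed,
    mz_window = dataset$mz_window
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tab <- do.call(rbind, lapply(dataset$spectra, function(sp) {
    data.frame(pixel_x = sp$x, pixel_y = sp$y, mz = sp$mz,
               intensity = sp$intensity)
  }))
  utils::write.csv(tab, file.path(dir, "spectra.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lay <- structure(
    list(spots = manifest$layout$spots,
         spot_diameter = manifest$layout$spot_diameter,
         raster_spacing = manifest$layout$raster_spacing,
         spot_pitch = manifest$layout$spot_pitch,
         spots_per_sample = manifest$layout$spots_per_sample,
         experiment_id = manifest$layout$experiment_id),
    class = "array_layout")
  panel <- manifest$panel
  class(panel) <- c("species_panel", "data.frame")
  noise <- do.call(noise_model, as.list(manifest$noise))
  tab <- utils::read.csv(file.path(dir, "spectra.csv"))
  px <- raster_pixels(lay)
  assign <- map_pixels_to_spots(lay, px)
  px <- merge(px, assign, by = "pixel_id", sort = FALSE)
  px <- px[order(px$pixel_id), , drop = FALSE]
  px$truth_segment <- ifelse(is.na(px$spot_id), "background", px$condition)
  key <- paste(tab$pixel_x, tab$pixel_y)
  spectra <- lapply(seq_len(nrow(px)), function(i) {
    sel <- key == paste(px$x[i], px$y[i])
    msi_spectrum(tab$mz[sel], tab$intensity[sel], x = px$x[i], y = px$y[i],
                 row = px$row[i], col = px$col[i])
  })
  conds <- unique(lay$spots$condition)
  truth_diff <- NULL
  if (length(conds) >= 2) {
    ref <- conds[1]
    truth_diff <- do.call(rbind, lapply(conds[-1], function(cond) {
      fc <- fold_for(panel, cond) / fold_for(panel, ref)
      diffd <- is.finite(fc) & fc != 1
      if (!any(diffd)) return(NULL)
      data.frame(species = panel$name[diffd], mz = panel$mz[diffd],
                 condition_ref = ref, condition_alt = cond,
                 true_fold = fc[diffd], stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(layout = lay, spectra = spectra, pixels = px,
         truth_differential = truth_diff, panel = panel, noise = noise,
         seed = manifest$seed, mz_window = manifest$mz_window),
    class = "msi_dataset")
}
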