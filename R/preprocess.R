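#' Total-ion-current normalization
#'
#' Rescales a spectrum so its intensities sum to `target_tic`. Relative peak
#' ratios are conserved exactly; m/z values are untouched.
#'
#' @param spectrum an [msi_spectrum()].
#' @param target_tic positive target total ion current.
#' @return the normalized `msi_spectrum`.
#' @export
tic_normalize <- function(spectrum, target_tic = 100) {
  stopifnot(inherits(spectrum, "msi_spectrum"), target_tic > 0)
  tic <- sum(spectrum$intensity)
  if (length(spectrum$intensity) == 0 || tic <= 0) {
    stop("degenerate spectrum: empty or zero total ion current")
  }
  spectrum$intensity <- spectrum$intensity * (target_tic / tic)
  spectrum
}

#' Peak picking by local-maximum detection
#'
#' Detects local intensity maxima after optional moving-average smoothing and
#' retains those exceeding `min_snr` times the spectrum's noise level,
#' estimated as the median absolute deviation (MAD) of all intensities. A
#' point is an apex when it is at least as intense as both neighbours and
#' strictly more intense than at least one of them (flat spectra therefore
#' yield zero peaks); boundary points are compared to their single neighbour.
#'
#' @param spectrum an [msi_spectrum()].
#' @param min_snr minimal signal-to-noise ratio over the MAD noise floor.
#' @param window moving-average smoothing width in points (1 = no smoothing),
#'   applied for detection only; apex intensities are taken from the raw
#'   spectrum.
#' @return object of class `msi_peaklist`: list with `mz`, `intensity`
#'   (sorted by m/z), `base_peak_intensity` (maximum before any filtering)
#'   and the pixel coordinates.
#' @export
pick_peaks <- function(spectrum, min_snr = 3, window = 1) {
  stopifnot(inherits(spectrum, "msi_spectrum"))
  n <- length(spectrum$mz)
  if (n == 0) stop("spectrum is empty")
  y <- spectrum$intensity
  ys <- if (window > 1) {
    stats::filter(y, rep(1 / window, window), sides = 2) |>
      (\(v) {v[is.na(v)] <- y[is.na(v)]; as.numeric(v)})()
  } else y
  noise <- stats::mad(y)
  thr <- min_snr * noise
  if (n == 1) {
    is_peak <- ys > thr & ys > 0
  } else {
    # boundary points are padded with themselves, so a flat run (and in
    # particular a flat spectrum) produces no apex at the edges
    left <- c(ys[1], ys[-n])
    right <- c(ys[-1], ys[n])
    is_peak <- ys >= left & ys >= right & (ys > left | ys > right) &
      ys > thr & ys > 0
  }
  new_peaklist(mz = spectrum$mz[is_peak], intensity = y[is_peak],
               base_peak_intensity = if (any(is_peak)) max(y[is_peak]) else 0,
               spectrum = spectrum)
}

new_peaklist <- function(mz, intensity, base_peak_intensity, spectrum = NULL,
                         template = NULL) {
  src <- template %||% spectrum
  structure(list(mz = mz, intensity = intensity,
                 base_peak_intensity = base_peak_intensity,
                 x = src$x, y = src$y, row = src$row, col = src$col),
            class = "msi_peaklist")
}

#' @export
print.msi_peaklist <- function(x, ...) {
  cat(sprintf("msi_peaklist: %d peaks, base peak %.4g, pixel (%s, %s)\n",
              length(x$mz), x$base_peak_intensity, format(x$x), format(x$y)))
  invisible(x)
}

#' Filter peaks below a fraction of the base peak
#'
#' Retains peaks whose intensity is at least `fraction` of the spectrum's
#' strongest peak (ties at the threshold survive: only peaks strictly below
#' it are discarded). The base-peak intensity is recorded before filtering,
#' so the operation is idempotent.
#'
#' @param peaklist an `msi_peaklist` from [pick_peaks()].
#' @param fraction relative intensity threshold in (0, 1); default 0.005,
#'   i.e. 0.5 percent of the base peak.
#' @return filtered `msi_peaklist`.
#' @export
filter_low_peaks <- function(peaklist, fraction = 0.005) {
  stopifnot(inherits(peaklist, "msi_peaklist"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (length(peaklist$mz) == 0) return(peaklist)
  base <- if (peaklist$base_peak_intensity > 0) {
    peaklist$base_peak_intensity
  } else max(peaklist$intensity)
  keep <- peaklist$intensity >= fraction * base
  peaklist$mz <- peaklist$mz[keep]
  peaklist$intensity <- peaklist$intensity[keep]
  peaklist$base_peak_intensity <- base
  peaklist
}

# Extract (mz, intensity) from an msi_spectrum or msi_peaklist.
peak_coords <- function(x) list(mz = x$mz, intensity = x$intensity)

#' Align spectra onto a shared m/z axis
#'
#' Pools the peaks of all spectra, sorts them by m/z and merges neighbours by
#' greedy agglomeration: a new consensus bin starts whenever the gap to the
#' previous peak exceeds `tolerance_ppm` (evaluated at the local m/z). The
#' consensus m/z of each bin is the intensity-weighted mean of its members.
#' Each input spectrum is returned with its peak m/z values replaced by the
#' consensus values (peaks of one spectrum falling in the same bin are
#' summed).
#'
#' @param spectra list of [msi_spectrum()] or `msi_peaklist` objects.
#' @param tolerance_ppm merge tolerance in parts per million.
#' @return list with `spectra` (inputs remapped to the shared axis) and
#'   `bins`, a data frame of consensus bins (`mz`, `mz_min`, `mz_max`,
#'   `n_peaks`).
#' @export
align_spectra <- function(spectra, tolerance_ppm = 20) {
  stopifnot(length(spectra) >= 1)
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0")
  pooled <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    pc <- peak_coords(spectra[[i]])
    if (length(pc$mz) == 0) return(NULL)
    data.frame(origin = i, mz = pc$mz, intensity = pc$intensity)
  }))
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(list(spectra = spectra,
                bins = data.frame(mz = numeric(), mz_min = numeric(),
                                  mz_max = numeric(), n_peaks = integer())))
  }
  pooled <- pooled[order(pooled$mz), , drop = FALSE]
  gap_tol <- tolerance_ppm * 1e-6 * pooled$mz[-nrow(pooled)]
  new_bin <- c(TRUE, diff(pooled$mz) > gap_tol)
  pooled$bin <- cumsum(new_bin)
  wsum <- tapply(pooled$mz * pooled$intensity, pooled$bin, sum)
  isum <- tapply(pooled$intensity, pooled$bin, sum)
  centre <- ifelse(isum > 0, wsum / isum,
                   tapply(pooled$mz, pooled$bin, mean))
  bins <- data.frame(
    mz = as.numeric(centre),
    mz_min = as.numeric(tapply(pooled$mz, pooled$bin, min)),
    mz_max = as.numeric(tapply(pooled$mz, pooled$bin, max)),
    n_peaks = as.integer(tapply(pooled$mz, pooled$bin, length))
  )
  remapped <- spectra
  for (i in seq_along(spectra)) {
    sel <- pooled$origin == i
    if (!any(sel)) next
    b <- pooled$bin[sel]
    ints <- as.numeric(tapply(pooled$intensity[sel], b, sum))
    mzs <- bins$mz[sort(unique(b))]
    if (inherits(spectra[[i]], "msi_peaklist")) {
      remapped[[i]]$mz <- mzs
      remapped[[i]]$intensity <- ints
    } else {
      remapped[[i]] <- msi_spectrum(mzs, ints, x = spectra[[i]]$x,
                                    y = spectra[[i]]$y, row = spectra[[i]]$row,
                                    col = spectra[[i]]$col)
    }
  }
  list(spectra = remapped, bins = bins)
}

#' Build the pixel-by-feature intensity matrix
#'
#' Assembles peak lists into a pixels x consensus-bins matrix: the value is
#' the summed intensity of a pixel's peaks assigned to the bin (nearest bin
#' centre; inputs are expected to come from [align_spectra()], whose remapped
#' peaks sit exactly on bin centres). Missing peaks are 0. All-zero columns
#' are dropped with a warning; all-zero rows (pixels with no surviving peaks)
#' are kept and flagged.
#'
#' @param peaklists list of `msi_peaklist` (or `msi_spectrum`) objects with
#'   pixel coordinates set; duplicate pixels are rejected.
#' @param bins consensus-bin data frame from [align_spectra()].
#' @param params optional list of preprocessing parameters recorded as
#'   provenance.
#' @return object of class `pixel_matrix`: list with `values` (matrix,
#'   row-major pixel order), `mz` (bin centres), `pixels` (data frame with
#'   `pixel_id`, `row`, `col`, `x`, `y`, `all_zero`), `params`.
#' @export
build_pixel_matrix <- function(peaklists, bins, params = list()) {
  stopifnot(length(peaklists) >= 1, nrow(bins) >= 1)
  px <- data.frame(
    x = vapply(peaklists, function(p) as.numeric(p$x), numeric(1)),
    y = vapply(peaklists, function(p) as.numeric(p$y), numeric(1)),
    row = vapply(peaklists, function(p) as.integer(p$row %||% NA_integer_), integer(1)),
    col = vapply(peaklists, function(p) as.integer(p$col %||% NA_integer_), integer(1))
  )
  key <- paste(px$row, px$col, px$x, px$y)
  if (anyDuplicated(key)) stop("duplicate pixels in peak lists")
  ord <- order(px$row, px$col, px$y, px$x)
  centres <- bins$mz
  edges <- c(-Inf, (centres[-length(centres)] + centres[-1]) / 2, Inf)
  values <- matrix(0, nrow = length(peaklists), ncol = length(centres))
  for (i in seq_along(ord)) {
    p <- peaklists[[ord[i]]]
    if (length(p$mz) == 0) next
    bin_of <- findInterval(p$mz, edges)
    for (j in seq_along(bin_of)) {
      values[i, bin_of[j]] <- values[i, bin_of[j]] + p$intensity[j]
    }
  }
  keep_col <- colSums(values) > 0
  if (!all(keep_col)) {
    warning(sum(!keep_col), " all-zero m/z column(s) dropped")
    values <- values[, keep_col, drop = FALSE]
    centres <- centres[keep_col]
  }
  pixels <- px[ord, , drop = FALSE]
  pixels$pixel_id <- seq_len(nrow(pixels))
  pixels$all_zero <- rowSums(values) == 0
  rownames(pixels) <- NULL
  rownames(values) <- paste0("px", pixels$pixel_id)
  colnames(values) <- sprintf("mz_%.4f", centres)
  structure(list(values = values, mz = centres, pixels = pixels,
                 params = params),
            class = "pixel_matrix")
}

#' @export
print.pixel_matrix <- function(x, ...) {
  cat(sprintf("pixel_matrix: %d pixels x %d m/z bins (%d all-zero pixels)\n",
              nrow(x$values), ncol(x$values), sum(x$pixels$all_zero)))
  invisible(x)
}

#' Subset a pixel matrix by pixel
#'
#' @param matrix a [build_pixel_matrix()] object.
#' @param keep logical or integer index over pixels (matrix rows).
#' @param drop_zero_columns drop columns that become all-zero after
#'   subsetting (quietly).
#' @return a `pixel_matrix` over the retained pixels.
#' @export
subset_pixels <- function(matrix, keep, drop_zero_columns = TRUE) {
  stopifnot(inherits(matrix, "pixel_matrix"))
  matrix$values <- matrix$values[keep, , drop = FALSE]
  matrix$pixels <- matrix$pixels[keep, , drop = FALSE]
  if (drop_zero_columns) {
    keep_col <- colSums(matrix$values) > 0
    matrix$values <- matrix$values[, keep_col, drop = FALSE]
    matrix$mz <- matrix$mz[keep_col]
  }
  matrix
}

#' Run the full preprocessing pipeline on a dataset
#'
#' Per pixel: total-ion-current normalization, peak picking, and the
#' 0.5-percent base-peak filter; then cross-pixel alignment of the surviving
#' peaks and assembly of the pixel-by-feature matrix. Pixels whose spectrum
#' has zero total ion current are passed through unnormalized with a warning
#' and end up as all-zero rows.
#'
#' @param dataset an [generate_dataset()] object, or a list of
#'   [msi_spectrum()] objects.
#' @param tolerance_ppm alignment tolerance in ppm.
#' @param min_snr peak-picking signal-to-noise threshold.
#' @param filter_fraction base-peak filter fraction (0.005 = 0.5 percent).
#' @param target_tic normalization target.
#' @param smooth_window smoothing width for peak detection.
#' @return a [build_pixel_matrix()] `pixel_matrix`.
#' @export
preprocess_dataset <- function(dataset, tolerance_ppm = 20, min_snr = 3,
                               filter_fraction = 0.005, target_tic = 100,
                               smooth_window = 1) {
  spectra <- if (inherits(dataset, "msi_dataset")) dataset$spectra else dataset
  stopifnot(length(spectra) >= 1)
  peaklists <- lapply(spectra, function(sp) {
    tic <- sum(sp$intensity)
    if (tic > 0) sp <- tic_normalize(sp, target_tic)
    else warning("pixel (", sp$x, ", ", sp$y, ") has zero TIC; left unnormalized")
    pl <- pick_peaks(sp, min_snr = min_snr, window = smooth_window)
    filter_low_peaks(pl, fraction = filter_fraction)
  })
  al <- align_spectra(peaklists, tolerance_ppm = tolerance_ppm)
  build_pixel_matrix(al$spectra, al$bins,
                     params = list(tolerance_ppm = tolerance_ppm,
                                   min_snr = min_snr,
                                   filter_fraction = filter_fraction,
                                   target_tic = target_tic,
                                   smooth_window = smooth_window))
}
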