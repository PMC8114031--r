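#' Create a printed-microarray layout
#'
#' Describes the geometry of a printed membrane microarray as imaged by
#' MALDI-MSI: spot centres, spot diameter, and the raster spacing of the
#' acquisition grid. Defaults reproduce the acquisition geometry of the
#' EV-membrane arrays this package models: 450 um spots rastered every
#' 150 um, which yields nine pixels per spot.
#'
#' Spots are placed on a regular grid with one sample per grid row and
#' `spots_per_sample` replicate spots per row. The spot pitch is a multiple of
#' `raster_spacing`, so the raster is phase-aligned to every spot centre (a
#' raster node falls exactly on each centre).
#'
#' @param n_samples number of printed samples (one grid row each).
#' @param spots_per_sample replicate spots printed per sample (3-5 on the
#'   arrays modelled here; other values are allowed).
#' @param spot_diameter printed spot diameter in um.
#' @param raster_spacing spacing of the acquisition raster in um.
#' @param conditions condition label per sample (recycled); default alternates
#'   `"wt"` and `"cd9ko"`.
#' @param spot_pitch centre-to-centre spot distance in um; default is the
#'   smallest multiple of `raster_spacing` strictly greater than
#'   `spot_diameter + raster_spacing`, guaranteeing non-overlapping spots.
#' @param experiment_id label of the replicate experiment the array belongs to.
#'
#' @return An object of class `array_layout`: a list with a `spots` data frame
#'   (`spot_id`, `sample_id`, `condition`, `x`, `y`), the geometry parameters
#'   and the experiment label.
#' @examples
#' lay <- make_layout(n_samples = 2, spots_per_sample = 4)
#' pixels_per_spot(450, 150)  # 9
#' @export
make_layout <- function(n_samples = 2, spots_per_sample = 4,
                        spot_diameter = 450, raster_spacing = 150,
                        conditions = c("wt", "cd9ko"),
                        spot_pitch = NULL,
                        experiment_id = "exp1") {
  stopifnot(n_samples >= 1, spots_per_sample >= 1)
  if (spot_diameter <= 0) stop("spot_diameter must be > 0")
  if (raster_spacing <= 0) stop("raster_spacing must be > 0")
  if (is.null(spot_pitch)) {
    spot_pitch <- raster_spacing *
      ceiling((spot_diameter + raster_spacing) / raster_spacing)
  }
  if (spot_pitch %% raster_spacing != 0) {
    stop("spot_pitch must be a multiple of raster_spacing (phase-aligned raster)")
  }
  if (spot_pitch <= spot_diameter) {
    stop("spot_pitch must exceed spot_diameter: spots would overlap")
  }
  conditions <- rep_len(conditions, n_samples)
  spots <- do.call(rbind, lapply(seq_len(n_samples), function(i) {
    data.frame(
      spot_id = sprintf("s%02d_r%d", i, seq_len(spots_per_sample)),
      sample_id = sprintf("s%02d", i),
      condition = conditions[i],
      x = (seq_len(spots_per_sample) - 1) * spot_pitch,
      y = (i - 1) * spot_pitch,
      stringsAsFactors = FALSE
    )
  }))
  rownames(spots) <- NULL
  structure(
    list(spots = spots, spot_diameter = spot_diameter,
         raster_spacing = raster_spacing, spot_pitch = spot_pitch,
         spots_per_sample = spots_per_sample,
         experiment_id = experiment_id),
    class = "array_layout"
  )
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf(
    "array_layout: %d spots (%d samples x %d replicates), diameter %g um, raster %g um, experiment '%s'\n",
    nrow(x$spots), length(unique(x$spots$sample_id)), x$spots_per_sample,
    x$spot_diameter, x$raster_spacing, x$experiment_id))
  invisible(x)
}

#' Raster pixel grid covering a layout
#'
#' Enumerates the acquisition raster: an axis-aligned grid with
#' `raster_spacing` pitch, phase-aligned to the spot centres, covering every
#' spot plus one spacing of background margin. Pixels are listed in row-major
#' order with 0-based `row`/`col` indices.
#'
#' @param layout an [make_layout()] object.
#' @return data frame with `pixel_id`, `row`, `col`, `x`, `y` (um).
#' @export
raster_pixels <- function(layout) {
  s <- layout$raster_spacing
  r_ext <- s * ceiling((layout$spot_diameter / 2) / s)
  xs <- seq(min(layout$spots$x) - r_ext - s, max(layout$spots$x) + r_ext + s, by = s)
  ys <- seq(min(layout$spots$y) - r_ext - s, max(layout$spots$y) + r_ext + s, by = s)
  grid <- expand.grid(col = seq_along(xs) - 1L, row = seq_along(ys) - 1L)
  grid <- grid[order(grid$row, grid$col), , drop = FALSE]
  data.frame(
    pixel_id = seq_len(nrow(grid)),
    row = grid$row, col = grid$col,
    x = xs[grid$col + 1L], y = ys[grid$row + 1L]
  )
}

#' Pixels recorded per spot for a given geometry
#'
#' Counts raster nodes falling inside one spot (Euclidean distance from the
#' spot centre less than or equal to the radius), for a raster phase-aligned
#' to the centre. With the default 450 um spots and 150 um raster this is 9.
#'
#' @param spot_diameter spot diameter in um.
#' @param raster_spacing raster spacing in um.
#' @return integer pixel count.
#' @export
pixels_per_spot <- function(spot_diameter = 450, raster_spacing = 150) {
  if (spot_diameter <= 0 || raster_spacing <= 0) stop("geometry must be positive")
  radius <- spot_diameter / 2
  m <- ceiling(radius / raster_spacing)
  offs <- seq(-m, m) * raster_spacing
  grid <- expand.grid(dx = offs, dy = offs)
  sum(sqrt(grid$dx^2 + grid$dy^2) <= radius)
}
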