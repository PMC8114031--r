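#' Assign raster pixels to printed spots
#'
#' A pixel belongs to a spot iff its centre lies within the spot circle
#' (Euclidean distance from the spot centre less than or equal to the
#' radius, so boundary pixels are assigned); all other pixels are
#' background. A pixel falling inside two spots violates the layout's
#' non-overlap invariant and is an error.
#'
#' @param layout an [make_layout()] object.
#' @param pixels data frame with `pixel_id`, `x`, `y` (e.g. from
#'   [raster_pixels()]).
#' @return data frame with `pixel_id`, `spot_id` (`NA` for background),
#'   `sample_id`, `condition`, `experiment_id`.
#' @export
map_pixels_to_spots <- function(layout, pixels) {
  stopifnot(inherits(layout, "array_layout"))
  radius <- layout$spot_diameter / 2
  dx <- outer(pixels$x, layout$spots$x, "-")
  dy <- outer(pixels$y, layout$spots$y, "-")
  inside <- sqrt(dx^2 + dy^2) <= radius
  hits <- rowSums(inside)
  if (any(hits > 1)) {
    bad <- pixels$pixel_id[which(hits > 1)[1]]
    stop("pixel ", bad, " lies inside two spots; layout invariant violated")
  }
  spot_idx <- apply(inside, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  data.frame(
    pixel_id = pixels$pixel_id,
    spot_id = layout$spots$spot_id[spot_idx],
    sample_id = layout$spots$sample_id[spot_idx],
    condition = layout$spots$condition[spot_idx],
    experiment_id = layout$experiment_id,
    stringsAsFactors = FALSE
  )
}

#' Aggregate pixel intensities to spot level
#'
#' The printed spot replicate is the statistical unit of the differential
#' analysis: for each spot, the mean intensity of each m/z feature over the
#' spot's pixels (normally nine) is computed. Background pixels are
#' excluded.
#'
#' @param matrix a [build_pixel_matrix()] `pixel_matrix` whose pixels carry
#'   coordinates.
#' @param assignment data frame from [map_pixels_to_spots()] for the same
#'   pixels (matched on `x`/`y` coordinates via the raster grid).
#' @param layout the [make_layout()] object (to detect spots with no
#'   assigned pixel, which is an error naming the spot).
#' @return long data frame of spot summaries: `spot_id`, `sample_id`,
#'   `condition`, `experiment_id`, `n_pixels`, `mz`, `species`,
#'   `mean_intensity`.
#' @export
aggregate_spot_intensities <- function(matrix, assignment, layout = NULL) {
  stopifnot(inherits(matrix, "pixel_matrix"))
  px <- matrix$pixels
  m <- merge(cbind(px, idx = seq_len(nrow(px))), assignment,
             by = "pixel_id", sort = FALSE)
  m <- m[!is.na(m$spot_id), , drop = FALSE]
  if (!is.null(layout)) {
    missing <- setdiff(layout$spots$spot_id, unique(m$spot_id))
    if (length(missing) > 0) {
      stop("spot(s) with no assigned pixel: ", paste(missing, collapse = ", "))
    }
  }
  if (nrow(m) == 0) stop("no on-spot pixels")
  out <- do.call(rbind, lapply(split(m, m$spot_id), function(g) {
    vals <- matrix$values[g$idx, , drop = FALSE]
    data.frame(
      spot_id = g$spot_id[1], sample_id = g$sample_id[1],
      condition = g$condition[1], experiment_id = g$experiment_id[1],
      n_pixels = nrow(g),
      mz = matrix$mz,
      species = colnames(matrix$values),
      mean_intensity = colMeans(vals),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample Student t-test
#'
#' Closed-form two-sided t-test; the pooled-variance (classic Student)
#' variant is the default, Welch available. When both groups have zero
#' variance: equal means give `t = 0, p = 1`; different means are a
#' degenerate infinite-t case, flagged with a warning and `p = 0`.
#'
#' @param group_a,group_b numeric vectors, each of length at least 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
student_t_test <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 observations")
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (variant == "pooled") {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- if (se > 0) (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)) else na + nb - 2
  }
  if (se == 0) {
    if (ma == mb) {
      return(list(t = 0, df = df, p = 1, mean_a = ma, mean_b = mb))
    }
    warning("zero variance in both groups with unequal means: t is infinite")
    return(list(t = sign(ma - mb) * Inf, df = df, p = 0,
                mean_a = ma, mean_b = mb))
  }
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb)
}

#' Per-species differential test within one experiment
#'
#' Runs [student_t_test()] for every m/z feature, comparing spot-replicate
#' mean intensities between two conditions of one replicate experiment.
#'
#' @param spot_summaries data frame from [aggregate_spot_intensities()].
#' @param condition_a,condition_b the two condition labels to compare
#'   (defaults: the first two present, in order of appearance).
#' @param alpha significance level for the `significant` flag.
#' @param variant t-test variant, see [student_t_test()].
#' @param p_adjust `"none"` (default, mirroring the original reporting; a
#'   notice is logged) or `"BH"` for Benjamini-Hochberg adjustment across
#'   species within each experiment.
#' @return data frame with one row per (experiment, species): `species`,
#'   `mz`, `experiment_id`, `mean_a`, `mean_b`, `direction` (+1 when the
#'   second condition is higher), `t`, `df`, `p`, `significant`.
#' @export
test_lipid_differences <- function(spot_summaries, condition_a = NULL,
                                   condition_b = NULL, alpha = 0.05,
                                   variant = "pooled",
                                   p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  conds <- unique(spot_summaries$condition)
  condition_a <- condition_a %||% conds[1]
  condition_b <- condition_b %||% setdiff(conds, condition_a)[1]
  stopifnot(condition_a %in% conds, condition_b %in% conds)
  out <- do.call(rbind, lapply(
    split(spot_summaries,
          list(spot_summaries$experiment_id, spot_summaries$species),
          drop = TRUE),
    function(g) {
      a <- g$mean_intensity[g$condition == condition_a]
      b <- g$mean_intensity[g$condition == condition_b]
      tt <- suppressWarnings(student_t_test(a, b, variant = variant))
      data.frame(
        species = g$species[1], mz = g$mz[1],
        experiment_id = g$experiment_id[1],
        mean_a = tt$mean_a, mean_b = tt$mean_b,
        direction = sign(tt$mean_b - tt$mean_a),
        t = tt$t, df = tt$df, p = tt$p,
        significant = tt$p < alpha,
        stringsAsFactors = FALSE
      )
    }))
  rownames(out) <- NULL
  if (p_adjust == "BH") {
    out$p <- stats::ave(out$p, out$experiment_id,
                        FUN = function(p) stats::p.adjust(p, "BH"))
    out$significant <- out$p < alpha
  } else {
    message("no multiple-testing correction applied (p_adjust = \"none\"); ",
            "false positives are controlled by the dual-replicate rule")
  }
  out[order(out$mz), , drop = FALSE]
}

#' Dual-replicate significance filter
#'
#' The reporting rule for differential lipid forms: a species is retained
#' only if it is statistically significant (`p < alpha`) in both independent
#' replicate experiments, with concordant effect direction. Species tested
#' in only one experiment are excluded with a warning.
#'
#' @param results_exp1,results_exp2 data frames from
#'   [test_lipid_differences()], one per replicate experiment.
#' @param alpha significance level (default 0.05).
#' @return data frame of retained species: `species`, `mz`, `p_exp1`,
#'   `p_exp2`, `direction`.
#' @export
dual_replicate_filter <- function(results_exp1, results_exp2, alpha = 0.05) {
  common <- intersect(results_exp1$species, results_exp2$species)
  lonely <- c(setdiff(results_exp1$species, common),
              setdiff(results_exp2$species, common))
  if (length(lonely) > 0) {
    warning("species tested in only one experiment excluded: ",
            paste(lonely, collapse = ", "))
  }
  r1 <- results_exp1[match(common, results_exp1$species), , drop = FALSE]
  r2 <- results_exp2[match(common, results_exp2$species), , drop = FALSE]
  hit <- r1$p < alpha & r2$p < alpha &
    r1$direction == r2$direction & r1$direction != 0
  out <- data.frame(species = common[hit], mz = r1$mz[hit],
                    p_exp1 = r1$p[hit], p_exp2 = r2$p[hit],
                    direction = r1$direction[hit], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$mz), , drop = FALSE]
}
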