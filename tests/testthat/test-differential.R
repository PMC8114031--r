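test_that("pixel-to-spot assignment matches a brute-force distance check", {
  lay <- make_layout(n_samples = 2, spots_per_sample = 4)
  px <- raster_pixels(lay)
  assign <- map_pixels_to_spots(lay, px)
  # oracle: per-pixel scan over all spots
  r <- lay$spot_diameter / 2
  for (i in sample(nrow(px), 60)) {
    dists <- sqrt((px$x[i] - lay$spots$x)^2 + (px$y[i] - lay$spots$y)^2)
    expected <- if (any(dists <= r)) lay$spots$spot_id[which(dists <= r)] else NA_character_
    expect_identical(assign$spot_id[i], expected)
  }
})

test_that("a pixel exactly on the spot boundary is assigned to the spot", {
  lay <- make_layout(n_samples = 1, spots_per_sample = 1, spot_diameter = 300,
                     raster_spacing = 150)
  px <- data.frame(pixel_id = 1L, x = lay$spots$x + 150, y = lay$spots$y)
  expect_identical(map_pixels_to_spots(lay, px)$spot_id, lay$spots$spot_id)
})

test_that("overlapping spots are detected as a layout violation", {
  lay <- make_layout(n_samples = 1, spots_per_sample = 2)
  lay$spots$x[2] <- lay$spots$x[1] + 100  # force overlap
  px <- data.frame(pixel_id = 1L, x = lay$spots$x[1] + 50, y = lay$spots$y[1])
  expect_error(map_pixels_to_spots(lay, px), "two spots")
})

test_that("spot aggregation averages pixel intensities per species", {
  lay <- make_layout(n_samples = 1, spots_per_sample = 1)
  px <- raster_pixels(lay)
  assign <- map_pixels_to_spots(lay, px)
  on_idx <- which(!is.na(assign$spot_id))
  vals <- matrix(0, nrow(px), 2)
  vals[on_idx, 1] <- 7          # all nine pixels equal
  vals[on_idx, 2] <- 1:9        # mean 5
  pm <- toy_pixel_matrix(vals)
  pm$pixels <- data.frame(x = px$x, y = px$y, row = px$row, col = px$col,
                          pixel_id = px$pixel_id,
                          all_zero = rowSums(vals) == 0)
  spots <- aggregate_spot_intensities(pm, assign, lay)
  expect_identical(nrow(spots), 2L)
  expect_true(all(spots$n_pixels == 9))
  expect_equal(spots$mean_intensity, c(7, 5))

  # a spot with no assigned pixels is an error naming the spot
  assign_bad <- assign
  assign_bad$spot_id[] <- NA_character_
  expect_error(aggregate_spot_intensities(pm, assign_bad, lay),
               lay$spots$spot_id[1], fixed = TRUE)
})

test_that("zero-noise spot means equal the generator's expected values", {
  panel <- default_species_panel()
  lay <- make_layout(n_samples = 2, spots_per_sample = 3)
  ds <- generate_dataset(lay, panel = panel,
                         noise = noise_model(0, 0, 0, 0.5, 0), seed = 3)
  pm <- preprocess_dataset(ds)
  assign <- map_pixels_to_spots(lay, pm$pixels)
  spots <- aggregate_spot_intensities(pm, assign, lay)
  spots$species <- match_bins_to_species(spots$mz, spots$species, panel)
  # expected: TIC-normalized apex intensity, identical for every wt spot
  sm_wt <- spots$mean_intensity[spots$species == "SM(d34:1)" &
                                  spots$condition == "wt"]
  expect_equal(max(sm_wt) - min(sm_wt), 0)
  sm_ko <- spots$mean_intensity[spots$species == "SM(d34:1)" &
                                  spots$condition == "cd9ko"]
  expect_equal(unique(sm_ko) / unique(sm_wt), 1.5, tolerance = 1e-9)
})

test_that("the Student t-test matches its closed form and stats::t.test", {
  same <- c(1, 2, 3)
  out <- student_t_test(same, same)
  expect_identical(out$t, 0)
  expect_identical(out$p, 1)

  shifted <- student_t_test(c(1, 2, 3), c(1001, 1002, 1003) + rnorm(3, sd = 1e-4))
  expect_lt(shifted$p, 1e-10)

  set.seed(10)
  for (rep in 1:50) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    mine <- student_t_test(a, b, "pooled")
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    # independent closed-form evaluation
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    t_cf <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    expect_equal(mine$t, t_cf, tolerance = 1e-12)

    w <- student_t_test(a, b, "welch")
    refw <- t.test(a, b)
    expect_equal(w$t, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(refw$parameter), tolerance = 1e-10)
    expect_equal(w$p, refw$p.value, tolerance = 1e-12)
  }

  expect_error(student_t_test(1, c(1, 2)), "at least 2")
  expect_warning(out <- student_t_test(c(1, 1), c(2, 2)), "zero variance")
  expect_identical(out$p, 0)
})

test_that("the dual-replicate rule keeps only concordant double hits", {
  mk <- function(species, p, direction) {
    data.frame(species = species, mz = seq_along(species), p = p,
               direction = direction, stringsAsFactors = FALSE)
  }
  r1 <- mk(c("a", "b", "c", "d"), c(0.04, 0.04, 0.20, 0.01), c(1, 1, 1, 1))
  r2 <- mk(c("a", "b", "c", "d"), c(0.04, 0.30, 0.01, 0.01), c(1, 1, 1, -1))
  hits <- dual_replicate_filter(r1, r2)
  expect_identical(hits$species, "a")   # b: ns in exp2; c: ns in exp1; d: discordant

  # species present in one experiment only are excluded with a warning
  expect_warning(h2 <- dual_replicate_filter(r1, mk("a", 0.01, 1)), "only one")
  expect_identical(h2$species, "a")
})

test_that("under the null the dual-replicate pass rate is far below alpha", {
  set.seed(123)
  n_species <- 1000
  run_null <- function() {
    res <- lapply(seq_len(n_species), function(i) {
      tt <- student_t_test(rnorm(4), rnorm(4))
      data.frame(species = paste0("s", i), mz = i, p = tt$p,
                 direction = sign(tt$mean_b - tt$mean_a))
    })
    do.call(rbind, res)
  }
  hits <- dual_replicate_filter(run_null(), run_null())
  expect_lte(nrow(hits) / n_species, 0.01)

  # set inclusion: every hit is individually significant in both experiments
  r1 <- run_null(); r2 <- run_null()
  hits2 <- dual_replicate_filter(r1, r2, alpha = 0.3)
  expect_true(all(hits2$species %in% r1$species[r1$p < 0.3]))
  expect_true(all(hits2$species %in% r2$species[r2$p < 0.3]))
})

test_that("optional Benjamini-Hochberg adjustment matches p.adjust", {
  lay <- make_layout(n_samples = 2, spots_per_sample = 4)
  ds <- generate_dataset(lay, seed = 17)
  pm <- suppressWarnings(preprocess_dataset(ds))
  spots <- aggregate_spot_intensities(pm, map_pixels_to_spots(lay, pm$pixels), lay)
  expect_message(raw <- test_lipid_differences(spots, "wt", "cd9ko"),
                 "no multiple-testing correction")
  adj <- test_lipid_differences(spots, "wt", "cd9ko", p_adjust = "BH")
  expect_equal(adj$p, p.adjust(raw$p, "BH"))
  expect_true(all(adj$p >= raw$p - 1e-15))
})

test_that("significance score and p-value are exact duals at the threshold", {
  expect_equal(significance_score(0.01), 20)
  expect_equal(significance_to_p(20), 0.01)
  p <- runif(20)
  expect_equal(significance_to_p(significance_score(p)), p, tolerance = 1e-12)
})
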