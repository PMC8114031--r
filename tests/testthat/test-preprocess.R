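test_that("TIC normalization hits the target exactly and preserves ratios", {
  sp <- msi_spectrum(c(600, 700), c(2, 2))
  expect_equal(tic_normalize(sp, 1)$intensity, c(0.5, 0.5))

  already <- msi_spectrum(c(600, 700, 800), c(10, 30, 60))
  expect_equal(tic_normalize(already, 100)$intensity, already$intensity)

  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    sp <- msi_spectrum(sort(runif(n, 550, 2000)), rexp(n, 1 / 10))
    out <- tic_normalize(sp, 100)
    expect_lt(abs(sum(out$intensity) - 100) / 100, 1e-9)
    nz <- sp$intensity > 0
    expect_equal(out$intensity[nz] / out$intensity[nz][1],
                 sp$intensity[nz] / sp$intensity[nz][1])
    expect_identical(out$mz, sp$mz)
  }

  expect_error(tic_normalize(msi_spectrum(c(600, 700), c(0, 0))), "degenerate")
})

test_that("peak picking finds isolated apexes and nothing on flat spectra", {
  # single Gaussian peak on zero baseline
  mz <- seq(700, 701, by = 0.01)
  y <- 50 * exp(-(mz - 700.5)^2 / (2 * 0.02^2))
  y[y < 1e-6] <- 0
  pl <- pick_peaks(msi_spectrum(mz, y))
  expect_length(pl$mz, 1)
  expect_equal(pl$mz, 700.5)
  expect_equal(pl$intensity, max(y))

  flat <- msi_spectrum(seq(600, 650, by = 1), rep(3, 51))
  expect_length(pick_peaks(flat)$mz, 0)
})

test_that("all species of a 12-lipid panel are picked at high SNR", {
  panel <- default_species_panel()
  noise <- noise_model(additive_noise_sd = 2)  # weakest species at SNR 20
  for (seed in 1:5) {
    sp <- simulate_spectrum(panel, "wt", noise, rng_seed = seed)
    pl <- pick_peaks(tic_normalize(sp), min_snr = 5)
    expect_length(pl$mz, 12)
    expect_true(all(abs(pl$mz - sort(panel$mz)) < 0.05))
  }
})

test_that("base-peak filtering matches a brute-force oracle and is idempotent", {
  pl <- spotMSI:::new_peaklist(mz = c(600, 700, 800),
                               intensity = c(100, 0.6, 0.4),
                               base_peak_intensity = 100,
                               spectrum = list(x = 0, y = 0, row = 0L, col = 0L))
  expect_length(filter_low_peaks(pl)$mz, 2)

  single <- random_peaklist(1)
  expect_length(filter_low_peaks(single)$mz, 1)

  expect_error(filter_low_peaks(pl, fraction = 0), "fraction")
  expect_error(filter_low_peaks(pl, fraction = 1), "fraction")

  set.seed(21)
  for (rep in 1:200) {
    pl <- random_peaklist(sample(1:40, 1))
    out <- filter_low_peaks(pl, 0.005)
    keep <- pl$intensity >= 0.005 * max(pl$intensity)  # oracle
    expect_identical(out$mz, pl$mz[keep])
    expect_identical(out$intensity, pl$intensity[keep])
    expect_identical(filter_low_peaks(out, 0.005), out)
  }
})

test_that("alignment merges within tolerance and keeps distinct species apart", {
  s1 <- msi_spectrum(703.57, 10, x = 0, y = 0)
  s2 <- msi_spectrum(703.58, 30, x = 150, y = 0)
  al <- align_spectra(list(s1, s2), tolerance_ppm = 20)
  expect_identical(nrow(al$bins), 1L)
  expect_equal(al$bins$mz, (703.57 * 10 + 703.58 * 30) / 40)

  s3 <- msi_spectrum(c(703.5, 760.6), c(5, 5))
  al2 <- align_spectra(list(s3), tolerance_ppm = 20)
  expect_identical(nrow(al2$bins), 2L)

  expect_error(align_spectra(list(s1), tolerance_ppm = 0), "tolerance")

  # jittered dataset (jitter sd = tolerance/4): one consensus bin per species
  panel <- default_species_panel()
  noise <- noise_model(tic_scale_cv = 0, mz_jitter_sd = 0.0035,
                       additive_noise_sd = 0, baseline_level = 0.5)
  pls <- lapply(1:40, function(i) {
    sp <- simulate_spectrum(panel, "wt", noise, rng_seed = i)
    sp$x <- i * 150; sp$y <- 0
    pick_peaks(sp)
  })
  al3 <- align_spectra(pls, tolerance_ppm = 20)
  expect_identical(nrow(al3$bins), nrow(panel))
})

test_that("the pixel matrix is faithful to its peak lists", {
  one <- spotMSI:::new_peaklist(mz = 700, intensity = 42,
                                base_peak_intensity = 42,
                                spectrum = list(x = 0, y = 0, row = 0L, col = 0L))
  m <- build_pixel_matrix(list(one), data.frame(mz = 700))
  expect_identical(dim(m$values), c(1L, 1L))
  expect_equal(m$values[1, 1], 42)

  # a pixel with no surviving peaks is kept as a flagged all-zero row
  none <- spotMSI:::new_peaklist(mz = numeric(), intensity = numeric(),
                                 base_peak_intensity = 0,
                                 spectrum = list(x = 150, y = 0, row = 0L, col = 1L))
  m2 <- build_pixel_matrix(list(one, none), data.frame(mz = 700))
  expect_equal(unname(m2$values[, 1]), c(42, 0))
  expect_identical(m2$pixels$all_zero, c(FALSE, TRUE))

  dup <- spotMSI:::new_peaklist(mz = 700, intensity = 1, base_peak_intensity = 1,
                                spectrum = list(x = 0, y = 0, row = 0L, col = 0L))
  expect_error(build_pixel_matrix(list(one, dup), data.frame(mz = 700)),
               "duplicate")
})

test_that("matrix row sums equal independently computed post-filter TICs", {
  lay <- make_layout(n_samples = 2, spots_per_sample = 3)
  ds <- generate_dataset(lay, seed = 9)
  pm <- suppressWarnings(preprocess_dataset(ds))
  # oracle: per-pixel sum of filtered peak intensities, computed without the
  # alignment/matrix machinery
  oracle <- vapply(ds$spectra, function(sp) {
    pl <- filter_low_peaks(pick_peaks(tic_normalize(sp, 100)), 0.005)
    sum(pl$intensity)
  }, numeric(1))
  key_ds <- paste(ds$pixels$x, ds$pixels$y)
  key_pm <- paste(pm$pixels$x, pm$pixels$y)
  expect_equal(unname(rowSums(pm$values)), oracle[match(key_pm, key_ds)],
               tolerance = 1e-12)
})

test_that("preprocessing is deterministic and recovers zero-noise truth", {
  panel <- default_species_panel()
  lay <- make_layout(n_samples = 2, spots_per_sample = 3)
  ds <- generate_dataset(lay, panel = panel,
                         noise = noise_model(0, 0, 0, 0.5, 0), seed = 1)
  pm1 <- preprocess_dataset(ds)
  pm2 <- preprocess_dataset(ds)
  expect_identical(pm1, pm2)
  # consensus bins sit exactly on the generated species (plus matrix peaks)
  expect_true(all(vapply(panel$mz, function(m) any(abs(pm1$mz - m) < 1e-9),
                         logical(1))))
  # per-condition intensity ratios equal the configured folds
  assign <- map_pixels_to_spots(lay, pm1$pixels)
  sm_col <- which.min(abs(pm1$mz - 687.545))
  pc_col <- which.min(abs(pm1$mz - 744.555))
  wt_rows <- which(assign$condition == "wt")
  ko_rows <- which(assign$condition == "cd9ko")
  expect_equal(mean(pm1$values[ko_rows, sm_col]) /
                 mean(pm1$values[wt_rows, sm_col]), 1.5, tolerance = 1e-9)
  expect_equal(mean(pm1$values[ko_rows, pc_col]) /
                 mean(pm1$values[wt_rows, pc_col]), 0.7, tolerance = 1e-9)
})
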