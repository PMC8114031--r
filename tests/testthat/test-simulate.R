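# intensity of the peak apex closest to a species m/z
apex_intensity <- function(spectrum, mz) {
  spectrum$intensity[which.min(abs(spectrum$mz - mz))]
}

test_that("zero-noise spectra are exact deterministic functions of the panel", {
  panel <- default_species_panel()
  sp <- simulate_spectrum(panel, "wt", zero_noise(), rng_seed = 3)
  for (i in seq_len(nrow(panel))) {
    expect_equal(apex_intensity(sp, panel$mz[i]), panel$base_intensity[i])
  }
  sp_ko <- simulate_spectrum(panel, "cd9ko", zero_noise(), rng_seed = 99)
  expect_equal(
    vapply(panel$mz, function(m) apex_intensity(sp_ko, m), numeric(1)),
    panel$base_intensity * panel$fold_cd9ko
  )
})

test_that("spectra are reproducible for a seed and differ across seeds", {
  panel <- default_species_panel()
  a <- simulate_spectrum(panel, "wt", noise_model(), rng_seed = 7)
  b <- simulate_spectrum(panel, "wt", noise_model(), rng_seed = 7)
  c <- simulate_spectrum(panel, "wt", noise_model(), rng_seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("species outside the observation window are rejected", {
  bad <- species_panel("X", mz = 2100, base_intensity = 10, wt = 1)
  expect_error(simulate_spectrum(bad, "wt", zero_noise()), "window")
})

test_that("configured fold changes are recovered by Monte-Carlo means", {
  panel <- species_panel(c("SMx", "PCx"), mz = c(687.5, 744.6),
                         base_intensity = c(60, 100),
                         wt = 1, cd9ko = c(2, 1))
  noise <- noise_model()  # documented defaults
  n <- 2000
  grab <- function(cond, off) vapply(seq_len(n), function(i) {
    sp <- simulate_spectrum(panel, cond, noise, rng_seed = off + i,
                            mz_window = c(550, 800))
    apex_intensity(sp, 687.5)
  }, numeric(1))
  wt <- grab("wt", 0); ko <- grab("cd9ko", n)
  ratio <- mean(ko) / mean(wt)
  se_ratio <- ratio * sqrt(var(ko) / n / mean(ko)^2 + var(wt) / n / mean(wt)^2)
  expect_lt(abs(ratio - 2), 3 * se_ratio)
})

test_that("generated datasets carry consistent ground truth", {
  lay <- make_layout(n_samples = 2, spots_per_sample = 3)
  ds <- generate_dataset(lay, seed = 5)
  expect_identical(sum(!is.na(ds$pixels$spot_id)), 2L * 3L * 9L)
  expect_length(ds$spectra, nrow(ds$pixels))
  # truth labels round-trip through the geometric spot assignment
  assign <- map_pixels_to_spots(lay, ds$pixels)
  on_spot <- !is.na(assign$spot_id)
  expect_identical(ds$pixels$truth_segment[on_spot], assign$condition[on_spot])
  expect_true(all(ds$pixels$truth_segment[!on_spot] == "background"))
  # planted differentials follow the panel's fold columns
  expect_setequal(ds$truth_differential$species,
                  ds$panel$name[ds$panel$fold_cd9ko != 1])
})

test_that("zero-noise disjoint conditions give exactly two on-spot row patterns", {
  panel <- species_panel(c("A1", "A2", "B1", "B2"),
                         mz = c(600, 650, 700, 750),
                         base_intensity = c(50, 80, 60, 90),
                         condA = c(1, 1, 0, 0), condB = c(0, 0, 1, 1))
  lay <- make_layout(n_samples = 2, spots_per_sample = 3,
                     conditions = c("condA", "condB"))
  ds <- generate_dataset(lay, panel = panel, noise = zero_noise(), seed = 2)
  pm <- suppressWarnings(preprocess_dataset(ds))
  on_spot <- !is.na(map_pixels_to_spots(lay, pm$pixels)$spot_id)
  patterns <- unique(apply(pm$values[on_spot, , drop = FALSE], 1, paste,
                           collapse = "|"))
  expect_length(patterns, 2)
})

test_that("serialization round-trips and is byte-identical for equal seeds", {
  lay <- make_layout(n_samples = 1, spots_per_sample = 3)
  ds <- generate_dataset(lay, seed = 42)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  write_dataset(ds, d1)
  write_dataset(generate_dataset(lay, seed = 42), d2)
  expect_identical(readBin(file.path(d1, "spectra.csv"), "raw", 2e6),
                   readBin(file.path(d2, "spectra.csv"), "raw", 2e6))
  back <- read_dataset(d1)
  expect_equal(length(back$spectra), length(ds$spectra))
  expect_equal(back$spectra[[10]]$mz, ds$spectra[[10]]$mz, tolerance = 1e-12)
  expect_identical(back$pixels$truth_segment, ds$pixels$truth_segment)
  # a different seed produces different content
  d3 <- file.path(tempdir(), "ds3")
  write_dataset(generate_dataset(lay, seed = 43), d3)
  expect_false(identical(readBin(file.path(d1, "spectra.csv"), "raw", 2e6),
                         readBin(file.path(d3, "spectra.csv"), "raw", 2e6)))
})
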