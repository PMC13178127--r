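small_bands <- function(p_c = 0.5, p_t = 0.5, n = 3, rho_group = NULL,
                        logsd = 0.6) {
  band_definition(
    center = seq(460, by = 15, length.out = n), fwhm = 8,
    lineshape = "lorentzian", p_occur_control = p_c, p_occur_treated = p_t,
    intensity_logsd = logsd,
    group_id = rho_group %||% rep(NA_character_, n)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("band library covers the printed fingerprint bands with assignments", {
  lib <- default_band_library()
  expect_gte(nrow(lib), 20)
  phe <- lib[lib$center == 1002, ]
  expect_match(phe$assignment, "phenylalanine")
  pi_band <- lib[lib$center == 787, ]
  expect_match(pi_band$assignment, "phosphatidylinositol")
  expect_true(all(lib$class %in% c("protein", "lipid", "unassigned")))
  des <- simulation_design()
  expect_true(all(lib$center >= des$grid_min & lib$center <= des$grid_max))
})

test_that("same seed reproduces the dataset and truth element-wise", {
  des <- simulation_design(small_bands(), n_control = 8, n_treated = 8,
                           grid_min = 450, grid_max = 520, grid_step = 2)
  a <- simulate_spectra(des, seed = 42)
  b <- simulate_spectra(des, seed = 42)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$truth$presence, b$truth$presence)
  c <- simulate_spectra(des, seed = 43)
  expect_false(identical(a$spectra, c$spectra))
})

test_that("designs without class effect plant no discriminative bands", {
  des <- simulation_design(small_bands(0.4, 0.4), n_control = 4,
                           n_treated = 4, grid_min = 450, grid_max = 520)
  sim <- simulate_spectra(des, seed = 1)
  expect_length(sim$truth$discriminative_band_indices, 0)
  des2 <- simulation_design(small_bands(c(0.2, 0.5, 0.5), c(0.9, 0.5, 0.5)),
                            n_control = 4, n_treated = 4,
                            grid_min = 450, grid_max = 520)
  expect_identical(simulate_spectra(des2, 1)$truth$discriminative_band_indices,
                   1L)
})

test_that("deterministic limit: always-on band peaks at its center", {
  bands <- band_definition(center = 480, fwhm = 10,
                           p_occur_control = 1, p_occur_treated = 1,
                           intensity_logsd = 0)
  des <- simulation_design(bands, n_control = 6, n_treated = 6,
                           grid_min = 450, grid_max = 520, grid_step = 2,
                           baseline_amplitude = 0, noise_sd = 0,
                           no_signal_fraction = 0)
  sim <- simulate_spectra(des, seed = 3)
  grid <- sim$spectra$wavenumber_cm1
  for (id in sim$metadata$spectrum_id) {
    expect_equal(grid[which.max(sim$spectra[[id]])], 480)
  }
})

test_that("empirical presence matches the class occurrence probability", {
  bands <- band_definition(center = 480, p_occur_control = 0.5,
                           p_occur_treated = 0.5)
  des <- simulation_design(bands, n_control = 1000, n_treated = 1000,
                           grid_min = 450, grid_max = 520, grid_step = 5,
                           no_signal_fraction = 0)
  sim <- simulate_spectra(des, seed = 7)
  frac <- mean(sim$truth$presence[, 1])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("group coupling spans independence to identity", {
  mk <- function(rho, seed) {
    bands <- small_bands(0.5, 0.5, n = 2, rho_group = c("g", "g"))
    des <- simulation_design(bands, n_control = 1200, n_treated = 1200,
                             grid_min = 450, grid_max = 520, grid_step = 5,
                             rho = rho, no_signal_fraction = 0)
    simulate_spectra(des, seed = seed)$truth$presence
  }
  pres1 <- mk(1, 11)
  expect_identical(pres1[, 1], pres1[, 2])   # rho = 1: identical indicators
  pres0 <- mk(0, 12)
  expect_gt(chisq.test(table(pres0[, 1], pres0[, 2]))$p.value, 0.01)
  pres9 <- mk(0.9, 13)
  expect_gt(cor(pres9[, 1], pres9[, 2]), 0.5)
})

test_that("zero-noise spectra are exact sums of analytic lineshapes", {
  bands <- small_bands(0.6, 0.6, n = 3, logsd = 0)  # unit amplitudes
  des <- simulation_design(bands, n_control = 10, n_treated = 10,
                           grid_min = 450, grid_max = 520, grid_step = 2,
                           baseline_amplitude = 0, noise_sd = 0,
                           no_signal_fraction = 0)
  sim <- simulate_spectra(des, seed = 5)
  grid <- sim$spectra$wavenumber_cm1
  for (i in seq_len(nrow(sim$metadata))) {
    expected <- numeric(length(grid))
    for (b in which(sim$truth$presence[i, ] == 1)) {
      expected <- expected + band_profile(grid, bands$center[b],
                                          bands$fwhm[b], bands$lineshape[b])
    }
    expect_equal(sim$spectra[[sim$metadata$spectrum_id[i]]], expected,
                 tolerance = 0)
  }
})

test_that("invalid designs are rejected with informative errors", {
  expect_error(simulation_design(small_bands(), grid_min = 500,
                                 grid_max = 470),
               "grid")
  expect_error(simulation_design(band_definition(center = 300),
                                 grid_min = 450, grid_max = 520),
               "300")
  expect_error(simulation_design(small_bands(), n_control = 0), "positive")
  expect_error(band_definition(center = 500, fwhm = -1), "fwhm")
  expect_error(band_definition(center = 500, p_occur_control = 1.2), "0, 1")
  expect_error(simulate_spectra(simulation_design(small_bands(),
                                                  grid_min = 450,
                                                  grid_max = 520)),
               "seed")
})

test_that("spectra datasets round-trip through the TSV dialect", {
  des <- simulation_design(small_bands(), n_control = 3, n_treated = 3,
                           grid_min = 450, grid_max = 520)
  sim <- simulate_spectra(des, seed = 9)
  dir <- withr::local_tempdir()
  write_spectra(sim$spectra, sim$metadata, dir)
  back <- read_spectra(dir)
  expect_equal(as.data.frame(back$spectra), as.data.frame(sim$spectra))
  expect_equal(as.data.frame(back$metadata), as.data.frame(sim$metadata))
})
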