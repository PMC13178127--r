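# closed-form spectra on a shared grid for peak/filter tests
lorentz_spectrum <- function(grid, centers, amps = 1, fwhm = 12) {
  y <- numeric(length(grid))
  amps <- rep_len(amps, length(centers))
  for (i in seq_along(centers)) {
    y <- y + amps[i] * band_profile(grid, centers[i], fwhm, "lorentzian")
  }
  y
}

test_that("vector normalization is exact, idempotent and scale-invariant", {
  expect_equal(vector_normalize(c(3, 4)), c(0.6, 0.8))
  u <- c(1, 0, 0)
  expect_equal(vector_normalize(u), u)
  expect_error(vector_normalize(c(0, 0, 0)), "zero spectrum")
  withr::local_seed(1)
  for (i in 1:20) {
    x <- rnorm(50)
    n1 <- vector_normalize(x)
    expect_equal(sqrt(sum(n1^2)), 1)
    expect_equal(vector_normalize(n1), n1)
    expect_equal(vector_normalize(runif(1, 0.1, 100) * x), n1)
  }
})

test_that("grid resampling interpolates linearly and respects the span", {
  sp <- tibble::tibble(wavenumber_cm1 = c(400, 402, 404), y = c(0, 2, 0))
  expect_equal(resample_to_grid(sp, c(400, 402, 404))$y, c(0, 2, 0))
  expect_equal(resample_to_grid(sp, 401)$y, 1.0)
  expect_error(resample_to_grid(sp, 399), "span")
})

test_that("noise estimator is robust, unbiased and shift-invariant", {
  expect_equal(estimate_noise(rep(5, 100)), 0)
  withr::local_seed(4)
  x <- rnorm(10000)
  est <- estimate_noise(x)
  expect_gt(est, 0.95)
  expect_lt(est, 1.05)
  expect_equal(estimate_noise(x + 17.3), est)
  expect_error(estimate_noise(rnorm(10)), "16")
})

test_that("peak detection finds analytic bands and nothing on flat input", {
  grid <- seq(450, 1600, by = 2)
  one <- lorentz_spectrum(grid, 1002)
  expect_equal(detect_peaks(grid, one), grid[which.min(abs(grid - 1002))])
  expect_length(detect_peaks(grid, rep(0, length(grid))), 0)
  # 1101 and 1447 fall between grid points; maxima land on a neighbour
  two <- lorentz_spectrum(grid, c(1101, 1447), amps = c(1, 0.7))
  pk <- detect_peaks(grid, two)
  expect_length(pk, 2)
  expect_lte(abs(pk[1] - 1101), 2)
  expect_lte(abs(pk[2] - 1447), 2)
  expect_error(detect_peaks(grid, one, smooth_window = 4), "odd")
})

test_that("no-signal filtering keeps exactly the band-bearing spectra", {
  grid <- seq(450, 700, by = 2)
  spectra <- tibble::tibble(
    wavenumber_cm1 = grid,
    s1 = lorentz_spectrum(grid, 500),
    s2 = rep(0, length(grid)),
    s3 = lorentz_spectrum(grid, c(520, 600)),
    s4 = rep(0, length(grid))
  )
  meta <- tibble::tibble(spectrum_id = paste0("s", 1:4),
                         group = c("control", "control", "treated", "treated"),
                         scheme = "A")
  out <- filter_no_signal(spectra, meta)
  expect_identical(names(out$spectra)[-1], c("s1", "s3"))
  expect_identical(out$metadata$spectrum_id, c("s1", "s3"))
  expect_identical(unname(out$retained), c(TRUE, FALSE, TRUE, FALSE))
  allzero <- spectra[c("wavenumber_cm1", "s2", "s4")]
  expect_warning(res <- filter_no_signal(allzero), "no spectra")
  expect_equal(ncol(res$spectra), 1)
})

test_that("filtered fraction matches the planted no-signal rate", {
  bands <- band_definition(center = c(480, 520), p_occur_control = 1,
                           p_occur_treated = 1, intensity_logsd = 0.2)
  des <- simulation_design(bands, n_control = 500, n_treated = 500,
                           grid_min = 450, grid_max = 560, grid_step = 2,
                           baseline_amplitude = 0, noise_sd = 0.01,
                           no_signal_fraction = 0.3)
  sim <- simulate_spectra(des, seed = 21)
  out <- filter_no_signal(sim$spectra, sim$metadata)
  frac <- mean(out$retained)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.3 * 0.7 / 1000))
  # retained spectra are exactly those with at least one planted band
  expect_identical(unname(out$retained),
                   unname(rowSums(sim$truth$presence) > 0))
})

test_that("band occurrence counts matching peaks per reference band", {
  grid <- seq(450, 700, by = 2)
  n <- 172
  with_band <- 86
  cols <- lapply(seq_len(n), function(i) {
    if (i <= with_band) lorentz_spectrum(grid, 520) else
      lorentz_spectrum(grid, 640)
  })
  names(cols) <- sprintf("s%03d", seq_len(n))
  spectra <- tibble::as_tibble(c(list(wavenumber_cm1 = grid), cols))
  occ <- band_occurrence(spectra, reference_bands = c(520, 475), tolerance = 4)
  expect_equal(occ$occurrence_fraction, c(0.5, 0))
  expect_equal(occ$n_spectra, c(172, 172))
  # invariant to per-spectrum intensity scaling
  scaled <- spectra
  for (j in 2:ncol(scaled)) scaled[[j]] <- scaled[[j]] * j
  expect_equal(band_occurrence(scaled, c(520, 475), tolerance = 4),
               occ)
  # two reference bands flanking one true peak both report it
  occ2 <- band_occurrence(spectra[1:(with_band + 1)],
                          reference_bands = c(518, 523), tolerance = 4)
  expect_equal(occ2$occurrence_fraction, c(1, 1))
  expect_error(band_occurrence(spectra[1], c(520)), "empty")
})

test_that("mean spectra average normalized intensities", {
  one <- tibble::tibble(wavenumber_cm1 = c(400, 402), a = c(3, 4))
  expect_equal(mean_spectrum(one)$intensity, c(0.6, 0.8))
  expect_equal(mean_spectrum(one, normalize_first = FALSE)$intensity, c(3, 4))
  two <- tibble::tibble(wavenumber_cm1 = c(400, 402), a = c(1, 0), b = c(0, 1))
  expect_equal(mean_spectrum(two)$intensity, c(0.5, 0.5))
  k <- tibble::tibble(wavenumber_cm1 = c(400, 402), a = c(3, 4), b = c(3, 4),
                      c = c(3, 4))
  expect_equal(mean_spectrum(k, normalize_first = FALSE)$intensity, c(3, 4))
})

test_that("binning aggregates adjacent grid points into labelled variables", {
  sp <- tibble::tibble(wavenumber_cm1 = c(400, 402, 404, 406),
                       s1 = c(1, 3, 5, 7), s2 = c(2, 2, 2, 2))
  meta <- tibble::tibble(spectrum_id = c("s1", "s2"),
                         group = c("control", "treated"), scheme = "A")
  ident <- bin_to_variables(sp, meta, bin_width = 2, normalize = FALSE)
  expect_identical(names(ident), c("spectrum_id", "group",
                                   "400", "402", "404", "406"))
  expect_equal(unlist(ident[1, -(1:2)], use.names = FALSE), c(1, 3, 5, 7))
  b4 <- bin_to_variables(sp, meta, bin_width = 4, normalize = FALSE)
  expect_identical(names(b4)[-(1:2)], c("401", "405"))
  expect_equal(unlist(b4[1, -(1:2)], use.names = FALSE), c(2, 6))
  # column count for exact divisions; per-spectrum mean preserved
  expect_equal(ncol(b4) - 2, 2)
  expect_equal(rowMeans(as.matrix(b4[-(1:2)])),
               rowMeans(t(as.matrix(sp[-1]))), ignore_attr = TRUE)
  expect_error(bin_to_variables(sp, meta, bin_width = 1), "grid step")
})
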