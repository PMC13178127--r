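#' Define a synthetic SERS simulation
#'
#' Bundles everything needed to generate a two-class SERS-like dataset:
#' the wavenumber grid, per-class sample sizes, a band table (see
#' [band_definition()] / [default_band_library()]), optional co-occurrence
#' groups, and the nuisance terms (polynomial baseline, Gaussian noise,
#' a fraction of no-signal spectra).
#'
#' Co-occurrence groups are declared through the `group_id` column of
#' `bands`: all bands sharing a non-`NA` `group_id` form one group whose
#' presence indicators are coupled with correlation `rho`.
#'
#' @param bands band table (one row per band).
#' @param n_control,n_treated number of spectra per class.
#' @param grid_min,grid_max,grid_step wavenumber grid in cm^-1.
#' @param rho within-group occurrence coupling in \[0, 1\]; a single value
#'   applied to every group.
#' @param baseline_amplitude scale of the random degree-3 polynomial
#'   baseline (0 disables it).
#' @param noise_sd standard deviation of i.i.d. Gaussian noise added to
#'   every grid point.
#' @param no_signal_fraction probability that a spectrum carries no bands at
#'   all (baseline + noise only), emulating empty SERS acquisitions.
#' @return A `simulation_design` object (a validated list).
#' @seealso [simulate_spectra()]
#' @export
simulation_design <- function(bands = default_band_library(),
                              n_control = 172, n_treated = 172,
                              grid_min = 450, grid_max = 1600, grid_step = 2,
                              rho = 0.7, baseline_amplitude = 0.3,
                              noise_sd = 0.05, no_signal_fraction = 0.2) {
  validate_bands(bands)
  if (!(grid_min < grid_max) || grid_step <= 0) {
    stop("invalid grid: need grid_min < grid_max and grid_step > 0",
         call. = FALSE)
  }
  if (n_control < 1 || n_treated < 1) {
    stop("sample counts must be positive", call. = FALSE)
  }
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  if (no_signal_fraction < 0 || no_signal_fraction > 1) {
    stop("no_signal_fraction must lie in [0, 1]", call. = FALSE)
  }
  bad <- bands$center < grid_min | bands$center > grid_max
  if (any(bad)) {
    stop("band center(s) outside the grid: ",
         paste(bands$center[bad], collapse = ", "), " cm^-1", call. = FALSE)
  }
  structure(
    list(bands = tibble::as_tibble(bands),
         n_control = as.integer(n_control),
         n_treated = as.integer(n_treated),
         grid_min = grid_min, grid_max = grid_max, grid_step = grid_step,
         rho = rho, baseline_amplitude = baseline_amplitude,
         noise_sd = noise_sd, no_signal_fraction = no_signal_fraction),
    class = "simulation_design"
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("<simulation_design>\n")
  cat(sprintf("  grid: %g-%g cm^-1, step %g (%d points)\n", x$grid_min,
              x$grid_max, x$grid_step, length(design_grid(x))))
  cat(sprintf("  spectra: %d control + %d treated\n", x$n_control, x$n_treated))
  cat(sprintf("  bands: %d (%d grouped), rho = %g\n", nrow(x$bands),
              sum(!is.na(x$bands$group_id)), x$rho))
  cat(sprintf("  baseline %g, noise sd %g, no-signal fraction %g\n",
              x$baseline_amplitude, x$noise_sd, x$no_signal_fraction))
  invisible(x)
}

design_grid <- function(design) {
  seq(design$grid_min, design$grid_max, by = design$grid_step)
}

#' Analytic band profile
#'
#' Peak-normalized Lorentzian or Gaussian profile on a wavenumber grid.
#'
#' @param grid wavenumber vector.
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1).
#' @param lineshape `"lorentzian"` or `"gaussian"`.
#' @return Numeric vector of unit peak height.
#' @export
band_profile <- function(grid, center, fwhm, lineshape = "lorentzian") {
  if (lineshape == "lorentzian") {
    hw2 <- (fwhm / 2)^2
    hw2 / ((grid - center)^2 + hw2)
  } else {
    exp(-4 * log(2) * (grid - center)^2 / fwhm^2)
  }
}

#' Simulate a two-class SERS dataset
#'
#' Draws spectra from a [simulation_design()]: stochastic band presence
#' (group-coupled where `group_id` is set), log-normal band amplitudes,
#' analytic lineshapes, a smooth random polynomial baseline and Gaussian
#' noise. A fraction of spectra are "no signal" (baseline + noise only).
#' The generative ground truth (per-spectrum band presence, discriminative
#' band indices, group membership) is returned alongside the data, so
#' recovery of planted structure can be scored exactly.
#'
#' Group coupling: for each group and spectrum a shared latent uniform `u`
#' is drawn; each member band uses the indicator `u < p_band` with
#' probability `rho` and an independent Bernoulli(`p_band`) draw otherwise.
#' Marginal occurrence probabilities are preserved exactly for any mix of
#' per-band probabilities; `rho = 1` makes equal-probability members
#' identical, `rho = 0` makes them independent.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed; the same seed reproduces the dataset
#'   element-for-element.
#' @param scheme incubation-scheme label ("A", "B" or "C") recorded in the
#'   metadata; purely descriptive.
#' @return A list of class `sers_simulation` with components
#' \describe{
#'   \item{spectra}{wide tibble: `wavenumber_cm1` plus one intensity column
#'     per spectrum.}
#'   \item{metadata}{tibble with `spectrum_id`, `group`
#'     (`control`/`treated`), `scheme`.}
#'   \item{truth}{list: `presence` (spectra x bands 0/1 matrix),
#'     `discriminative_band_indices`, `group_membership`, `no_signal`
#'     (logical), `bands` (the band table).}
#' }
#' @export
#' @examples
#' des <- simulation_design(n_control = 5, n_treated = 5, noise_sd = 0.02)
#' sim <- simulate_spectra(des, seed = 1)
#' sim$metadata
simulate_spectra <- function(design, seed, scheme = "A") {
  stopifnot(inherits(design, "simulation_design"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  grid <- design_grid(design)
  bands <- design$bands
  nb <- nrow(bands)
  n <- design$n_control + design$n_treated
  groups <- split(seq_len(nb), bands$group_id)

  # precompute unit-height profiles, one per band
  profiles <- vapply(seq_len(nb), function(b) {
    band_profile(grid, bands$center[b], bands$fwhm[b], bands$lineshape[b])
  }, numeric(length(grid)))

  cls <- rep(c("control", "treated"), c(design$n_control, design$n_treated))

  withr::local_seed(seed)
  no_signal <- stats::runif(n) < design$no_signal_fraction
  presence <- matrix(0L, n, nb)
  intens <- matrix(0, length(grid), n)
  t01 <- (grid - design$grid_min) / (design$grid_max - design$grid_min)

  for (i in seq_len(n)) {
    p <- if (cls[i] == "control") bands$p_occur_control else bands$p_occur_treated
    pres <- stats::runif(nb) < p                      # independent draws
    for (g in groups) {                               # overwrite grouped bands
      u <- stats::runif(1)
      use_shared <- stats::runif(length(g)) < design$rho
      pres[g] <- ifelse(use_shared, u < p[g], pres[g])
    }
    if (no_signal[i]) pres[] <- FALSE
    presence[i, ] <- as.integer(pres)
    y <- numeric(length(grid))
    for (b in which(pres)) {
      amp <- stats::rlnorm(1, bands$intensity_logmean[b],
                           bands$intensity_logsd[b])
      y <- y + amp * profiles[, b]
    }
    if (design$baseline_amplitude > 0) {
      coef <- stats::runif(4, -1, 1) * design$baseline_amplitude
      y <- y + coef[1] + coef[2] * t01 + coef[3] * t01^2 + coef[4] * t01^3
    }
    if (design$noise_sd > 0) {
      y <- y + stats::rnorm(length(grid), sd = design$noise_sd)
    }
    intens[, i] <- y
  }

  ids <- sprintf("s%04d", seq_len(n))
  spectra <- tibble::as_tibble(
    c(list(wavenumber_cm1 = grid),
      stats::setNames(lapply(seq_len(n), function(i) intens[, i]), ids))
  )
  metadata <- tibble::tibble(spectrum_id = ids, group = cls, scheme = scheme)
  rownames(presence) <- ids
  truth <- list(
    presence = presence,
    discriminative_band_indices =
      which(bands$p_occur_control != bands$p_occur_treated),
    group_membership = stats::setNames(bands$group_id, as.character(bands$center)),
    no_signal = no_signal,
    bands = bands
  )
  structure(list(spectra = spectra, metadata = metadata, truth = truth,
                 design = design, seed = seed),
            class = "sers_simulation")
}

#' @export
print.sers_simulation <- function(x, ...) {
  cat("<sers_simulation>\n")
  cat(sprintf("  %d spectra x %d grid points, seed %d\n",
              nrow(x$metadata), nrow(x$spectra), x$seed))
  cat(sprintf("  %d bands, %d discriminative, %d no-signal spectra\n",
              nrow(x$truth$bands),
              length(x$truth$discriminative_band_indices),
              sum(x$truth$no_signal)))
  invisible(x)
}

#' Write / read a spectra dataset as TSV
#'
#' The on-disk dialect is a spectral matrix TSV (first column
#' `wavenumber_cm1`, one column per spectrum) plus a metadata TSV
#' (`spectrum_id`, `group`, `scheme`).
#'
#' @param spectra wide spectra tibble.
#' @param metadata metadata tibble.
#' @param dir output directory (created if needed).
#' @return `write_spectra()` returns the paths invisibly; `read_spectra()`
#'   returns `list(spectra, metadata)`.
#' @export
write_spectra <- function(spectra, metadata, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ps <- file.path(dir, "spectra.tsv")
  pm <- file.path(dir, "metadata.tsv")
  readr::write_tsv(spectra, ps)
  readr::write_tsv(metadata, pm)
  invisible(c(spectra = ps, metadata = pm))
}

#' @rdname write_spectra
#' @export
read_spectra <- function(dir) {
  list(
    spectra = readr::read_tsv(file.path(dir, "spectra.tsv"),
                              show_col_types = FALSE),
    metadata = readr::read_tsv(file.path(dir, "metadata.tsv"),
                               show_col_types = FALSE)
  )
}
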