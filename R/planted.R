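#' Planted-structure benchmark design
#'
#' Builds a [simulation_design()] for recovery studies: `n_signal`
#' discriminative bands (occurrence `p_lo` in controls vs `p_hi` in treated
#' spectra) followed by `n_noise` irrelevant bands (occurrence `p_noise` in
#' both classes), laid out one band per 15 cm^-1 feature bin so that
#' [bin_to_variables()] with `bin_width = 15` yields exactly one feature per
#' band. Bands are Gaussian with 7 cm^-1 width and sit on the bin centers,
#' keeping leakage into neighbouring bins negligible — the planted ground
#' truth then maps one-to-one onto feature columns. Co-occurrence groups
#' can be planted over the leading bands via `group_ids`.
#'
#' @param n_signal,n_noise number of discriminative / irrelevant bands.
#' @param n_per_class spectra per class.
#' @param p_hi,p_lo treated/control occurrence of the discriminative bands.
#' @param p_noise occurrence of irrelevant bands (both classes).
#' @param group_ids optional character vector assigning the leading bands
#'   to co-occurrence groups (e.g. `rep(c("g1", "g2"), each = 4)`).
#' @param rho within-group occurrence coupling.
#' @param noise_sd,baseline_amplitude,no_signal_fraction nuisance terms,
#'   see [simulation_design()]; defaults give clean recovery conditions.
#' @return A `simulation_design`.
#' @export
#' @examples
#' des <- planted_design(n_signal = 3, n_noise = 10, n_per_class = 50)
#' sim <- simulate_spectra(des, seed = 1)
#' sim$truth$discriminative_band_indices
planted_design <- function(n_signal = 5, n_noise = 75, n_per_class = 300,
                           p_hi = 0.9, p_lo = 0.1, p_noise = 0.5,
                           group_ids = NULL, rho = 0, noise_sd = 0.02,
                           baseline_amplitude = 0, no_signal_fraction = 0) {
  nb <- n_signal + n_noise
  grid_min <- 400
  step <- 3
  k <- 5                                   # grid points per 15 cm^-1 bin
  grid_max <- grid_min + step * (k * nb)   # exact division into nb bins
  centers <- grid_min + step * (k * (seq_len(nb) - 1) + (k - 1) / 2)
  signal <- seq_len(n_signal)
  gid <- rep(NA_character_, nb)
  if (!is.null(group_ids)) gid[seq_along(group_ids)] <- group_ids
  bands <- band_definition(
    center = centers, fwhm = 7, lineshape = "gaussian",
    p_occur_control = ifelse(seq_len(nb) %in% signal, p_lo, p_noise),
    p_occur_treated = ifelse(seq_len(nb) %in% signal, p_hi, p_noise),
    intensity_logmean = 0, intensity_logsd = 0.6, group_id = gid
  )
  simulation_design(bands, n_control = n_per_class, n_treated = n_per_class,
                    grid_min = grid_min, grid_max = grid_max,
                    grid_step = step, rho = rho,
                    baseline_amplitude = baseline_amplitude,
                    noise_sd = noise_sd,
                    no_signal_fraction = no_signal_fraction)
}

#' Simulate a planted design and bin it into one feature per band
#'
#' Convenience wrapper used by recovery studies: simulates a
#' [planted_design()] and bins the spectra at the design's band spacing,
#' without vector normalization — the shared per-spectrum norm would couple
#' every feature to the class (treated spectra carry more bands, hence
#' larger norms) and make nominally irrelevant bands weakly informative.
#'
#' @param design a [planted_design()].
#' @param seed integer seed.
#' @param bin_width feature bin width in cm^-1 (the design's band spacing).
#' @return Feature tibble from [bin_to_variables()]; column `j + 2`
#'   corresponds to band `j` of the design.
#' @export
planted_features <- function(design, seed, bin_width = 15) {
  sim <- simulate_spectra(design, seed = seed)
  bin_to_variables(sim$spectra, sim$metadata, bin_width = bin_width,
                   normalize = FALSE)
}
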