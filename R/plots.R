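#' Plot class-wise mean spectra
#'
#' @param spectra wide spectra tibble.
#' @param metadata metadata tibble with `spectrum_id` and `group`.
#' @param normalize_first vector-normalize before averaging.
#' @return A ggplot of the mean spectrum per group.
#' @export
plot_mean_spectra <- function(spectra, metadata, normalize_first = TRUE) {
  per_group <- lapply(split(metadata$spectrum_id, metadata$group), function(ids) {
    mean_spectrum(spectra[c(names(spectra)[1], ids)],
                  normalize_first = normalize_first)
  })
  d <- dplyr::bind_rows(per_group, .id = "group")
  ggplot2::ggplot(d, ggplot2::aes(.data$wavenumber_cm1, .data$intensity,
                                  colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "mean intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a band-occurrence profile
#'
#' @param profile tibble from [band_occurrence()].
#' @return A ggplot of occurrence fraction per band center.
#' @export
plot_occurrence <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$band_center_cm1,
                                        .data$occurrence_fraction)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$band_center_cm1,
                                       yend = 0), linewidth = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "band center (cm⁻¹)", y = "relative occurrence") +
    ggplot2::theme_minimal()
}
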