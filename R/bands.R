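#' Reference library of endolysosomal SERS bands
#'
#' Returns a tibble of vibrational bands commonly observed in SERS spectra of
#' endolysosomes probed with gold nanoparticles, covering the fingerprint
#' region (475--1543 cm^-1). Each band carries a free-text assignment and a
#' `protein` / `lipid` tag used to annotate co-occurrence maps. Occurrence
#' probabilities and intensity parameters are simulation defaults and can be
#' overridden column-wise before building a [simulation_design()].
#'
#' @param p_occur default per-class occurrence probability applied to every
#'   band (both classes); length 1.
#' @param fwhm default full width at half maximum in cm^-1.
#' @param intensity_logmean,intensity_logsd log-normal amplitude parameters
#'   (log scale), shared by all bands.
#'
#' @return A tibble with one row per band and columns `center`, `fwhm`,
#'   `lineshape`, `p_occur_control`, `p_occur_treated`, `intensity_logmean`,
#'   `intensity_logsd`, `group_id`, `assignment`, `class`.
#' @export
#' @examples
#' lib <- default_band_library()
#' dplyr::filter(lib, grepl("phenylalanine", assignment))
default_band_library <- function(p_occur = 0.5, fwhm = 12,
                                 intensity_logmean = 0,
                                 intensity_logsd = 0.6) {
  b <- function(center, assignment, class) {
    tibble::tibble(center = center, assignment = assignment, class = class)
  }
  bands <- dplyr::bind_rows(
    b(475,  "S-S disulfide stretching",                 "protein"),
    b(496,  "S-S disulfide stretching",                 "protein"),
    b(497,  "S-S disulfide stretching",                 "protein"),
    b(545,  "S-S disulfide stretching",                 "protein"),
    b(547,  "tryptophan",                               "protein"),
    b(564,  "tryptophan",                               "protein"),
    b(679,  "disulfide C-S/S-S",                        "protein"),
    b(698,  "C-S stretching",                           "protein"),
    b(732,  "tryptophan ring vibration",                "protein"),
    b(776,  "phosphatidylinositol",                     "lipid"),
    b(787,  "phosphatidylinositol",                     "lipid"),
    b(798,  "phosphate O-P-O stretching",               "lipid"),
    b(826,  "phospholipid PO2 stretching",              "lipid"),
    b(842,  "tyrosine ring breathing",                  "protein"),
    b(977,  "proline/valine",                           "protein"),
    b(1002, "phenylalanine ring breathing",             "protein"),
    b(1012, "phenylalanine",                            "protein"),
    b(1028, "phenylalanine",                            "protein"),
    b(1041, "tyrosine",                                 "protein"),
    b(1054, "lipid intrachain C-C stretching",          "lipid"),
    b(1056, "lipid asymmetric C-C stretching",          "lipid"),
    b(1077, "lipid intrachain C-C stretching",          "lipid"),
    b(1101, "lipid C-C stretching",                     "lipid"),
    b(1104, "lipid intrachain C-C stretching",          "lipid"),
    b(1125, "lipid symmetric C-C stretching",           "lipid"),
    b(1132, "protein backbone C-C/C-N",                 "protein"),
    b(1135, "protein C-C/C-N stretching",               "protein"),
    b(1165, "protein backbone",                         "protein"),
    b(1191, "amino acid side chain",                    "protein"),
    b(1196, "aromatic amino acids",                     "protein"),
    b(1218, "amide III",                                "protein"),
    b(1231, "amide III",                                "protein"),
    b(1240, "amide III",                                "protein"),
    b(1245, "amide III",                                "protein"),
    b(1271, "amide III",                                "protein"),
    b(1277, "amide III",                                "protein"),
    b(1288, "amide III",                                "protein"),
    b(1303, "lipid CH2 twisting",                       "lipid"),
    b(1317, "lipid CH2/CH3 deformation",                "lipid"),
    b(1342, "tryptophan",                               "protein"),
    b(1347, "tryptophan",                               "protein"),
    b(1365, "tryptophan",                               "protein"),
    b(1372, "lipid tail CH deformation",                "lipid"),
    b(1413, "tryptophan",                               "protein"),
    b(1424, "lipid methylene deformation",              "lipid"),
    b(1433, "lipid methylene deformation",              "lipid"),
    b(1447, "lipid chain packing CH2 deformation",      "lipid"),
    b(1481, "lipid methylene deformation",              "lipid"),
    b(1487, "amide II",                                 "protein"),
    b(1523, "amide II",                                 "protein"),
    b(1543, "amide II",                                 "protein")
  )
  tibble::tibble(
    center = bands$center,
    fwhm = fwhm,
    lineshape = "lorentzian",
    p_occur_control = p_occur,
    p_occur_treated = p_occur,
    intensity_logmean = intensity_logmean,
    intensity_logsd = intensity_logsd,
    group_id = NA_character_,
    assignment = bands$assignment,
    class = bands$class
  )
}

#' Construct a band definition table
#'
#' Thin validated constructor for the band table consumed by
#' [simulation_design()]. All arguments are recycled to the length of
#' `center`.
#'
#' @param center band centers in cm^-1.
#' @param fwhm full widths at half maximum in cm^-1 (> 0).
#' @param lineshape `"lorentzian"` or `"gaussian"`.
#' @param p_occur_control,p_occur_treated per-class occurrence probabilities
#'   in \[0, 1\].
#' @param intensity_logmean,intensity_logsd log-normal amplitude parameters.
#' @param group_id co-occurrence group label or `NA` for ungrouped bands.
#' @param assignment free-text assignment.
#' @param class `"protein"`, `"lipid"` or `"unassigned"`.
#' @return A tibble with one row per band.
#' @export
band_definition <- function(center, fwhm = 12, lineshape = "lorentzian",
                            p_occur_control = 0.5, p_occur_treated = 0.5,
                            intensity_logmean = 0, intensity_logsd = 0.6,
                            group_id = NA_character_,
                            assignment = "", class = "unassigned") {
  out <- tibble::tibble(
    center = as.numeric(center), fwhm = fwhm, lineshape = lineshape,
    p_occur_control = p_occur_control, p_occur_treated = p_occur_treated,
    intensity_logmean = intensity_logmean, intensity_logsd = intensity_logsd,
    group_id = as.character(group_id), assignment = assignment, class = class
  )
  validate_bands(out)
  out
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), nrow(bands) >= 1)
  if (any(bands$fwhm <= 0)) stop("band fwhm must be positive", call. = FALSE)
  if (!all(bands$lineshape %in% c("lorentzian", "gaussian"))) {
    stop("lineshape must be 'lorentzian' or 'gaussian'", call. = FALSE)
  }
  probs <- c(bands$p_occur_control, bands$p_occur_treated)
  if (any(probs < 0 | probs > 1)) {
    stop("occurrence probabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(bands)
}
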