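#' Vector (Euclidean) normalization
#'
#' Scales an intensity vector to unit Euclidean norm, the standard
#' normalization applied to SERS spectra before averaging or multivariate
#' analysis. Idempotent and invariant to positive rescaling.
#'
#' @param intensities numeric vector with at least one nonzero element.
#' @return The vector divided by its Euclidean norm.
#' @export
#' @examples
#' vector_normalize(c(3, 4))  # 0.6 0.8
vector_normalize <- function(intensities) {
  nrm <- sqrt(sum(intensities^2))
  if (!is.finite(nrm) || nrm == 0) stop("zero spectrum", call. = FALSE)
  intensities / nrm
}

#' Linear resampling onto a wavenumber grid
#'
#' @param spectrum tibble/data frame with columns `wavenumber_cm1` and one
#'   intensity column, or a two-column numeric data frame.
#' @param grid target wavenumber vector; must lie within the spectrum's span.
#' @return Tibble with `wavenumber_cm1` and the interpolated intensities.
#' @export
resample_to_grid <- function(spectrum, grid) {
  wn <- spectrum[[1]]
  if (min(grid) < min(wn) || max(grid) > max(wn)) {
    stop("grid extends outside the spectrum's wavenumber span", call. = FALSE)
  }
  out <- lapply(spectrum[-1], function(y) {
    stats::approx(wn, y, xout = grid, method = "linear")$y
  })
  tibble::as_tibble(c(list(wavenumber_cm1 = grid), out))
}

#' Robust noise estimate for a spectrum
#'
#' Estimates the standard deviation of additive white noise from the median
#' absolute deviation of the first difference of the intensities:
#' `MAD(diff(x)) / (sqrt(2) * 0.6745)`. Insensitive to bands and smooth
#' baselines, and invariant to adding a constant.
#'
#' @param intensities numeric vector, length >= 16.
#' @return Estimated noise standard deviation (intensity units).
#' @export
estimate_noise <- function(intensities) {
  if (length(intensities) < 16) {
    stop("need at least 16 grid points to estimate noise", call. = FALSE)
  }
  d <- diff(intensities)
  stats::median(abs(d - stats::median(d))) / (sqrt(2) * 0.6745)
}

# prominence of local maxima: height minus the higher of the two minima
# separating the peak from the nearest higher point (or the signal edge)
peak_prominences <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h
    i <- p
    while (i > 1) {
      i <- i - 1
      if (x[i] > h) break
      if (x[i] < lmin) lmin <- x[i]
    }
    rmin <- h
    i <- p
    while (i < n) {
      i <- i + 1
      if (x[i] > h) break
      if (x[i] < rmin) rmin <- x[i]
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect peaks in a spectrum
#'
#' Savitzky-Golay smoothing (polynomial order 2) followed by local-maximum
#' detection; a maximum is reported as a peak when its topographic
#' prominence is at least `min_prominence_snr` times the robust noise
#' estimate of the raw spectrum (see [estimate_noise()]).
#'
#' @param wavenumbers ascending wavenumber vector.
#' @param intensities matching intensity vector.
#' @param min_prominence_snr prominence threshold in units of noise sd.
#' @param smooth_window odd Savitzky-Golay window length (>= 3 points).
#' @return Ascending vector of peak wavenumbers (grid positions of maxima).
#' @export
detect_peaks <- function(wavenumbers, intensities, min_prominence_snr = 5,
                         smooth_window = 9) {
  if (smooth_window < 3 || smooth_window %% 2 == 0) {
    stop("smooth_window must be odd and >= 3", call. = FALSE)
  }
  sm <- signal::sgolayfilt(intensities, p = 2, n = smooth_window)
  n <- length(sm)
  if (n < 3) return(numeric(0))
  cand <- which(sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] > sm[3:n]) + 1L
  if (length(cand) == 0) return(numeric(0))
  prom <- peak_prominences(sm, cand)
  noise <- estimate_noise(intensities)
  # absolute floor guards against float ripple on noise-free spectra
  floor_abs <- 1e-10 * diff(range(sm))
  keep <- prom >= pmax(min_prominence_snr * noise, floor_abs) & prom > 0
  sort(wavenumbers[cand[keep]])
}

peaks_per_spectrum <- function(spectra, min_prominence_snr, smooth_window) {
  wn <- spectra[[1]]
  lapply(spectra[-1], function(y) {
    detect_peaks(wn, y, min_prominence_snr = min_prominence_snr,
                 smooth_window = smooth_window)
  })
}

#' Remove spectra with no signal
#'
#' Drops spectra with fewer than `min_peaks` detected peaks at
#' `min_prominence_snr` times the noise level — the elimination step applied
#' to raw SERS datasets before averaging and classification. Order is
#' preserved; metadata (if supplied) is subset in step.
#'
#' @param spectra wide spectra tibble (`wavenumber_cm1` + spectrum columns).
#' @param metadata optional metadata tibble with `spectrum_id` matching the
#'   spectrum column names.
#' @param min_prominence_snr,smooth_window peak-detection parameters, see
#'   [detect_peaks()].
#' @param min_peaks minimum number of peaks a spectrum must show.
#' @return List with `spectra`, `metadata` (or `NULL`), and `retained`, a
#'   named logical over the input spectra.
#' @export
filter_no_signal <- function(spectra, metadata = NULL,
                             min_prominence_snr = 5, min_peaks = 1,
                             smooth_window = 9) {
  stopifnot(min_prominence_snr > 0, min_peaks > 0)
  pk <- peaks_per_spectrum(spectra, min_prominence_snr, smooth_window)
  keep <- vapply(pk, function(p) length(p) >= min_peaks, logical(1))
  if (!any(keep)) warning("no spectra retained", call. = FALSE)
  out_spec <- spectra[c(TRUE, keep)]
  out_meta <- NULL
  if (!is.null(metadata)) {
    out_meta <- metadata[metadata$spectrum_id %in% names(pk)[keep], ,
                         drop = FALSE]
  }
  list(spectra = out_spec, metadata = out_meta, retained = keep)
}

#' Relative band occurrence
#'
#' For each reference band, the fraction of spectra with at least one
#' detected peak within `tolerance` of the band center — the per-dataset
#' band-occurrence profile shown alongside average SERS spectra.
#'
#' @inheritParams filter_no_signal
#' @param reference_bands wavenumber vector of band centers.
#' @param tolerance matching half-window in cm^-1.
#' @return Tibble with `band_center_cm1`, `occurrence_fraction`, `n_spectra`.
#' @export
band_occurrence <- function(spectra, reference_bands, tolerance = 4,
                            min_prominence_snr = 5, smooth_window = 9) {
  stopifnot(tolerance > 0)
  if (ncol(spectra) < 2) stop("empty dataset", call. = FALSE)
  pk <- peaks_per_spectrum(spectra, min_prominence_snr, smooth_window)
  n <- length(pk)
  frac <- vapply(reference_bands, function(b) {
    sum(vapply(pk, function(p) any(abs(p - b) <= tolerance), logical(1))) / n
  }, numeric(1))
  tibble::tibble(band_center_cm1 = reference_bands,
                 occurrence_fraction = frac, n_spectra = n)
}

#' Mean spectrum of a dataset
#'
#' @inheritParams filter_no_signal
#' @param normalize_first vector-normalize each spectrum before averaging
#'   (the convention used for average SERS spectra).
#' @return Tibble with `wavenumber_cm1` and `intensity`.
#' @export
mean_spectrum <- function(spectra, normalize_first = TRUE) {
  if (ncol(spectra) < 2) stop("empty dataset", call. = FALSE)
  m <- as.matrix(spectra[-1])
  if (normalize_first) m <- apply(m, 2, vector_normalize)
  tibble::tibble(wavenumber_cm1 = spectra[[1]], intensity = rowMeans(m))
}

#' Bin spectra into wavenumber variables
#'
#' Averages adjacent grid points into contiguous bins of `bin_width`,
#' producing the samples-by-variables feature table used by the surrogate
#' forest and PCA. Variable names are the bin-center wavenumbers. A trailing
#' partial bin is dropped.
#'
#' @inheritParams filter_no_signal
#' @param bin_width bin width in cm^-1; must be at least the grid step.
#' @param normalize vector-normalize each spectrum before binning.
#' @return Tibble with `spectrum_id`, `group` (if metadata given), and one
#'   numeric column per bin, named by bin-center wavenumber.
#' @export
bin_to_variables <- function(spectra, metadata = NULL, bin_width = 2,
                             normalize = TRUE) {
  wn <- spectra[[1]]
  step <- stats::median(diff(wn))
  if (bin_width < step - 1e-9) {
    stop("bin_width must be at least the grid step (", step, ")",
         call. = FALSE)
  }
  k <- max(1L, as.integer(round(bin_width / step)))
  nb <- length(wn) %/% k
  idx <- rep(seq_len(nb), each = k)
  m <- as.matrix(spectra[-1])
  if (normalize) m <- apply(m, 2, vector_normalize)
  m <- m[seq_len(nb * k), , drop = FALSE]
  wn_used <- wn[seq_len(nb * k)]
  centers <- as.vector(tapply(wn_used, idx, mean))
  binned <- apply(m, 2, function(y) as.vector(tapply(y, idx, mean)))
  binned <- matrix(binned, nrow = nb)
  out <- tibble::as_tibble(stats::setNames(
    lapply(seq_len(nb), function(j) binned[j, ]),
    format_wn(centers)
  ))
  ids <- names(spectra)[-1]
  front <- tibble::tibble(spectrum_id = ids)
  if (!is.null(metadata)) {
    front$group <- metadata$group[match(ids, metadata$spectrum_id)]
  }
  dplyr::bind_cols(front, out)
}

format_wn <- function(x) {
  sprintf("%.10g", x)
}

# split a feature tibble into X / y / labels, tolerating absent id/group cols
features_parts <- function(data, label_col = "group") {
  nm <- names(data)
  meta_cols <- intersect(c("spectrum_id", label_col), nm)
  vars <- setdiff(nm, meta_cols)
  X <- as.matrix(data[vars])
  storage.mode(X) <- "double"
  y <- if (label_col %in% nm) data[[label_col]] else NULL
  list(X = X, y = y, variables = vars,
       ids = if ("spectrum_id" %in% nm) data$spectrum_id else NULL)
}
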