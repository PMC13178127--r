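#' PCA eigenspectra of a feature table
#'
#' Column-mean-centered principal component analysis (via SVD, no scaling)
#' of the binned spectral feature table. Loadings are returned as
#' eigenspectra — component-shaped patterns over wavenumber variables —
#' under a deterministic sign convention: the loading element of largest
#' magnitude is made positive.
#'
#' @param data feature tibble (optional `spectrum_id` / `group` columns plus
#'   numeric variables), e.g. from [bin_to_variables()].
#' @param n_components number of components; at most
#'   `min(n_spectra - 1, n_variables)`.
#' @param label_col class-label column carried through to the scores.
#' @return Object of class `pca_result`: `loadings` (components x
#'   variables), `scores` (spectra x components), `explained_variance`
#'   (fractions, all components), `variables`, `labels`.
#' @export
pca_eigenspectra <- function(data, n_components = 3, label_col = "group") {
  parts <- features_parts(data, label_col)
  n <- nrow(parts$X)
  p <- ncol(parts$X)
  if (n_components > min(n - 1, p)) {
    stop("n_components must be <= min(n_spectra - 1, n_variables)",
         call. = FALSE)
  }
  pc <- stats::prcomp(parts$X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  load <- t(pc$rotation[, seq_len(n_components), drop = FALSE])
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    j <- which.max(abs(load[k, ]))
    if (load[k, j] < 0) {
      load[k, ] <- -load[k, ]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(load) <- paste0("PC", seq_len(n_components))
  colnames(load) <- parts$variables
  colnames(scores) <- rownames(load)
  structure(list(loadings = load, scores = scores,
                 explained_variance = ev, variables = parts$variables,
                 labels = parts$y, ids = parts$ids),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- nrow(x$loadings)
  cat("<pca_result>\n")
  cat(sprintf("  %d components over %d variables\n", k, ncol(x$loadings)))
  cat(sprintf("  explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$explained_variance[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy PCA eigenspectra or scores
#'
#' @param x a `pca_result`.
#' @param matrix `"loadings"` (long eigenspectra) or `"scores"`.
#' @param ... unused.
#' @export
tidy.pca_result <- function(x, matrix = "loadings", ...) {
  if (matrix == "scores") {
    out <- tibble::as_tibble(x$scores)
    if (!is.null(x$ids)) out <- dplyr::bind_cols(
      tibble::tibble(spectrum_id = x$ids), out)
    if (!is.null(x$labels)) out$group <- x$labels
    return(out)
  }
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(component = rownames(x$loadings)),
                     tibble::as_tibble(x$loadings)),
    -"component", names_to = "variable", values_to = "loading")
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(n_components = nrow(x$loadings),
                 pc1_explained = x$explained_variance[1],
                 total_explained =
                   sum(x$explained_variance[seq_len(nrow(x$loadings))]))
}

#' Plot PCA eigenspectra
#'
#' @param object a `pca_result`.
#' @param ... unused.
#' @return A ggplot of each component's loading over wavenumber.
#' @export
autoplot.pca_result <- function(object, ...) {
  d <- tidy(object)
  d$wavenumber <- suppressWarnings(as.numeric(d$variable))
  if (anyNA(d$wavenumber)) d$wavenumber <- as.numeric(factor(d$variable))
  ggplot2::ggplot(d, ggplot2::aes(.data$wavenumber, .data$loading)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component)) +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "loading (eigenspectrum)") +
    ggplot2::theme_minimal()
}
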