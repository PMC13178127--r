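#' Build a spectrally resolved co-occurrence map
#'
#' Assembles the relation map: rows are the SMD-selected (important)
#' wavenumber variables sorted by descending wavenumber, columns are all
#' variables, and cell values are MAA(row, column). A relation threshold
#' marks which variables count as related to each important band; by
#' default it is `mean + 2 sd` of the null MAA pool between real and shadow
#' variables recorded during [smd_select()]'s threshold run. Columns are
#' annotated `protein` / `lipid` / `unassigned` by matching their
#' wavenumber to a band table.
#'
#' @param smd an `smd_result` from [smd_select()].
#' @param maa a `maa_matrix` from [mean_adjusted_agreement()] on the same
#'   forest; computed from `smd$forest` when omitted.
#' @param annotations band table with `center` and `class` columns used to
#'   annotate columns (default [default_band_library()]).
#' @param relation_threshold numeric threshold on MAA; `NULL` uses the
#'   shadow-null default.
#' @param annotation_tolerance maximal |variable - band center| in cm^-1
#'   for an annotation to apply.
#' @return An object of class `relation_map`: list with `values` (rows x
#'   columns MAA matrix), `mask` (`values > threshold`), `threshold`,
#'   `row_variables`, `col_variables`, `annotation`.
#' @export
build_relation_map <- function(smd, maa = NULL,
                               annotations = default_band_library(),
                               relation_threshold = NULL,
                               annotation_tolerance = 4) {
  stopifnot(inherits(smd, "smd_result"))
  if (is.null(maa)) maa <- mean_adjusted_agreement(smd$forest)
  stopifnot(inherits(maa, "maa_matrix"))
  if (!identical(maa$variables, names(smd$smd))) {
    stop("smd and maa refer to different variable sets", call. = FALSE)
  }
  if (is.null(relation_threshold)) {
    relation_threshold <- smd$shadow$maa_null_mean +
      2 * smd$shadow$maa_null_sd
    if (!is.finite(relation_threshold)) relation_threshold <- 0
  }
  sel <- names(smd$smd)[smd$selected]
  if (length(sel) == 0) {
    warning("no variables selected; relation map is empty", call. = FALSE)
  }
  wn_rows <- suppressWarnings(as.numeric(sel))
  ord <- if (anyNA(wn_rows)) order(sel, decreasing = TRUE) else
    order(wn_rows, decreasing = TRUE)
  sel <- sel[ord]
  values <- maa$maa[sel, , drop = FALSE]
  cols <- maa$variables
  wn_cols <- suppressWarnings(as.numeric(cols))
  ann <- rep("unassigned", length(cols))
  if (!anyNA(wn_cols) && nrow(annotations) > 0) {
    nearest <- vapply(wn_cols, function(w) {
      d <- abs(annotations$center - w)
      i <- which.min(d)
      if (d[i] <= annotation_tolerance) annotations$class[i] else "unassigned"
    }, character(1))
    ann <- nearest
  }
  structure(
    list(values = values, mask = values > relation_threshold,
         threshold = relation_threshold, row_variables = sel,
         col_variables = cols,
         annotation = stats::setNames(ann, cols)),
    class = "relation_map"
  )
}

#' @export
print.relation_map <- function(x, ...) {
  cat("<relation_map>\n")
  cat(sprintf("  %d important bands x %d variables, relation threshold %.4f\n",
              nrow(x$values), ncol(x$values), x$threshold))
  cat(sprintf("  related cells: %d\n", sum(x$mask)))
  invisible(x)
}

#' Tidy a relation map into long form
#'
#' @param x a `relation_map`.
#' @param ... unused.
#' @return Tibble with `band` (row, important variable), `variable`
#'   (column), `maa`, `related`, `annotation`.
#' @export
tidy.relation_map <- function(x, ...) {
  if (nrow(x$values) == 0) {
    return(tibble::tibble(band = character(), variable = character(),
                          maa = numeric(), related = logical(),
                          annotation = character()))
  }
  out <- tidyr::expand_grid(band = x$row_variables,
                            variable = x$col_variables)
  out$maa <- as.vector(t(x$values))
  out$related <- as.vector(t(x$mask))
  out$annotation <- unname(x$annotation[out$variable])
  out
}

#' Heatmap of a relation map
#'
#' @param object a `relation_map`.
#' @param ... unused.
#' @return A ggplot tile heatmap: important bands (rows, descending
#'   wavenumber) against all spectral variables, filled by MAA, with a
#'   protein/lipid annotation strip along the horizontal axis.
#' @export
autoplot.relation_map <- function(object, ...) {
  d <- tidy(object)
  if (nrow(d) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("empty relation map"))
  }
  d$band_wn <- as.numeric(d$band)
  d$var_wn <- as.numeric(d$variable)
  ann <- tibble::tibble(var_wn = as.numeric(object$col_variables),
                        annotation = unname(object$annotation))
  y0 <- min(d$band_wn) - 0.06 * diff(range(d$band_wn)) - 1
  ggplot2::ggplot(d, ggplot2::aes(.data$var_wn, .data$band_wn)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$maa)) +
    ggplot2::geom_rug(data = ann[ann$annotation != "unassigned", ],
                      ggplot2::aes(x = .data$var_wn,
                                   colour = .data$annotation),
                      inherit.aes = FALSE, sides = "b", length  = ggplot2::unit(0.03, "npc")) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_colour_manual(values = c(protein = "#E69F00",
                                            lipid = "#009E73")) +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "important band (cm⁻¹)",
                  fill = "MAA", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Export a relation map to disk
#'
#' Writes the MAA value matrix and the boolean relation mask as TSV, a JSON
#' summary (selected bands, threshold, annotations), and optionally a
#' rendered heatmap. TSV round-trips reproduce the values exactly.
#'
#' @param map a `relation_map`.
#' @param dir output directory.
#' @param heatmap also write `relation_map.png` (requires a functional
#'   graphics device).
#' @return Named character vector of written paths, invisibly.
#' @export
export_relation_map <- function(map, dir, heatmap = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pv <- file.path(dir, "relation_map_values.tsv")
  pm <- file.path(dir, "relation_map_mask.tsv")
  pj <- file.path(dir, "relation_map.json")
  mat_to_tsv(map$values, pv)
  mat_to_tsv(map$mask * 1L, pm)
  jsonlite::write_json(
    list(important_bands = map$row_variables,
         relation_threshold = map$threshold,
         annotation = as.list(map$annotation)),
    pj, auto_unbox = TRUE, digits = NA)
  paths <- c(values = pv, mask = pm, summary = pj)
  if (heatmap) {
    ph <- file.path(dir, "relation_map.png")
    ggplot2::ggsave(ph, autoplot(map), width = 9, height = 4, dpi = 150)
    paths <- c(paths, heatmap = ph)
  }
  invisible(paths)
}

#' @rdname export_relation_map
#' @export
read_relation_map_values <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[-1])
  rownames(m) <- d[[1]]
  m
}

mat_to_tsv <- function(m, path) {
  d <- tibble::as_tibble(m, .name_repair = "minimal")
  if (nrow(d) > 0 || !is.null(rownames(m))) {
    d <- dplyr::bind_cols(tibble::tibble(band = rownames(m) %||% character(0)), d)
  } else {
    d <- dplyr::bind_cols(tibble::tibble(band = character(0)), d)
  }
  readr::write_tsv(d, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
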