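#' Run the full spectral analysis pipeline
#'
#' Orchestrates simulate (or load) -> filter -> bin -> surrogate forest ->
#' SMD selection -> MAA -> relation map -> PCA as one seeded run, writing
#' every intermediate artifact to `out_dir` together with a manifest
#' recording parameters, the seed and an MD5 checksum of every file.
#' Rerunning with the same config and seed reproduces every checksum.
#'
#' @param config a named list (or path to a YAML/JSON file) with elements
#' \describe{
#'   \item{design}{a [simulation_design()] or a list of its arguments;
#'     mutually exclusive with `input_dir`.}
#'   \item{input_dir}{directory holding `spectra.tsv` / `metadata.tsv` (see
#'     [read_spectra()]).}
#'   \item{preprocessing}{optional list: `min_prominence_snr` (5),
#'     `min_peaks` (1), `smooth_window` (9), `bin_width` (2), `normalize`
#'     (TRUE), `tolerance` (4).}
#'   \item{forest}{optional list: `num_trees` (500), `mtry`, `s`,
#'     `min_node_size` (5), `bootstrap` (TRUE), `n_shadow_repeats` (1).}
#'   \item{seed}{integer, required.}
#' }
#' @param out_dir output directory.
#' @param seed overrides `config$seed` when given.
#' @return The manifest as a list (also written to `manifest.json`):
#'   parameters, seed, per-stage outputs, file checksums, and headline
#'   results (number selected, relation threshold, PC1 explained fraction).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("config error: seed is required", call. = FALSE)
  seed <- as.integer(seed)
  if (is.null(config$design) && is.null(config$input_dir)) {
    stop("config error: need either a simulation design or input_dir",
         call. = FALSE)
  }
  pp <- utils::modifyList(
    list(min_prominence_snr = 5, min_peaks = 1, smooth_window = 9,
         bin_width = 2, normalize = TRUE, tolerance = 4),
    config$preprocessing %||% list())
  fp <- utils::modifyList(
    list(num_trees = 500, mtry = NULL, s = NULL, min_node_size = 5,
         bootstrap = TRUE, n_shadow_repeats = 1),
    config$forest %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  # stage 1: obtain spectra
  truth <- NULL
  if (!is.null(config$design)) {
    design <- config$design
    if (!inherits(design, "simulation_design")) {
      design <- do.call(simulation_design, coerce_design_args(design))
    }
    sim <- simulate_spectra(design, seed = seed)
    spectra <- sim$spectra
    metadata <- sim$metadata
    truth <- sim$truth
    write_spectra(spectra, metadata, out_dir)
    jsonlite::write_json(
      list(discriminative_band_indices = truth$discriminative_band_indices,
           presence = truth$presence, no_signal = truth$no_signal),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    log_stage("simulate", "%d spectra, %d bands", nrow(metadata),
              nrow(truth$bands))
  } else {
    ds <- read_spectra(config$input_dir)
    spectra <- ds$spectra
    metadata <- ds$metadata
    log_stage("load", "%d spectra from %s", nrow(metadata), config$input_dir)
  }

  # stage 2: preprocessing
  flt <- filter_no_signal(spectra, metadata,
                          min_prominence_snr = pp$min_prominence_snr,
                          min_peaks = pp$min_peaks,
                          smooth_window = pp$smooth_window)
  log_stage("filter", "retained %d / %d spectra", sum(flt$retained),
            length(flt$retained))
  ref_bands <- if (!is.null(truth)) truth$bands$center else
    default_band_library()$center
  occ <- band_occurrence(flt$spectra, ref_bands, tolerance = pp$tolerance,
                         min_prominence_snr = pp$min_prominence_snr,
                         smooth_window = pp$smooth_window)
  readr::write_tsv(occ, file.path(out_dir, "occurrence.tsv"))
  avg <- mean_spectrum(flt$spectra, normalize_first = TRUE)
  readr::write_tsv(avg, file.path(out_dir, "mean_spectrum.tsv"))
  features <- bin_to_variables(flt$spectra, flt$metadata,
                               bin_width = pp$bin_width,
                               normalize = pp$normalize)
  readr::write_tsv(features, file.path(out_dir, "features.tsv"))

  # stage 3: surrogate forest + SMD selection + MAA
  smd <- smd_select(features, num_trees = fp$num_trees, mtry = fp$mtry,
                    s = fp$s, min_node_size = fp$min_node_size,
                    bootstrap = fp$bootstrap,
                    n_shadow_repeats = fp$n_shadow_repeats, seed = seed)
  readr::write_tsv(tidy(smd), file.path(out_dir, "smd.tsv"))
  maa <- mean_adjusted_agreement(smd$forest)
  readr::write_tsv(tidy(maa), file.path(out_dir, "maa.tsv"))
  log_stage("rfsmd", "%d / %d variables selected (threshold %.3f)",
            sum(smd$selected), length(smd$smd), smd$threshold)

  # stage 4: relation map + PCA eigenspectra
  ann <- if (!is.null(truth)) truth$bands else default_band_library()
  rmap <- suppressWarnings(build_relation_map(smd, maa, annotations = ann))
  export_relation_map(rmap, out_dir)
  n_comp <- min(3, nrow(features) - 1, length(maa$variables))
  pca <- pca_eigenspectra(features, n_components = n_comp)
  readr::write_tsv(tidy(pca), file.path(out_dir, "pca_loadings.tsv"))
  readr::write_tsv(
    tibble::tibble(component = paste0("PC", seq_along(pca$explained_variance)),
                   explained = pca$explained_variance),
    file.path(out_dir, "pca_explained.tsv"))
  log_stage("map", "%d related cells; PC1 explains %.1f%%", sum(rmap$mask),
            100 * pca$explained_variance[1])

  params <- list(preprocessing = pp,
                 forest = fp[!vapply(fp, is.null, logical(1))], seed = seed)
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    parameters = params,
    parameter_hash = unname(tools::md5sum(write_temp_json(params))),
    seed = seed,
    n_spectra = nrow(metadata),
    n_retained = sum(flt$retained),
    n_variables = length(smd$smd),
    n_selected = sum(smd$selected),
    smd_threshold = smd$threshold,
    relation_threshold = rmap$threshold,
    n_related_cells = sum(rmap$mask),
    pc1_explained = pca$explained_variance[1],
    checksums = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
}

coerce_design_args <- function(x) {
  if (!is.null(x$bands) && !inherits(x$bands, "data.frame")) {
    x$bands <- tibble::as_tibble(do.call(
      function(...) dplyr::bind_rows(lapply(list(...), tibble::as_tibble)),
      x$bands))
  }
  x
}

write_temp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  f
}
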