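#' Surrogate minimal depth
#'
#' For every variable `v` and tree `t`, the minimal depth of `v` in `t` is
#' the depth of the shallowest internal node at which `v` is either the
#' primary split variable or one of the node's stored surrogates; if `v`
#' appears nowhere in the tree it is assigned the depth of the deepest
#' internal node plus one. The surrogate minimal depth SMD(`v`) is the mean
#' of these per-tree depths over all trees. Low SMD marks variables that
#' split — or closely mimic splits — near the roots of many trees, i.e.
#' important variables.
#'
#' Trees without a single internal node carry no depth information and are
#' excluded from the average; a forest consisting only of such trees is an
#' error.
#'
#' @param forest a [fit_forest()] object.
#' @return Named numeric vector of SMD values, one per variable.
#' @export
surrogate_minimal_depth <- function(forest) {
  p <- length(forest$variables)
  depth_sum <- numeric(p)
  n_used <- 0L
  for (tr in forest$trees) {
    nd <- tr$nodes
    internal <- !nd$is_leaf
    if (!any(internal)) next
    n_used <- n_used + 1L
    dmax <- max(nd$depth[internal])
    d <- rep(dmax + 1, p)
    # primary appearances
    pv <- nd$var[internal]
    pd <- nd$depth[internal]
    for (i in seq_along(pv)) {
      if (pd[i] < d[pv[i]]) d[pv[i]] <- pd[i]
    }
    # surrogate appearances
    sv <- tr$surrogates$var
    if (length(sv)) {
      node_depth <- nd$depth[tr$surrogates$node]
      for (i in seq_along(sv)) {
        if (node_depth[i] < d[sv[i]]) d[sv[i]] <- node_depth[i]
      }
    }
    depth_sum <- depth_sum + d
  }
  if (n_used == 0L) {
    stop("forest contains no internal nodes; SMD undefined", call. = FALSE)
  }
  stats::setNames(depth_sum / n_used, forest$variables)
}

#' SMD variable selection with a shadow-variable threshold
#'
#' Fits a surrogate forest, computes surrogate minimal depth for every
#' variable, and selects important variables against a shadow-variable
#' null: the feature table is augmented with an independently permuted copy
#' of every column (class labels untouched) and the forest is refit with
#' the same parameters. Within that augmented forest real and shadow
#' variables compete for the same split and surrogate slots, so their SMD
#' values live on a common scale; a real variable is selected when its
#' null-scale SMD falls below a threshold computed from the shadow SMDs.
#' With `n_shadow_repeats > 1` the shadow fit is repeated and both the
#' per-variable null-scale SMD and the threshold are averaged.
#'
#' Two threshold modes are provided. `"shadow_min"` (default) uses the
#' minimum shadow SMD: a variable must outrank every one of the `p`
#' permuted decoys, a family-wise guard in the spirit of Boruta with an
#' expected null selection rate of roughly `1 / (p + 1)`. `"shadow_mean"`
#' uses the mean shadow SMD — the average depth an irrelevant variable
#' reaches by chance; because real irrelevant variables and shadows are
#' exchangeable, about half of them fall below this mean, so it
#' characterizes the null rather than controlling false selection.
#'
#' The shadow fit also yields a null pool of mean-adjusted-agreement values
#' between real and shadow variables, stored for use as the default relation
#' threshold of [build_relation_map()].
#'
#' @inheritParams fit_forest
#' @param n_shadow_repeats number of independent shadow permutation rounds.
#' @param threshold_mode `"shadow_min"` or `"shadow_mean"`, see Details.
#' @return An object of class `smd_result` with the fitted `forest`, the
#'   main-forest `smd` vector (the importance measure), `smd_null_scale`
#'   (per-variable SMD on the augmented-forest scale), `threshold`, logical
#'   `selected` (`smd_null_scale < threshold`), and shadow diagnostics.
#' @export
#' @examples
#' d <- tibble::tibble(group = rep(c("a", "b"), each = 15),
#'                     sig = c(rnorm(15), rnorm(15, 3)),
#'                     noise = rnorm(30))
#' r <- smd_select(d, num_trees = 30, seed = 7)
#' tidy(r)
smd_select <- function(data, label_col = "group", num_trees = 500,
                       mtry = NULL, s = NULL, min_node_size = 5,
                       bootstrap = TRUE, n_shadow_repeats = 1,
                       threshold_mode = c("shadow_min", "shadow_mean"),
                       seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(n_shadow_repeats >= 1)
  parts <- features_parts(data, label_col)
  p <- ncol(parts$X)
  forest <- fit_forest(data, label_col = label_col, num_trees = num_trees,
                       mtry = mtry, s = s, min_node_size = min_node_size,
                       bootstrap = bootstrap, seed = seed)
  smd <- surrogate_minimal_depth(forest)

  withr::local_seed((seed %% 900000000L) + 7L)
  rep_seeds <- sample.int(.Machine$integer.max, n_shadow_repeats)
  shadow_thresholds <- numeric(n_shadow_repeats)
  real_null_scale <- matrix(0, p, n_shadow_repeats)
  shadow_smd_all <- list()
  maa_null <- list()
  for (r in seq_len(n_shadow_repeats)) {
    withr::local_seed(rep_seeds[r])
    Xs <- apply(parts$X, 2, sample)
    colnames(Xs) <- paste0(".shadow_", parts$variables)
    aug <- dplyr::bind_cols(
      tibble::tibble(!!label_col := parts$y),
      tibble::as_tibble(parts$X),
      tibble::as_tibble(Xs)
    )
    sf <- fit_forest(aug, label_col = label_col, num_trees = num_trees,
                     mtry = mtry, s = s, min_node_size = min_node_size,
                     bootstrap = bootstrap, seed = rep_seeds[r] %% 1000000L)
    smd_aug <- surrogate_minimal_depth(sf)
    real_null_scale[, r] <- smd_aug[seq_len(p)]
    sh <- smd_aug[(p + 1):(2 * p)]
    shadow_thresholds[r] <- switch(threshold_mode,
                                   shadow_min = min(sh),
                                   shadow_mean = mean(sh))
    shadow_smd_all[[r]] <- sh
    maa_aug <- mean_adjusted_agreement(sf)
    maa_null[[r]] <- as.vector(maa_aug$maa[seq_len(p), (p + 1):(2 * p)])
  }
  threshold <- mean(shadow_thresholds)
  smd_null_scale <- stats::setNames(rowMeans(real_null_scale),
                                    parts$variables)
  null_pool <- unlist(maa_null)
  structure(
    list(forest = forest, smd = smd, smd_null_scale = smd_null_scale,
         threshold = threshold, threshold_mode = threshold_mode,
         selected = smd_null_scale < threshold,
         shadow = list(thresholds = shadow_thresholds,
                       smd = shadow_smd_all,
                       maa_null_mean = mean(null_pool),
                       maa_null_sd = stats::sd(null_pool),
                       n_repeats = n_shadow_repeats)),
    class = "smd_result"
  )
}

#' @export
print.smd_result <- function(x, ...) {
  cat("<smd_result>\n")
  cat(sprintf("  %d variables, %s threshold %.3f (%d shadow repeat%s)\n",
              length(x$smd), x$threshold_mode, x$threshold,
              x$shadow$n_repeats,
              if (x$shadow$n_repeats > 1) "s" else ""))
  cat(sprintf("  %d selected: %s\n", sum(x$selected),
              paste(utils::head(names(x$smd)[x$selected], 12),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname smd_select
#' @param x an `smd_result`.
#' @param ... unused.
#' @export
tidy.smd_result <- function(x, ...) {
  tibble::tibble(variable = names(x$smd), smd = unname(x$smd),
                 smd_null_scale = unname(x$smd_null_scale),
                 threshold = x$threshold, selected = unname(x$selected))
}

#' @export
glance.smd_result <- function(x, ...) {
  tibble::tibble(n_variables = length(x$smd), n_selected = sum(x$selected),
                 threshold = x$threshold, threshold_mode = x$threshold_mode,
                 shadow_repeats = x$shadow$n_repeats,
                 num_trees = x$forest$params$num_trees,
                 seed = x$forest$params$seed)
}

#' Plot SMD values against the selection threshold
#'
#' @param object an `smd_result`.
#' @param ... unused.
#' @return A ggplot: SMD per wavenumber variable with the shadow threshold
#'   line; selected variables highlighted.
#' @export
autoplot.smd_result <- function(object, ...) {
  d <- tidy(object)
  d$wavenumber <- suppressWarnings(as.numeric(d$variable))
  if (anyNA(d$wavenumber)) d$wavenumber <- seq_along(d$variable)
  ggplot2::ggplot(d, ggplot2::aes(.data$wavenumber, .data$smd_null_scale,
                                  colour = .data$selected)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#D55E00")) +
    ggplot2::labs(x = "wavenumber (cm⁻¹)",
                  y = "surrogate minimal depth (null scale)",
                  colour = "selected") +
    ggplot2::theme_minimal()
}
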