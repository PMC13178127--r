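#' Mean adjusted agreement between variables
#'
#' MAA(i, j) is the mean, over all internal nodes of the forest whose
#' primary split variable is `i`, of the adjusted agreement of `j`'s best
#' surrogate split at that node; nodes where `j` is not among the stored
#' top-`s` surrogates contribute 0. Rows of variables that never act as a
#' primary splitter are all zero. High MAA(i, j) means `j` can consistently
#' mimic the partitions induced by `i` — in spectral terms, the two
#' wavenumber variables co-occur. MAA is not symmetric in general.
#'
#' @param forest a [fit_forest()] object with `s >= 1` stored surrogates.
#' @return An object of class `maa_matrix`: list with `maa` (p x p matrix,
#'   diagonal stored as 1), `n_primary` (nodes per primary variable), and
#'   `variables`.
#' @export
mean_adjusted_agreement <- function(forest) {
  if (forest$params$s < 1) stop("no surrogates stored", call. = FALSE)
  p <- length(forest$variables)
  acc <- matrix(0, p, p)
  n_primary <- numeric(p)
  for (tr in forest$trees) {
    nd <- tr$nodes
    internal <- which(!nd$is_leaf)
    if (!length(internal)) next
    node_var <- rep(NA_integer_, length(nd$id))
    node_var[nd$id] <- nd$var
    pv <- nd$var[internal]
    tab <- tabulate(pv, nbins = p)
    n_primary <- n_primary + tab
    sv <- tr$surrogates
    if (length(sv$var)) {
      i_var <- node_var[sv$node]
      idx <- (sv$var - 1) * p + i_var          # column-major (i, j) cell
      add <- rowsum(sv$adjusted, idx)
      acc[as.numeric(rownames(add))] <- acc[as.numeric(rownames(add))] + add
    }
  }
  maa <- acc / ifelse(n_primary > 0, n_primary, 1)
  diag(maa) <- 1
  dimnames(maa) <- list(forest$variables, forest$variables)
  structure(list(maa = maa,
                 n_primary = stats::setNames(n_primary, forest$variables),
                 variables = forest$variables),
            class = "maa_matrix")
}

#' @export
print.maa_matrix <- function(x, ...) {
  off <- x$maa[upper.tri(x$maa) | lower.tri(x$maa)]
  cat("<maa_matrix>\n")
  cat(sprintf("  %d variables; off-diagonal MAA: median %.4f, max %.4f\n",
              length(x$variables), stats::median(off), max(off)))
  cat(sprintf("  %d variables never primary\n", sum(x$n_primary == 0)))
  invisible(x)
}

#' Tidy an MAA matrix into long form
#'
#' @param x a `maa_matrix`.
#' @param ... unused.
#' @return Tibble with `primary`, `related`, `maa`, `n_primary`, excluding
#'   the diagonal.
#' @export
tidy.maa_matrix <- function(x, ...) {
  p <- length(x$variables)
  out <- tidyr::expand_grid(primary = x$variables, related = x$variables)
  out$maa <- as.vector(t(x$maa))
  out$n_primary <- rep(unname(x$n_primary), each = p)
  out[out$primary != out$related, , drop = FALSE]
}
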