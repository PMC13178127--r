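#' Gini impurity of a label vector
#'
#' @param labels vector of class labels (any atomic type).
#' @return `1 - sum(p_k^2)` over class proportions `p_k`.
#' @export
#' @examples
#' gini_impurity(c(1, 1, 0, 0))  # 0.5
gini_impurity <- function(labels) {
  if (length(labels) == 0) stop("empty label vector", call. = FALSE)
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

#' Best primary split by exhaustive midpoint scan
#'
#' Reference implementation of the CART split search used at every internal
#' node: for each candidate variable, candidate thresholds are the midpoints
#' between consecutive distinct sorted values; the split maximizing the
#' weighted Gini decrease is returned. Decrease ties are broken by the
#' variable with the best (lowest) tie-break priority — by default the
#' lowest variable index — then by lowest threshold. [fit_forest()] draws a
#' random priority per tree (stored as `tie_priority`) so that ties do not
#' systematically favour low column positions.
#'
#' @param X numeric sample-by-variable matrix.
#' @param y class labels, length `nrow(X)`.
#' @param candidates variable indices to scan (default: all).
#' @param tie_priority integer vector over all variables, smaller =
#'   preferred on exact decrease ties; default is the variable index.
#' @return A one-row tibble with `var`, `threshold`, `decrease`, `p_left`,
#'   or `NULL` when no candidate variable admits a split (leaf sentinel).
#' @export
best_primary_split <- function(X, y, candidates = seq_len(ncol(X)),
                               tie_priority = seq_len(ncol(X))) {
  n <- nrow(X)
  stopifnot(n >= 2, length(candidates) >= 1)
  if (length(unique(y)) < 2) stop("need >= 2 classes present", call. = FALSE)
  g_parent <- gini_impurity(y)
  best <- NULL
  for (v in candidates[order(tie_priority[candidates])]) {
    x <- X[, v]
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    for (i in seq_len(n - 1)) {
      if (xs[i + 1] <= xs[i]) next
      mid <- (xs[i] + xs[i + 1]) / 2
      if (!(mid > xs[i] && mid < xs[i + 1])) next
      nl <- i; nr <- n - i
      dec <- g_parent - (nl / n) * gini_impurity(ys[seq_len(i)]) -
        (nr / n) * gini_impurity(ys[(i + 1):n])
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- tibble::tibble(var = v, threshold = mid, decrease = dec,
                               p_left = nl / n)
      }
    }
  }
  best
}

#' Chance-corrected agreement of a surrogate partition
#'
#' Given the primary split's left/right routing and a candidate surrogate
#' routing over the same samples, computes the adjusted agreement
#' `max(0, (A - p_maj) / (1 - p_maj))` where `A` is the matching fraction
#' under the better of the two orientations (direct or mirrored) and
#' `p_maj = max(p_L, 1 - p_L)` of the primary split. A surrogate that merely
#' sends everything to the primary's majority side scores 0; an exact copy
#' scores 1.
#'
#' @param primary_left logical vector: `TRUE` where the primary split routes
#'   a sample left.
#' @param surrogate_left logical vector of the same length for the surrogate.
#' @return Adjusted agreement in \[0, 1\].
#' @export
adjusted_agreement <- function(primary_left, surrogate_left) {
  n <- length(primary_left)
  stopifnot(n >= 2, length(surrogate_left) == n)
  nl <- sum(primary_left)
  if (nl == 0 || nl == n) {
    stop("primary split routes all samples one way", call. = FALSE)
  }
  p_maj <- max(nl / n, 1 - nl / n)
  a <- max(sum(primary_left == surrogate_left),
           sum(primary_left != surrogate_left)) / n
  max(0, (a - p_maj) / (1 - p_maj))
}

#' Surrogate splits for a primary split
#'
#' Reference implementation of the per-node surrogate search: for every
#' variable other than the primary's, all midpoint thresholds and both
#' orientations are scanned and the threshold maximizing the adjusted
#' agreement against the primary partition is kept. The top `s` surrogates
#' with adjusted agreement > 0 are returned, sorted by descending adjusted
#' agreement (exact ties by best tie-break priority, default the lower
#' variable index).
#'
#' @inheritParams best_primary_split
#' @param X numeric sample-by-variable matrix (node samples).
#' @param primary one-row data frame as returned by [best_primary_split()].
#' @param s maximum number of surrogates to keep.
#' @return Tibble with `var`, `threshold`, `mirrored`, `agreement`,
#'   `adjusted` (possibly fewer than `s` rows, possibly empty).
#' @export
surrogate_splits <- function(X, primary, s,
                             tie_priority = seq_len(ncol(X))) {
  stopifnot(s >= 0)
  if (s == 0) {
    return(tibble::tibble(var = integer(), threshold = numeric(),
                          mirrored = logical(), agreement = numeric(),
                          adjusted = numeric()))
  }
  n <- nrow(X)
  primary_left <- X[, primary$var] <= primary$threshold
  nl <- sum(primary_left)
  p_maj <- max(nl / n, 1 - nl / n)
  rows <- list()
  for (v in seq_len(ncol(X))) {
    if (v == primary$var) next
    x <- X[, v]
    xs <- sort(unique(x))
    if (length(xs) < 2) next
    best <- NULL
    for (i in seq_len(length(xs) - 1)) {
      mid <- (xs[i] + xs[i + 1]) / 2
      if (!(mid > xs[i] && mid < xs[i + 1])) next
      surr_left <- x <= mid
      for (mirrored in c(FALSE, TRUE)) {
        sl <- if (mirrored) !surr_left else surr_left
        a <- sum(primary_left == sl) / n
        adj <- max(0, (a - p_maj) / (1 - p_maj))
        if (is.null(best) || adj > best$adjusted + 1e-12) {
          best <- tibble::tibble(var = v, threshold = mid,
                                 mirrored = mirrored, agreement = a,
                                 adjusted = adj)
        }
      }
    }
    if (!is.null(best) && best$adjusted > 0) rows[[length(rows) + 1]] <- best
  }
  if (length(rows) == 0) {
    return(tibble::tibble(var = integer(), threshold = numeric(),
                          mirrored = logical(), agreement = numeric(),
                          adjusted = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$adjusted, tie_priority[out$var]), , drop = FALSE]
  utils::head(out, s)
}
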