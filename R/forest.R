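#' Fit a classification forest with surrogate splits
#'
#' Grows an ensemble of CART-style classification trees in which every
#' internal node additionally stores its top `s` surrogate splits — splits on
#' other variables that best mimic the primary split's sample routing,
#' ranked by adjusted agreement. The surrogate records are what surrogate
#' minimal depth ([surrogate_minimal_depth()]) and mean adjusted agreement
#' ([mean_adjusted_agreement()]) are read from.
#'
#' Splitting follows CART conventions: Gini impurity, midpoint thresholds
#' between consecutive distinct values, ties broken by lowest variable index
#' then lowest threshold. At each node the primary split is chosen among
#' `mtry` uniformly drawn candidate variables; surrogates are scanned over
#' all variables. Recursion stops at class purity or node size
#' `min_node_size`. The fit is fully deterministic given `seed`.
#'
#' @param data tibble/data frame of features: optional `spectrum_id`, a label
#'   column (default `group`) with exactly the class of each sample, and
#'   numeric feature columns (e.g. from [bin_to_variables()]).
#' @param label_col name of the class-label column.
#' @param num_trees number of trees.
#' @param mtry candidate variables per node; default `ceiling(sqrt(p))`.
#' @param s surrogates stored per node; default `max(5, ceiling(p / 100))`.
#' @param min_node_size nodes at or below this size are not split.
#' @param bootstrap grow each tree on a bootstrap resample.
#' @param seed integer seed (required).
#' @return An object of class `surrogate_forest`.
#' @export
#' @examples
#' d <- tibble::tibble(group = rep(c("a", "b"), each = 10),
#'                     x1 = c(rnorm(10), rnorm(10, 4)), x2 = rnorm(20))
#' f <- fit_forest(d, num_trees = 10, seed = 1)
#' f
fit_forest <- function(data, label_col = "group", num_trees = 500,
                       mtry = NULL, s = NULL, min_node_size = 5,
                       bootstrap = TRUE, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  parts <- features_parts(data, label_col)
  if (is.null(parts$y)) stop("label column '", label_col, "' not found",
                             call. = FALSE)
  y <- factor(parts$y)
  if (nlevels(y) < 2) stop("need at least two classes", call. = FALSE)
  p <- ncol(parts$X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  if (is.null(s)) s <- max(5L, ceiling(p / 100))
  stopifnot(num_trees >= 1, mtry >= 1, mtry <= p, s >= 0, min_node_size >= 1)
  withr::local_seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max, num_trees)
  trees <- .fit_forest_cpp(parts$X, as.integer(y) - 1L, nlevels(y),
                           as.integer(num_trees), as.integer(mtry),
                           as.integer(s), as.integer(min_node_size),
                           bootstrap, tree_seeds)
  structure(
    list(trees = trees, variables = parts$variables, classes = levels(y),
         params = list(num_trees = num_trees, mtry = mtry, s = s,
                       min_node_size = min_node_size, bootstrap = bootstrap,
                       seed = seed)),
    class = "surrogate_forest"
  )
}

#' @export
print.surrogate_forest <- function(x, ...) {
  ni <- vapply(x$trees, function(t) sum(!t$nodes$is_leaf), integer(1))
  cat("<surrogate_forest>\n")
  cat(sprintf("  %d trees on %d variables, classes: %s\n",
              length(x$trees), length(x$variables),
              paste(x$classes, collapse = " / ")))
  cat(sprintf("  mtry %d, %d surrogates/node, min node size %d, seed %d\n",
              x$params$mtry, x$params$s, x$params$min_node_size,
              x$params$seed))
  cat(sprintf("  internal nodes/tree: median %g\n", stats::median(ni)))
  invisible(x)
}

#' Tidy the node table of a surrogate forest
#'
#' @param x a `surrogate_forest`.
#' @param ... unused.
#' @return Tibble with one row per node over all trees (`tree`, `node`,
#'   `depth`, `size`, `is_leaf`, `variable`, `threshold`, `decrease`,
#'   `p_left`).
#' @export
tidy.surrogate_forest <- function(x, ...) {
  purrr::imap_dfr(x$trees, function(tr, t) {
    nd <- tr$nodes
    tibble::tibble(tree = t, node = nd$id, depth = nd$depth, size = nd$size,
                   is_leaf = nd$is_leaf,
                   variable = ifelse(is.na(nd$var), NA_character_,
                                     x$variables[nd$var]),
                   threshold = nd$threshold, decrease = nd$decrease,
                   p_left = nd$p_left)
  })
}

#' @export
glance.surrogate_forest <- function(x, ...) {
  ni <- vapply(x$trees, function(t) sum(!t$nodes$is_leaf), integer(1))
  dp <- vapply(x$trees, function(t) {
    d <- t$nodes$depth[!t$nodes$is_leaf]
    if (length(d)) max(d) else NA_integer_
  }, integer(1))
  tibble::tibble(num_trees = length(x$trees),
                 n_variables = length(x$variables),
                 mean_internal_nodes = mean(ni),
                 max_internal_depth = max(dp, na.rm = TRUE),
                 s = x$params$s, mtry = x$params$mtry,
                 seed = x$params$seed)
}

#' Serialize a surrogate forest to JSON
#'
#' Writes the complete forest — per-node primary splits, surrogate records,
#' in-bag indices and parameters — to a JSON file; [read_forest_json()]
#' reconstructs an identical object. The serialized form is the surface
#' against which SMD/MAA oracles can be checked.
#'
#' @param forest a `surrogate_forest`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(forest, path) {
  obj <- list(variables = forest$variables, classes = forest$classes,
              params = forest$params,
              trees = lapply(forest$trees, function(tr) {
                list(nodes = tr$nodes, surrogates = tr$surrogates,
                     inbag = tr$inbag, tie_priority = tr$tie_priority)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_forest_json
#' @export
read_forest_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  trees <- lapply(obj$trees, function(tr) {
    list(nodes = tr$nodes, surrogates = tr$surrogates,
         inbag = as.integer(tr$inbag),
         tie_priority = as.integer(tr$tie_priority))
  })
  structure(list(trees = trees, variables = obj$variables,
                 classes = obj$classes, params = obj$params),
            class = "surrogate_forest")
}
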