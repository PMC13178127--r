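# Naive brute-force oracles, written independently of the package's split
# search: plain double loops over every candidate (variable, threshold,
# orientation), no sorting tricks, no shared helpers.

oracle_gini <- function(y) {
  cnt <- table(y)
  1 - sum((as.numeric(cnt) / length(y))^2)
}

# enumerate all (variable, midpoint threshold) pairs, return the maximizer
# of the weighted Gini decrease; ties -> lowest var, lowest threshold
oracle_best_split <- function(X, y, candidates = seq_len(ncol(X))) {
  n <- nrow(X)
  g0 <- oracle_gini(y)
  best <- NULL
  for (v in sort(candidates)) {
    vals <- sort(unique(X[, v]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      if (!(thr > vals[i] && thr < vals[i + 1])) next
      left <- X[, v] <= thr
      nl <- sum(left)
      if (nl == 0 || nl == n) next
      dec <- g0 - (nl / n) * oracle_gini(y[left]) -
        ((n - nl) / n) * oracle_gini(y[!left])
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(var = v, threshold = thr, decrease = dec,
                     p_left = nl / n)
      }
    }
  }
  best
}

# per-variable best surrogate by full enumeration; returns the top-s table
oracle_surrogates <- function(X, primary_var, primary_thr, s) {
  n <- nrow(X)
  prim_left <- X[, primary_var] <= primary_thr
  p_maj <- max(mean(prim_left), 1 - mean(prim_left))
  out <- NULL
  for (v in seq_len(ncol(X))) {
    if (v == primary_var) next
    vals <- sort(unique(X[, v]))
    if (length(vals) < 2) next
    best <- NULL
    for (i in seq_len(length(vals) - 1)) {
      thr <- (vals[i] + vals[i + 1]) / 2
      if (!(thr > vals[i] && thr < vals[i + 1])) next
      for (mirrored in c(FALSE, TRUE)) {
        sl <- X[, v] <= thr
        if (mirrored) sl <- !sl
        a <- mean(prim_left == sl)
        adj <- max(0, (a - p_maj) / (1 - p_maj))
        if (is.null(best) || adj > best$adjusted + 1e-12) {
          best <- list(var = v, threshold = thr, mirrored = mirrored,
                       agreement = a, adjusted = adj)
        }
      }
    }
    if (!is.null(best) && best$adjusted > 0) {
      out <- rbind(out, as.data.frame(best))
    }
  }
  if (is.null(out)) {
    return(data.frame(var = integer(), threshold = numeric(),
                      mirrored = logical(), agreement = numeric(),
                      adjusted = numeric()))
  }
  out <- out[order(-out$adjusted, out$var), , drop = FALSE]
  head(out, s)
}

# recompute each node's sample set of a fitted tree by routing the in-bag
# samples from the root, following the stored primary splits
oracle_node_samples <- function(tree, X) {
  nd <- tree$nodes
  sets <- vector("list", length(nd$id))
  sets[[1]] <- tree$inbag
  for (k in order(nd$depth)) {
    if (nd$is_leaf[k]) next
    rows <- sets[[nd$id[k]]]
    left <- X[rows, nd$var[k]] <= nd$threshold[k]
    sets[[nd$left[k]]] <- rows[left]
    sets[[nd$right[k]]] <- rows[!left]
  }
  sets
}

# exhaustive walk: per-tree minimal depth of every variable (primary or
# surrogate appearance), absent = deepest internal depth + 1; mean over
# trees with at least one internal node
oracle_smd <- function(forest) {
  p <- length(forest$variables)
  per_tree <- list()
  for (tr in forest$trees) {
    nd <- tr$nodes
    if (all(nd$is_leaf)) next
    walk <- function(id, depth) {
      k <- which(nd$id == id)
      if (nd$is_leaf[k]) return(NULL)
      here <- data.frame(var = nd$var[k], depth = depth)
      sv <- tr$surrogates$var[tr$surrogates$node == id]
      if (length(sv)) here <- rbind(here, data.frame(var = sv, depth = depth))
      rbind(here, walk(nd$left[k], depth + 1), walk(nd$right[k], depth + 1))
    }
    app <- walk(1, 0)
    dmax <- max(app$depth)
    d <- rep(dmax + 1, p)
    for (r in seq_len(nrow(app))) {
      d[app$var[r]] <- min(d[app$var[r]], app$depth[r])
    }
    per_tree[[length(per_tree) + 1]] <- d
  }
  if (!length(per_tree)) stop("no internal nodes")
  colMeans(do.call(rbind, per_tree))
}

# exhaustive MAA recomputation from the serialized trees
oracle_maa <- function(forest) {
  p <- length(forest$variables)
  acc <- matrix(0, p, p)
  n_primary <- numeric(p)
  for (tr in forest$trees) {
    nd <- tr$nodes
    for (k in seq_along(nd$id)) {
      if (nd$is_leaf[k]) next
      i <- nd$var[k]
      n_primary[i] <- n_primary[i] + 1
      sel <- tr$surrogates$node == nd$id[k]
      for (r in which(sel)) {
        j <- tr$surrogates$var[r]
        acc[i, j] <- acc[i, j] + tr$surrogates$adjusted[r]
      }
    }
  }
  m <- acc / ifelse(n_primary > 0, n_primary, 1)
  diag(m) <- 1
  m
}
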