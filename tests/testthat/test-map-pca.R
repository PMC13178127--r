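dup_pair_result <- function(seed = 3) {
  withr::local_seed(seed)
  n <- 60
  y <- rep(c("control", "treated"), each = n / 2)
  x1 <- ifelse(y == "treated", 4, 0) + rnorm(n, sd = 0.2)
  d <- tibble::tibble(group = y, `1002` = x1, `1101` = x1,
                      `798` = rnorm(n), `679` = rnorm(n))
  smd_select(d, num_trees = 40, seed = seed)
}

test_that("relation maps mark duplicates as related and annotate columns", {
  r <- dup_pair_result()
  map <- build_relation_map(r)
  expect_true(all(rownames(map$values) == map$row_variables))
  # rows sorted by descending wavenumber
  expect_identical(map$row_variables,
                   map$row_variables[order(as.numeric(map$row_variables),
                                           decreasing = TRUE)])
  td <- tidy(map)
  dup <- td[td$band == "1101" & td$variable == "1002", ]
  if (nrow(dup) == 1) {
    expect_equal(dup$maa, 1.0)
    expect_true(dup$related)
  }
  dup2 <- td[td$band == "1002" & td$variable == "1101", ]
  if (nrow(dup2) == 1) expect_equal(dup2$maa, 1.0)
  expect_true(any(c(nrow(dup), nrow(dup2)) == 1))
  # annotations come from the band library: 1002 = protein, 798/1101 = lipid
  expect_equal(unname(map$annotation[c("1002", "1101", "798")]),
               c("protein", "lipid", "lipid"))
  # mask consistency
  expect_identical(map$mask, map$values > map$threshold)
})

test_that("empty selections yield an empty map, not an error", {
  r <- dup_pair_result()
  r$selected[] <- FALSE
  expect_warning(map <- build_relation_map(r), "no variables selected")
  expect_equal(nrow(map$values), 0)
  expect_equal(nrow(tidy(map)), 0)
  dir <- withr::local_tempdir()
  export_relation_map(map, dir)
  hdr <- readr::read_tsv(file.path(dir, "relation_map_values.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(hdr), 0)
})

test_that("exported relation maps round-trip exactly", {
  r <- dup_pair_result(seed = 5)
  map <- build_relation_map(r)
  dir <- withr::local_tempdir()
  export_relation_map(map, dir)
  vals <- read_relation_map_values(file.path(dir, "relation_map_values.tsv"))
  expect_equal(unname(vals), unname(map$values))
  expect_identical(rownames(vals), map$row_variables)
  mask <- read_relation_map_values(file.path(dir, "relation_map_mask.tsv"))
  expect_equal(unname(mask == 1), unname(vals > map$threshold))
})

test_that("selected variable names are stable under column reordering", {
  des <- planted_design(n_signal = 3, n_noise = 17, n_per_class = 150)
  feat <- planted_features(des, seed = 31)
  r1 <- smd_select(feat, num_trees = 150, seed = 31)
  withr::local_seed(1)
  perm <- c(1, 2, sample(3:ncol(feat)))
  r2 <- smd_select(feat[, perm], num_trees = 150, seed = 31)
  # candidate draws attach to column positions, so borderline noise picks
  # may differ; the planted variables and the error level must not
  signal <- names(r1$smd)[1:3]
  expect_true(all(r1$selected[signal]))
  expect_true(all(r2$selected[signal]))
  expect_lte(sum(r1$selected) - 3, 2)
  expect_lte(sum(r2$selected) - 3, 2)
})

test_that("PCA loadings are orthonormal eigenspectra with a fixed sign", {
  withr::local_seed(9)
  n <- 40
  X <- matrix(rnorm(n * 10), n, 10)
  colnames(X) <- paste0("w", 1:10)
  d <- dplyr::bind_cols(tibble::tibble(group = rep(c("a", "b"), n / 2)),
                        tibble::as_tibble(X))
  pc <- pca_eigenspectra(d, n_components = 4)
  G <- pc$loadings %*% t(pc$loadings)
  expect_equal(G, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1 + 1e-12)
  for (k in 1:4) {
    j <- which.max(abs(pc$loadings[k, ]))
    expect_gt(pc$loadings[k, j], 0)
  }
  # sign convention makes the decomposition deterministic under sign flips
  d2 <- d
  d2[-1] <- -d2[-1]
  pc2 <- pca_eigenspectra(d2, n_components = 4)
  expect_equal(abs(pc2$loadings), abs(pc$loadings), tolerance = 1e-8)
  expect_error(pca_eigenspectra(d, n_components = 39), "n_components")
})

test_that("rank-one data loads entirely on the first component", {
  t_ <- seq(-1, 1, length.out = 20)
  dirvec <- vector_normalize(c(3, 1, -2, 0.5))
  X <- outer(t_, dirvec) + 5
  colnames(X) <- paste0("w", 1:4)
  d <- dplyr::bind_cols(tibble::tibble(group = rep(c("a", "b"), 10)),
                        tibble::as_tibble(X))
  pc <- pca_eigenspectra(d, n_components = 2)
  expect_equal(pc$explained_variance[1], 1.0)
  expect_equal(abs(sum(pc$loadings[1, ] * dirvec)), 1, tolerance = 1e-8)
})

test_that("PC1 separates planted groups at least as well as single variables", {
  wins <- 0
  for (s in 1:10) {
    withr::local_seed(s)
    n <- 60
    y <- rep(c("control", "treated"), each = n / 2)
    shift <- ifelse(y == "treated", 1, 0)
    X <- matrix(rnorm(n * 12), n, 12)
    X[, 1:6] <- X[, 1:6] + shift * 1.2    # diffuse multivariate effect
    colnames(X) <- paste0("w", 1:12)
    d <- dplyr::bind_cols(tibble::tibble(group = y), tibble::as_tibble(X))
    pc <- pca_eigenspectra(d, n_components = 1)
    t_pc <- abs(t.test(pc$scores[y == "treated", 1],
                       pc$scores[y == "control", 1])$statistic)
    t_best <- max(apply(X, 2, function(x) {
      abs(t.test(x[y == "treated"], x[y == "control"])$statistic)
    }))
    wins <- wins + (t_pc > t_best)
  }
  expect_gte(wins, 8)
})
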