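# iid Gaussian feature table with random balanced labels (null data)
null_features <- function(n, p, seed) {
  withr::local_seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(group = rep(c("control", "treated"), length.out = n)),
    tibble::as_tibble(X)
  )
}
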