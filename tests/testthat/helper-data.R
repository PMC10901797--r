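# small fixture builders shared across test files

tiny_dataset <- function(n = 30, p = 12, seed = 1, n_sites = 2) {
  set.seed(seed)
  connectome_dataset(
    X = matrix(rnorm(n * p), n, p),
    y = rnorm(n),
    covariates = data.frame(age = runif(n, 8, 22),
                            sex = rbinom(n, 1, 0.5),
                            motion = rlnorm(n, -2.2, 0.5)),
    site = rep_len(paste0("site", seq_len(n_sites)), n),
    family_id = sprintf("fam%02d", seq_len(n)))
}

# brute-force per-column Pearson correlations (independent of the package's
# vectorized path)
brute_cor <- function(X, y) {
  apply(X, 2, function(col) {
    if (sd(col) == 0) 0 else cor(col, y)
  })
}
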