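#' Plain k-fold split
#'
#' Shuffles `1..n` with the given seed and deals the permutation round-robin
#' into `k` folds of size `floor(n/k)` or `ceiling(n/k)`. Dealing round-robin
#' (rather than in contiguous chunks) makes the family-aware splitter with
#' all-singleton families coincide with this one bitwise for the same seed.
#'
#' @param n number of rows.
#' @param k fold count, `2 <= k <= n`.
#' @param seed RNG seed.
#' @return List of `k` disjoint sorted test-index vectors whose union is
#'   `1..n`.
#' @export
plain_kfold <- function(n, k, seed = 1) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2 || k > n) stop_("need 2 <= k <= n")
  perm <- with_seed(seed, sample.int(n))
  lapply(seq_len(k), function(f) sort(perm[seq(f, n, by = k)]))
}

#' Family-aware k-fold split
#'
#' Assigns whole families to folds so relatives never straddle a train/test
#' boundary: families are shuffled with the seed, ordered largest first
#' (random within size ties), and dealt greedily to the currently smallest
#' fold by subject count. With 500 two-member families and `k = 5` every test
#' fold holds exactly 100 families (200 subjects); with all-singleton
#' families the scheme reduces to a balanced plain k-fold.
#'
#' @param family_ids family label per subject.
#' @param k fold count; must not exceed the number of families.
#' @param seed RNG seed.
#' @return List of `k` disjoint sorted test-index vectors partitioning the
#'   subjects.
#' @export
family_kfold <- function(family_ids, k, seed = 1) {
  family_ids <- as.character(family_ids)
  k <- as.integer(k)
  fams <- split(seq_along(family_ids), family_ids)
  if (k < 2) stop_("need k >= 2")
  if (k > length(fams))
    stop_("k (", k, ") exceeds the number of families (", length(fams), ")")
  fams <- with_seed(seed, sample(fams))
  fams <- fams[order(-lengths(fams))]     # stable: ties keep shuffled order
  counts <- integer(k)
  assign_to <- integer(length(fams))
  for (i in seq_along(fams)) {
    f <- which.min(counts)
    assign_to[i] <- f
    counts[f] <- counts[f] + length(fams[[i]])
  }
  lapply(seq_len(k), function(f)
    sort(unlist(fams[assign_to == f], use.names = FALSE)))
}

#' Duplicate a random percentage of subjects (subject leakage)
#'
#' Samples `round(pct/100 * n)` subjects without replacement and appends
#' verbatim copies of their rows (features, phenotype, covariates, site) with
#' fresh subject ids and fresh singleton family ids -- duplicates are *not*
#' tied to their source family, so family-aware splitting can still separate
#' a duplicate from its original, which is exactly the leakage being modeled.
#'
#' @param dataset a [connectome_dataset()].
#' @param pct percentage of subjects to duplicate, in `[0, 100]`.
#' @param seed RNG seed for the sample.
#' @return The augmented [connectome_dataset()] (`pct = 0` returns the input
#'   unchanged).
#' @export
inject_subject_leakage <- function(dataset, pct, seed = 1) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  if (pct < 0 || pct > 100) stop_("pct must lie in [0, 100]")
  n <- n_subjects(dataset)
  m <- round(pct / 100 * n)
  if (m == 0) return(dataset)
  idx <- with_seed(seed, sample.int(n, m))
  truth <- dataset$truth
  if (!is.null(truth) && !is.null(truth$latent))
    truth$latent <- c(truth$latent, truth$latent[idx])
  structure(list(
    subject_ids = c(dataset$subject_ids,
                    paste0(dataset$subject_ids[idx], ".dup", seq_len(m))),
    X = rbind(dataset$X, dataset$X[idx, , drop = FALSE]),
    y = c(dataset$y, dataset$y[idx]),
    covariates = rbind(dataset$covariates,
                       dataset$covariates[idx, , drop = FALSE]),
    site = c(dataset$site, dataset$site[idx]),
    family_id = c(dataset$family_id, sprintf(".dupfam%05d", seq_len(m))),
    truth = truth),
    class = "connectome_dataset")
}
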