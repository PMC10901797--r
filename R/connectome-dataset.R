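#' Connectome dataset
#'
#' Container for a subject-by-edge connectivity feature matrix together with
#' the phenotype, nuisance covariates, acquisition site and family labels
#' needed by the prediction pipelines. Edge features are typically Fisher-z
#' transformed correlations between parcel time series (one column per node
#' pair, see [vectorize_upper_triangle()]).
#'
#' Rows with a missing phenotype are dropped at construction time (a message
#' reports the count); connectivity features must be fully finite. Subjects
#' without an explicit family label are treated as singleton families, so
#' family-aware splitting is always well defined.
#'
#' @param X numeric matrix, `n_subjects x n_edges`, no non-finite values.
#' @param y numeric phenotype vector, length `n_subjects`; `NA` entries cause
#'   the corresponding rows to be dropped.
#' @param covariates data frame or numeric matrix of per-subject covariates
#'   (e.g. `age` in years, `sex` coded 0/1, `motion` as mean framewise
#'   displacement in mm). An intercept column is *not* included here; the
#'   correction stage adds it.
#' @param site character/factor site label per subject; default: one site.
#' @param family_id character/factor family label per subject; `NA` or missing
#'   labels become singleton families.
#' @param subject_ids unique subject identifiers; default `"sub00001"`, ...
#' @param truth optional list of generative ground truth (used by the
#'   synthetic generator; see [generate_dataset()]).
#'
#' @return An object of class `connectome_dataset`: a list with elements
#'   `subject_ids`, `X`, `y`, `covariates`, `site`, `family_id` (and `truth`
#'   when supplied).
#' @seealso [read_connectome_dataset()], [generate_dataset()]
#' @export
connectome_dataset <- function(X, y, covariates, site = NULL, family_id = NULL,
                               subject_ids = NULL, truth = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X)))
    stop_("X contains non-finite values; connectivity features must be complete")
  n <- nrow(X)
  y <- as.numeric(y)
  if (length(y) != n)
    stop_("length(y) [", length(y), "] does not match nrow(X) [", n, "]")

  if (is.null(subject_ids)) subject_ids <- sprintf("sub%05d", seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n) stop_("subject_ids length does not match nrow(X)")
  if (anyDuplicated(subject_ids)) stop_("subject_ids must be unique")

  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop_("covariates must have one row per subject")
  if (!all(vapply(covariates, is.numeric, logical(1))))
    stop_("all covariate columns must be numeric (code binary covariates 0/1)")
  if (anyNA(covariates)) stop_("covariates contain missing values")

  site <- if (is.null(site)) rep("site1", n) else as.character(site)
  if (length(site) != n) stop_("site length does not match nrow(X)")
  if (anyNA(site)) stop_("site labels contain NA")

  if (is.null(family_id)) family_id <- rep(NA_character_, n)
  family_id <- as.character(family_id)
  if (length(family_id) != n) stop_("family_id length does not match nrow(X)")
  # singletons (unlabelled subjects) get their own family
  miss <- is.na(family_id)
  if (any(miss)) family_id[miss] <- paste0(".singleton_", subject_ids[miss])

  keep <- !is.na(y)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("Dropping ", n_drop, " subject(s) with missing phenotype")
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    covariates <- covariates[keep, , drop = FALSE]
    site <- site[keep]
    family_id <- family_id[keep]
    subject_ids <- subject_ids[keep]
    if (!is.null(truth) && !is.null(truth$latent)) truth$latent <- truth$latent[keep]
  }
  if (nrow(X) < 2) stop_("a connectome_dataset needs at least 2 subjects")

  rownames(covariates) <- NULL
  structure(list(subject_ids = subject_ids, X = X, y = y,
                 covariates = covariates, site = site, family_id = family_id,
                 truth = truth),
            class = "connectome_dataset")
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat("connectome_dataset:", length(x$y), "subjects x", ncol(x$X), "edges\n")
  cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  cat("  sites:", length(unique(x$site)),
      " families:", length(unique(x$family_id)),
      " (", sum(table(x$family_id) > 1), "with >1 member )\n")
  if (!is.null(x$truth))
    cat("  synthetic (effect_size =", x$truth$config$effect_size, ")\n")
  invisible(x)
}

# row subset preserving all aligned fields (internal)
dataset_rows <- function(dataset, idx) {
  truth <- dataset$truth
  if (!is.null(truth) && !is.null(truth$latent)) truth$latent <- truth$latent[idx]
  structure(list(subject_ids = dataset$subject_ids[idx],
                 X = dataset$X[idx, , drop = FALSE],
                 y = dataset$y[idx],
                 covariates = dataset$covariates[idx, , drop = FALSE],
                 site = dataset$site[idx],
                 family_id = dataset$family_id[idx],
                 truth = truth),
            class = "connectome_dataset")
}

n_subjects <- function(dataset) length(dataset$y)

#' Read a connectome dataset from delimited text files
#'
#' Loads a subject-by-edge feature table and a phenotype/covariate table and
#' joins them strictly on subject identifier. Any subject present in one file
#' but not the other is an error (silent row dropping would itself be a data
#' hygiene bug of the kind this package measures). Rows with a missing
#' phenotype value are dropped with a message.
#'
#' @param features_file delimited text, first column the subject id, remaining
#'   columns one edge feature each (header row = edge ids).
#' @param pheno_file delimited text with one row per subject, containing the
#'   id column, the phenotype column, the covariate columns and (optionally)
#'   site and family columns.
#' @param phenotype name of the phenotype column in `pheno_file`.
#' @param covariates character vector of covariate column names.
#' @param site,family optional column names for site and family labels.
#' @param id name of the subject-id column in `pheno_file` (default
#'   `"subject_id"`).
#' @param sep field separator for both files (default `","`).
#' @return A [connectome_dataset()].
#' @export
read_connectome_dataset <- function(features_file, pheno_file, phenotype,
                                    covariates, site = NULL, family = NULL,
                                    id = "subject_id", sep = ",") {
  feat <- utils::read.table(features_file, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  pheno <- utils::read.table(pheno_file, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(feat[[1]])
  for (col in c(id, phenotype, covariates, site, family))
    if (!col %in% names(pheno))
      stop_("column '", col, "' not found in ", pheno_file)
  pids <- as.character(pheno[[id]])
  only_feat <- setdiff(ids, pids)
  only_pheno <- setdiff(pids, ids)
  if (length(only_feat) || length(only_pheno))
    stop_("unmatched subject ids between feature and phenotype tables: ",
          paste(utils::head(c(only_feat, only_pheno), 5), collapse = ", "))
  pheno <- pheno[match(ids, pids), , drop = FALSE]
  connectome_dataset(
    X = as.matrix(feat[, -1, drop = FALSE]),
    y = pheno[[phenotype]],
    covariates = pheno[, covariates, drop = FALSE],
    site = if (!is.null(site)) pheno[[site]],
    family_id = if (!is.null(family)) pheno[[family]],
    subject_ids = ids)
}
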