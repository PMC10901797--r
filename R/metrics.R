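#' Pearson correlation between observed and predicted phenotype
#'
#' The primary performance metric. If either vector is constant the
#' correlation is undefined; this is surfaced as `NA` with a warning, never
#' silently reported as 0.
#'
#' @param y observed phenotype (length >= 3).
#' @param y_pred predicted phenotype.
#' @return Correlation, or `NA_real_` (with a warning) for constant input.
#' @export
pearson_r <- function(y, y_pred) {
  if (length(y) != length(y_pred)) stop_("y and y_pred lengths differ")
  if (length(y) < 3) stop_("need at least 3 observations")
  if (stats::sd(y) == 0 || stats::sd(y_pred) == 0) {
    warning("constant input: Pearson r is undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(y, y_pred)
}

#' Cross-validation R-squared (q2)
#'
#' `q2 = 1 - sum((y - y_pred)^2) / sum((y - mean(y))^2)`, where the mean is
#' taken over the observed values in the concatenated prediction vector
#' (duplicated subjects, if any, included as-is). Unlike a squared
#' correlation, q2 can be substantially negative: predictions worse than
#' predicting the mean.
#'
#' @param y observed phenotype (non-constant).
#' @param y_pred predicted phenotype.
#' @return q2 value (at most 1, unbounded below).
#' @export
q_squared <- function(y, y_pred) {
  if (length(y) != length(y_pred)) stop_("y and y_pred lengths differ")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_("q2 is undefined for a constant observed phenotype")
  1 - sum((y - y_pred)^2) / sst
}

#' Metrics on predictions concatenated across folds
#'
#' Joins per-fold observed/predicted pairs into one vector per iteration and
#' computes a single Pearson r and a single q2 -- never a mean of per-fold
#' metrics, which differs whenever fold means are shifted.
#'
#' @param fold_predictions list of folds, each a list (or data frame) with
#'   elements `observed` and `predicted`.
#' @return List with elements `r` and `q2`.
#' @export
concat_metrics <- function(fold_predictions) {
  obs <- unlist(lapply(fold_predictions, `[[`, "observed"), use.names = FALSE)
  pred <- unlist(lapply(fold_predictions, `[[`, "predicted"), use.names = FALSE)
  list(r = pearson_r(obs, pred), q2 = q_squared(obs, pred))
}

#' Fold-averaged coefficient vector of a pipeline result
#'
#' Embeds each outer fold's coefficients in the full edge space (zeros for
#' unselected edges) and averages arithmetically across folds. Identical to
#' `coef()` on the result; provided as an explicit verb for scripted
#' comparisons.
#'
#' @param result a [run_pipeline()] result.
#' @return Numeric vector of length `n_edges`.
#' @export
average_coefficients <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  rowMeans(result$coefficients)
}

#' Pearson similarity of two coefficient vectors
#'
#' Correlation over all edges between two fold-averaged coefficient vectors
#' (e.g. a leaky pipeline against the gold standard).
#'
#' @param a,b numeric coefficient vectors of equal length.
#' @return Pearson correlation.
#' @export
coefficient_similarity <- function(a, b) {
  if (length(a) != length(b)) stop_("coefficient vectors differ in length")
  pearson_r(a, b)
}

#' Size-adjusted selected-edge counts per subnetwork
#'
#' Counts how many selected edges fall in each subnetwork (unordered pair of
#' canonical networks) and divides by the subnetwork's total edge count, so
#' each entry is the fraction of that subnetwork's edges that were selected.
#' Subnetworks with no edges in the parcellation get `NA` (with a message)
#' and are excluded from downstream rank correlations.
#'
#' @param selected_edges integer indices of selected edges.
#' @param parc a [parcellation()].
#' @return Named numeric vector of length `n_networks*(n_networks+1)/2`, with
#'   attributes `raw` (unadjusted counts) and `sizes`.
#' @export
subnetwork_counts <- function(selected_edges, parc) {
  map <- edge_subnetwork_map(parc)
  nb <- attr(map, "n_subnetworks")
  labels <- attr(map, "labels")
  sizes <- tabulate(map, nbins = nb)
  raw <- tabulate(map[selected_edges], nbins = nb)
  adj <- ifelse(sizes > 0, raw / sizes, NA_real_)
  if (any(sizes == 0))
    message(sum(sizes == 0),
            " empty subnetwork(s) excluded (no edges in parcellation)")
  structure(stats::setNames(adj, labels), raw = stats::setNames(raw, labels),
            sizes = sizes)
}

#' Spearman rank similarity of subnetwork profiles
#'
#' Spearman correlation (average ranks for ties) between two size-adjusted
#' subnetwork count vectors; entries that are `NA` in either profile (empty
#' subnetworks) are dropped pairwise.
#'
#' @param counts_a,counts_b vectors from [subnetwork_counts()].
#' @return Spearman correlation.
#' @export
subnetwork_rank_similarity <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b))
    stop_("subnetwork count vectors differ in length")
  ok <- is.finite(counts_a) & is.finite(counts_b)
  if (sum(ok) < 3) stop_("fewer than 3 comparable subnetworks")
  stats::cor(counts_a[ok], counts_b[ok], method = "spearman")
}
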