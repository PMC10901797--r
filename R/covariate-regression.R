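#' Fit a covariate-regression (confound residualization) model
#'
#' Estimates per-edge ordinary-least-squares loadings of the feature matrix
#' on the covariates, `beta_hat = (C'C)^{-1} C' X`, where `C` is the covariate
#' matrix with an intercept column prepended internally. The solve uses a QR
#' decomposition, not an explicit inverse. In the non-leaky pipeline this is
#' fit on the training rows only and then applied to both partitions; fitting
#' it on the full dataset is the leaky variant ([leaky_covariates()]).
#'
#' @param X numeric matrix, subjects x edges.
#' @param covariates data frame or matrix of raw covariates (no intercept);
#'   column names are recorded and enforced at apply time.
#' @return An object of class `covariate_model` with elements `beta_hat`
#'   (`(k+1) x p`, intercept row first) and `covariate_names`.
#' @seealso [apply_covariates()], [leaky_covariates()]
#' @export
fit_covariates <- function(X, covariates) {
  X <- as.matrix(X)
  C <- build_design(covariates)
  if (nrow(C) != nrow(X)) stop_("covariates and X row counts differ")
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    bad <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    stop_("covariate matrix is rank deficient; collinear column(s): ",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrC, X)
  structure(list(beta_hat = beta,
                 covariate_names = colnames(C)[-1]),
            class = "covariate_model")
}

#' Residualize features using a fitted covariate model
#'
#' Computes `X - C %*% beta_hat` with the training-estimated loadings. The
#' covariate columns must match the fit-time names and order exactly; silent
#' reordering is refused.
#'
#' @param model a [fit_covariates()] result.
#' @param X feature matrix to adjust.
#' @param covariates covariates for the rows of `X` (same columns as at fit).
#' @return Adjusted matrix, same shape as `X`.
#' @export
apply_covariates <- function(model, X, covariates) {
  stopifnot(inherits(model, "covariate_model"))
  X <- as.matrix(X)
  C <- build_design(covariates)
  if (!identical(colnames(C)[-1], model$covariate_names))
    stop_("covariate columns (", paste(colnames(C)[-1], collapse = ", "),
          ") do not match the fitted model (",
          paste(model$covariate_names, collapse = ", "),
          "); reorder or rename explicitly")
  if (nrow(C) != nrow(X)) stop_("covariates and X row counts differ")
  out <- X - C %*% model$beta_hat
  dimnames(out) <- dimnames(X)
  out
}

#' Full-data (leaky) covariate regression
#'
#' Exactly [fit_covariates()] followed by [apply_covariates()] on the same
#' data. Provided as a distinct entry point so pipelines that residualize on
#' the combined training and test data declare the leakage explicitly.
#'
#' @inheritParams fit_covariates
#' @return Adjusted matrix.
#' @export
leaky_covariates <- function(X, covariates) {
  apply_covariates(fit_covariates(X, covariates), X, covariates)
}

# prepend the intercept column; validate numeric covariates
build_design <- function(covariates) {
  covariates <- as.data.frame(covariates)
  C <- as.matrix(covariates)
  if (ncol(C) == 0) C <- matrix(numeric(0), nrow(covariates), 0)
  if (!is.numeric(C)) stop_("covariates must be numeric")
  if (anyNA(C)) stop_("covariates contain missing values")
  if (is.null(colnames(C)) && ncol(C) > 0)
    colnames(C) <- paste0("c", seq_len(ncol(C)))
  cbind("(intercept)" = 1, C)
}
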