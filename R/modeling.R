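#' Model specification
#'
#' Declarative description of the predictive model used inside each outer
#' fold: the model family, its hyperparameter grid, the nested fold count for
#' the grid search, and the fraction of edges kept by univariate feature
#' selection.
#'
#' @param kind `"ridge"` (L2-penalized linear regression with a nested grid
#'   search over `alpha_grid`), `"cpm"` (connectome-based predictive
#'   modeling: signed edge sums and a univariate line), or `"svr"`
#'   (radial-basis support vector regression with a nested grid over
#'   `c_grid`; delegates to \pkg{e1071}).
#' @param alpha_grid ridge penalty grid, default `10^(-3:3)`.
#' @param c_grid SVR cost grid, default `10^(-3:3)` (`C` is inversely
#'   proportional to regularization strength).
#' @param inner_k nested fold count for hyperparameter selection, default 5.
#' @param feature_fraction fraction of edges retained by selection, default
#'   0.05 (the conventional "top 5%").
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("ridge", "cpm", "svr"),
                       alpha_grid = 10^(-3:3), c_grid = 10^(-3:3),
                       inner_k = 5, feature_fraction = 0.05) {
  kind <- match.arg(kind)
  if (length(alpha_grid) < 1 || any(alpha_grid <= 0))
    stop_("alpha_grid must be non-empty and strictly positive")
  if (length(c_grid) < 1 || any(c_grid <= 0))
    stop_("c_grid must be non-empty and strictly positive")
  if (feature_fraction <= 0 || feature_fraction > 1)
    stop_("feature_fraction must lie in (0, 1]")
  structure(list(kind = kind, alpha_grid = sort(alpha_grid),
                 c_grid = sort(c_grid), inner_k = as.integer(inner_k),
                 feature_fraction = feature_fraction),
            class = "model_spec")
}

#' Univariate feature selection by phenotype correlation
#'
#' Keeps the `max(1, floor(fraction * p))` edges with the largest absolute
#' Pearson correlation with the phenotype (for fixed `n`, ranking by p-value
#' is equivalent to ranking by `|r|`). Ties break toward the smallest edge
#' index; a zero-variance edge has its correlation defined as 0 and is never
#' selected unless every edge is zero-variance.
#'
#' @param X feature matrix (training rows only, in a non-leaky pipeline).
#' @param y phenotype vector.
#' @param fraction fraction of edges to keep, in `(0, 1]`.
#' @return Sorted integer vector of selected edge indices.
#' @export
select_features <- function(X, y, fraction = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop_("feature selection needs at least 3 subjects")
  if (fraction <= 0 || fraction > 1) stop_("fraction must lie in (0, 1]")
  k <- max(1L, floor(fraction * p))
  r <- edge_correlations(X, y)
  ord <- order(-abs(r), seq_len(p))
  sort(ord[seq_len(k)])
}

# per-edge Pearson correlation with y; zero-variance edges get r = 0
edge_correlations <- function(X, y) {
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  num <- as.numeric(crossprod(X, yc))
  ssx <- colSums(X^2) - nrow(X) * colMeans(X)^2
  ssx[ssx < 0] <- 0
  den <- sqrt(ssx) * sy
  r <- ifelse(den > 0, num / den, 0)
  r[!is.finite(r)] <- 0
  r
}

# closed-form ridge (intercept unpenalized) for a whole penalty grid via one
# SVD of the centered design; returns list(coef matrix p_sel x n_alpha,
# intercepts)
ridge_path <- function(X, y, alphas) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  sv <- svd(Xc)
  uty <- as.numeric(crossprod(sv$u, y - ym))
  d <- sv$d
  B <- vapply(alphas, function(a)
    as.numeric(sv$v %*% (d * uty / (d^2 + a))), numeric(ncol(X)))
  B <- matrix(B, ncol = length(alphas))
  b0 <- ym - as.numeric(crossprod(xm, B))
  list(coef = B, intercept = b0)
}

#' Fit ridge regression with nested hyperparameter selection
#'
#' Inside the training partition: `inner_k`-fold plain splits; within each
#' inner-training partition the edges are re-selected and ridge fit at every
#' grid penalty; per penalty the inner-fold predictions are concatenated and
#' one Pearson r computed; the winning penalty maximizes that r (ties go to
#' the largest penalty, i.e. the strongest regularization). The final model
#' re-selects edges on the full training partition and refits at the winner.
#'
#' Feature re-selection inside each inner partition keeps selection from
#' leaking into the hyperparameter choice. When `fixed_features` is supplied
#' (the leaky-selection pipeline) no selection is performed anywhere and the
#' given edge set is used throughout.
#'
#' @param X,y training features and phenotype.
#' @param spec a [model_spec()] with `kind = "ridge"`.
#' @param seed seed for the inner splits.
#' @param fixed_features optional pre-chosen edge index set.
#' @return An object of class `c("ridge_model", "connectome_model")` with
#'   `selected_edges`, `coefficients`, `intercept`, `chosen_alpha`,
#'   `inner_r` (per-grid-value nested performance) and `n_edges`.
#' @export
fit_ridge_nested <- function(X, y, spec = model_spec(), seed = 1,
                             fixed_features = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= spec$inner_k)
    stop_("need more training rows (", n, ") than inner folds (",
          spec$inner_k, ")")
  grid <- spec$alpha_grid
  folds <- plain_kfold(n, spec$inner_k, seed)
  preds <- matrix(NA_real_, n, length(grid))
  for (f in folds) {
    tr <- setdiff(seq_len(n), f)
    sel <- fixed_features %||%
      select_features(X[tr, , drop = FALSE], y[tr], spec$feature_fraction)
    fit <- ridge_path(X[tr, sel, drop = FALSE], y[tr], grid)
    preds[f, ] <- sweep(X[f, sel, drop = FALSE] %*% fit$coef, 2,
                        fit$intercept, "+")
  }
  inner_r <- apply(preds, 2, function(p) {
    if (stats::sd(p) == 0) -Inf else stats::cor(y, p)
  })
  # ties (and -Inf degeneracies) resolve toward the largest penalty
  winner <- grid[utils::tail(order(inner_r, grid), 1)]
  sel <- fixed_features %||% select_features(X, y, spec$feature_fraction)
  fit <- ridge_path(X[, sel, drop = FALSE], y, winner)
  structure(list(kind = "ridge", selected_edges = sel,
                 coefficients = as.numeric(fit$coef),
                 intercept = fit$intercept, chosen_alpha = winner,
                 inner_r = stats::setNames(inner_r, grid),
                 n_edges = ncol(X)),
            class = c("ridge_model", "connectome_model"))
}

#' Fit a connectome-based predictive model (CPM)
#'
#' Selects edges as in [select_features()], splits them by the sign of their
#' training correlation with the phenotype, collapses each subject to a
#' single score `sum(positive edges) - sum(negative edges)`, and fits a
#' univariate OLS line of the phenotype on that score. Edges with exactly
#' zero correlation contribute to neither sum; an absent sign contributes 0.
#'
#' @param X,y training features and phenotype.
#' @param spec a [model_spec()].
#' @param seed unused (CPM has no nested search); kept for the common fitting
#'   interface.
#' @param fixed_features optional pre-chosen edge index set (leaky
#'   selection); signs are still derived from the training rows.
#' @return An object of class `c("cpm_model", "connectome_model")` with
#'   `selected_edges`, `cpm_signs` (+1/-1 per selected edge), `slope`,
#'   `intercept`, `n_edges`.
#' @export
fit_cpm <- function(X, y, spec = model_spec(kind = "cpm"), seed = NULL,
                    fixed_features = NULL) {
  X <- as.matrix(X)
  sel <- fixed_features %||% select_features(X, y, spec$feature_fraction)
  r <- edge_correlations(X[, sel, drop = FALSE], y)
  signs <- sign(r)
  score <- cpm_score(X, sel, signs)
  if (stats::sd(score) == 0)
    stop_("CPM summary score has zero variance; cannot fit the univariate line")
  slope <- stats::cov(score, y) / stats::var(score)
  structure(list(kind = "cpm", selected_edges = sel, cpm_signs = signs,
                 slope = slope, intercept = mean(y) - slope * mean(score),
                 n_edges = ncol(X)),
            class = c("cpm_model", "connectome_model"))
}

cpm_score <- function(X, sel, signs) {
  as.numeric(X[, sel, drop = FALSE] %*% signs)
}

#' Fit radial-basis support vector regression with nested cost selection
#'
#' Same nested protocol as [fit_ridge_nested()] but the grid runs over the
#' SVR cost `C` (inversely proportional to regularization strength); the
#' kernel machine itself is \pkg{e1071}'s `svm`. Carries no edge
#' coefficients.
#'
#' @inheritParams fit_ridge_nested
#' @return An object of class `c("svr_model", "connectome_model")`.
#' @export
fit_svr_nested <- function(X, y, spec = model_spec(kind = "svr"), seed = 1,
                           fixed_features = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= spec$inner_k)
    stop_("need more training rows than inner folds")
  grid <- spec$c_grid
  folds <- plain_kfold(n, spec$inner_k, seed)
  preds <- matrix(NA_real_, n, length(grid))
  for (f in folds) {
    tr <- setdiff(seq_len(n), f)
    sel <- fixed_features %||%
      select_features(X[tr, , drop = FALSE], y[tr], spec$feature_fraction)
    for (ci in seq_along(grid)) {
      m <- e1071::svm(X[tr, sel, drop = FALSE], y[tr], kernel = "radial",
                      cost = grid[ci], type = "eps-regression")
      preds[f, ci] <- stats::predict(m, X[f, sel, drop = FALSE])
    }
  }
  inner_r <- apply(preds, 2, function(p) {
    if (stats::sd(p) == 0) -Inf else stats::cor(y, p)
  })
  winner <- grid[utils::tail(order(inner_r, grid), 1)]
  sel <- fixed_features %||% select_features(X, y, spec$feature_fraction)
  fit <- e1071::svm(X[, sel, drop = FALSE], y, kernel = "radial",
                    cost = winner, type = "eps-regression")
  structure(list(kind = "svr", selected_edges = sel, svm_fit = fit,
                 chosen_alpha = winner, inner_r = stats::setNames(inner_r, grid),
                 n_edges = ncol(X)),
            class = c("svr_model", "connectome_model"))
}

#' Fit the model named by a model_spec
#'
#' Dispatch wrapper used by the pipeline orchestrator; all fitting functions
#' see only the rows handed to them, so any leakage is the caller's explicit
#' decision.
#'
#' @inheritParams fit_ridge_nested
#' @return A fitted `connectome_model`.
#' @export
fit_model <- function(X, y, spec = model_spec(), seed = 1,
                      fixed_features = NULL) {
  switch(spec$kind,
         ridge = fit_ridge_nested(X, y, spec, seed, fixed_features),
         cpm = fit_cpm(X, y, spec, seed, fixed_features),
         svr = fit_svr_nested(X, y, spec, seed, fixed_features))
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_edges)
    stop_("newdata has ", ncol(newdata), " edges; model expects ",
          object$n_edges)
  as.numeric(newdata[, object$selected_edges, drop = FALSE] %*%
               object$coefficients) + object$intercept
}

#' @export
predict.cpm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_edges)
    stop_("newdata has ", ncol(newdata), " edges; model expects ",
          object$n_edges)
  object$intercept + object$slope *
    cpm_score(newdata, object$selected_edges, object$cpm_signs)
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_edges)
    stop_("newdata has ", ncol(newdata), " edges; model expects ",
          object$n_edges)
  as.numeric(stats::predict(object$svm_fit,
                            newdata[, object$selected_edges, drop = FALSE]))
}

#' Coefficients of a fitted model embedded in the full edge space
#'
#' Unselected edges get weight zero, so coefficient vectors from pipelines
#' that selected different edges remain directly comparable. For CPM the
#' per-edge "coefficient" is its +/-1 sign times the univariate slope (a
#' convention; CPM is not an edge-linear model). SVR has no edge
#' coefficients: a vector of `NA` is returned.
#'
#' @param object a fitted `connectome_model`.
#' @param ... unused.
#' @return Numeric vector of length `n_edges`.
#' @export
coef.connectome_model <- function(object, ...) {
  full <- rep(0, object$n_edges)
  if (object$kind == "ridge") {
    full[object$selected_edges] <- object$coefficients
  } else if (object$kind == "cpm") {
    full[object$selected_edges] <- object$cpm_signs * object$slope
  } else {
    full[] <- NA_real_
  }
  full
}
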