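#' Fit a ComBat site-harmonization model
#'
#' Location/scale harmonization of multi-site features: per feature `v` and
#' site `i` the model removes an additive effect `gamma[i,v]` and a
#' multiplicative effect `delta[i,v]`, estimated on data standardized by the
#' per-feature grand mean `alpha[v]` and pooled SD. With `eb = TRUE`
#' (default) the site parameters are shrunk across features by parametric
#' empirical Bayes (normal prior for the location effects, inverse-gamma,
#' moment-matched, for the scale effects), the standard ComBat estimator;
#' with `eb = FALSE` the raw per-site estimates are used, which makes the
#' correction exactly idempotent and per-site means exactly equal after
#' adjustment.
#'
#' In the non-leaky pipeline this is fit on training rows only and the frozen
#' parameters are applied to the test rows ([apply_combat()]); fitting on the
#' full dataset is the leaky variant ([leaky_combat()]).
#'
#' Internal variance conventions (divide-by-`n` site scale, divide-by-`N`
#' pooled variance) are chosen to be mutually consistent so that applying the
#' eb-off correction twice equals applying it once.
#'
#' @param X numeric matrix, subjects x features.
#' @param site site label per row; every site needs at least 2 subjects.
#' @param eb logical, empirical-Bayes shrinkage of site parameters.
#' @return An object of class `combat_model`: `alpha_hat` (per-feature grand
#'   mean), `pooled_sd`, `gamma_star` and `delta_star` (site x feature, on
#'   the standardized scale), `known_sites`, `eb`.
#' @export
fit_combat <- function(X, site, eb = TRUE) {
  X <- as.matrix(X)
  site <- as.character(site)
  if (length(site) != nrow(X)) stop_("site length must match nrow(X)")
  counts <- table(site)
  if (any(counts < 2))
    stop_("site(s) with a single subject in the training data: ",
          paste(names(counts)[counts < 2], collapse = ", "),
          " (scale effect undefined)")
  sites <- names(counts)
  n_i <- as.numeric(counts)
  N <- nrow(X)

  site_means <- rowsum(X, site) / n_i            # sites x p, rowsum is sorted
  alpha <- colMeans(X)
  resid <- X - site_means[site, , drop = FALSE]
  var_pooled <- colMeans(resid^2)                 # 1/N
  if (any(var_pooled <= 0))
    stop_("feature(s) with zero pooled within-site variance: ",
          paste(utils::head(which(var_pooled <= 0), 5), collapse = ", "))
  pooled_sd <- sqrt(var_pooled)

  Z <- sweep(sweep(X, 2, alpha), 2, pooled_sd, "/")
  gamma_hat <- rowsum(Z, site) / n_i
  delta2_hat <- rowsum((Z - gamma_hat[site, , drop = FALSE])^2, site) / n_i
  if (any(delta2_hat <= 0))
    stop_("site/feature combination with zero scale; cannot harmonize")

  if (eb && ncol(X) >= 3) {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    for (k in seq_along(sites)) {
      g <- gamma_hat[k, ]; d2 <- delta2_hat[k, ]
      g_bar <- mean(g); t2 <- stats::var(g)
      m <- mean(d2); s2 <- stats::var(d2)
      if (!is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0) next
      lambda <- (2 * s2 + m^2) / s2               # inverse-gamma shape
      theta <- (m * s2 + m^3) / s2                # inverse-gamma scale
      g_st <- g; d2_st <- d2
      for (iter in 1:100) {
        g_new <- (n_i[k] * t2 * g + d2_st * g_bar) / (n_i[k] * t2 + d2_st)
        sse <- n_i[k] * d2 + n_i[k] * (g - g_new)^2
        d2_new <- (theta + 0.5 * sse) / (n_i[k] / 2 + lambda - 1)
        conv <- max(abs(g_new - g_st) / (abs(g_st) + 1e-12),
                    abs(d2_new - d2_st) / (abs(d2_st) + 1e-12))
        g_st <- g_new; d2_st <- d2_new
        if (conv < 1e-6) break
      }
      gamma_star[k, ] <- g_st
      delta2_star[k, ] <- d2_st
    }
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
  }

  structure(list(alpha_hat = alpha, pooled_sd = pooled_sd,
                 gamma_star = gamma_star, delta_star = sqrt(delta2_star),
                 known_sites = sites, eb = eb),
            class = "combat_model")
}

#' Apply a fitted ComBat model
#'
#' Adjusts each row with its own site's frozen parameters:
#' `x_adj = pooled_sd * (z - gamma_star) / delta_star + alpha_hat`, where
#' `z = (x - alpha_hat) / pooled_sd`. Rows from a site unseen at fit time are
#' an error: cross-validated ComBat cannot harmonize sites it has no
#' parameters for.
#'
#' @param model a [fit_combat()] result.
#' @param X feature matrix to adjust (training-data feature dimensionality).
#' @param site site label per row of `X`.
#' @return Adjusted matrix, same shape as `X`.
#' @export
apply_combat <- function(model, X, site) {
  stopifnot(inherits(model, "combat_model"))
  X <- as.matrix(X)
  site <- as.character(site)
  if (length(site) != nrow(X)) stop_("site length must match nrow(X)")
  if (ncol(X) != length(model$alpha_hat))
    stop_("feature count differs from the fitted model")
  unseen <- setdiff(unique(site), model$known_sites)
  if (length(unseen))
    stop_("site(s) not seen when fitting ComBat: ",
          paste(unseen, collapse = ", "))
  k <- match(site, model$known_sites)
  Z <- sweep(sweep(X, 2, model$alpha_hat), 2, model$pooled_sd, "/")
  Zadj <- (Z - model$gamma_star[k, , drop = FALSE]) /
    model$delta_star[k, , drop = FALSE]
  out <- sweep(sweep(Zadj, 2, model$pooled_sd, "*"), 2, model$alpha_hat, "+")
  dimnames(out) <- dimnames(X)
  out
}

#' Full-data (leaky) ComBat
#'
#' Exactly [fit_combat()] followed by [apply_combat()] on the same data:
#' site parameters are estimated on the combined training and test rows,
#' which is the leaky practice the benchmark measures.
#'
#' @inheritParams fit_combat
#' @return Adjusted matrix.
#' @export
leaky_combat <- function(X, site, eb = TRUE) {
  apply_combat(fit_combat(X, site, eb = eb), X, site)
}
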