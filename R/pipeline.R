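#' Pipeline specification
#'
#' Declares, stage by stage, whether each step of a connectome prediction
#' pipeline is performed correctly inside the cross-validation folds (`"cv"`),
#' leakily on the combined training and test data (`"leaky"`), or omitted
#' (`"none"`), together with the splitting rule and the amount of injected
#' subject duplication. The gold standard is
#' `pipeline_spec()` with all defaults: cv site correction, cv covariate
#' regression, cv feature selection, family-aware splits, no duplicated
#' subjects.
#'
#' @param site_correction `"cv"`, `"leaky"` or `"none"` -- ComBat site
#'   harmonization.
#' @param covariate_regression `"cv"`, `"leaky"` or `"none"` -- confound
#'   residualization of the features.
#' @param feature_selection `"cv"` (re-selected within each training
#'   partition) or `"leaky"` (one edge set chosen on the full raw data).
#' @param split `"family_aware"` (families never straddle folds) or `"plain"`
#'   (families ignored -- which *is* family leakage whenever multi-member
#'   families exist).
#' @param subject_leakage_pct percentage of subjects duplicated before
#'   splitting, in `[0, 100]`.
#' @param outer_k outer fold count (default 5; 20 for twin-style analyses).
#' @param covariate_exclusions covariate names excluded from the design
#'   (e.g. `"age"` when the phenotype being predicted is age itself).
#' @param combat_eb logical, empirical-Bayes shrinkage inside ComBat.
#' @return An object of class `pipeline_spec`.
#' @seealso [run_pipeline()], [pipeline_variants()]
#' @export
pipeline_spec <- function(site_correction = c("cv", "leaky", "none"),
                          covariate_regression = c("cv", "leaky", "none"),
                          feature_selection = c("cv", "leaky"),
                          split = c("family_aware", "plain"),
                          subject_leakage_pct = 0,
                          outer_k = 5,
                          covariate_exclusions = character(),
                          combat_eb = TRUE) {
  spec <- list(site_correction = match.arg(site_correction),
               covariate_regression = match.arg(covariate_regression),
               feature_selection = match.arg(feature_selection),
               split = match.arg(split),
               subject_leakage_pct = subject_leakage_pct,
               outer_k = as.integer(outer_k),
               covariate_exclusions = as.character(covariate_exclusions),
               combat_eb = isTRUE(combat_eb))
  if (spec$subject_leakage_pct < 0 || spec$subject_leakage_pct > 100)
    stop_("subject_leakage_pct must lie in [0, 100]")
  if (spec$outer_k < 2) stop_("outer_k must be at least 2")
  structure(spec, class = "pipeline_spec")
}

#' @rdname pipeline_spec
#' @param ... arguments forwarded to [pipeline_spec()] (e.g. `outer_k`,
#'   `covariate_exclusions`).
#' @export
gold_standard_spec <- function(...) pipeline_spec(...)

#' @export
print.pipeline_spec <- function(x, ...) {
  cat("pipeline_spec: site =", x$site_correction,
      "| covariates =", x$covariate_regression,
      "| selection =", x$feature_selection,
      "| split =", x$split,
      "| subject leakage =", paste0(x$subject_leakage_pct, "%"),
      "| outer k =", x$outer_k, "\n")
  if (length(x$covariate_exclusions))
    cat("  excluded covariates:",
        paste(x$covariate_exclusions, collapse = ", "), "\n")
  invisible(x)
}

#' The 11 benchmark pipeline variants
#'
#' The gold standard, the three non-leaky analysis alternatives (omitting
#' covariate regression, site correction, or both), and the leaky variants:
#' leaky feature selection, leaky site correction, leaky covariate
#' regression, family leakage (plain splits), and subject leakage at 5, 10
#' and 20 percent.
#'
#' @param ... arguments forwarded to every [pipeline_spec()] (e.g. `outer_k`,
#'   `covariate_exclusions`, `combat_eb`).
#' @return Named list of [pipeline_spec()] objects.
#' @export
pipeline_variants <- function(...) {
  list(
    gold_standard = pipeline_spec(...),
    no_covariate_regression = pipeline_spec(covariate_regression = "none", ...),
    no_site_correction = pipeline_spec(site_correction = "none", ...),
    no_covariates_no_site = pipeline_spec(covariate_regression = "none",
                                          site_correction = "none", ...),
    leaky_feature_selection = pipeline_spec(feature_selection = "leaky", ...),
    leaky_site_correction = pipeline_spec(site_correction = "leaky", ...),
    leaky_covariate_regression = pipeline_spec(covariate_regression = "leaky", ...),
    family_leakage = pipeline_spec(split = "plain", ...),
    subject_leakage_5 = pipeline_spec(subject_leakage_pct = 5, ...),
    subject_leakage_10 = pipeline_spec(subject_leakage_pct = 10, ...),
    subject_leakage_20 = pipeline_spec(subject_leakage_pct = 20, ...))
}

#' Run one prediction pipeline
#'
#' Executes a [pipeline_spec()] end to end on a dataset and returns the
#' concatenated test predictions and performance. Execution order: (1)
#' subject duplication, if requested; (2) any stage marked `"leaky"` applied
#' once to the full dataset (ComBat, then covariate regression; leaky feature
#' selection fixes the edge set on the full *raw* features and phenotype);
#' (3) the outer split; (4) per fold, cv-mode ComBat then covariate
#' regression are fit on the training rows and applied to both partitions,
#' the model is fit on the adjusted training rows (selecting edges itself
#' unless the set was fixed leakily) and predicts the test fold; (5)
#' predictions are concatenated across folds and scored once with Pearson's
#' r and q-squared.
#'
#' @param dataset a [connectome_dataset()].
#' @param spec a [pipeline_spec()].
#' @param model a [model_spec()].
#' @param seed seed controlling the outer split, the nested splits and any
#'   duplication resampling.
#' @return An object of class `pipeline_result`: `predictions` (aligned to
#'   the possibly augmented subject order), `observed`, `r`, `q2`, `folds`,
#'   per-fold `selected_edges`, `coefficients` (full-edge-length matrix, one
#'   column per outer fold), `chosen_alpha`, and provenance (`spec`, `model`,
#'   `seed`).
#' @export
run_pipeline <- function(dataset, spec = pipeline_spec(),
                         model = model_spec(), seed = 1) {
  stopifnot(inherits(dataset, "connectome_dataset"),
            inherits(spec, "pipeline_spec"), inherits(model, "model_spec"))
  if (spec$subject_leakage_pct > 0)
    dataset <- inject_subject_leakage(dataset, spec$subject_leakage_pct,
                                      seed = seed + 104729L)
  n <- n_subjects(dataset)
  covs <- dataset$covariates
  if (length(spec$covariate_exclusions))
    covs <- covs[, setdiff(colnames(covs), spec$covariate_exclusions),
                 drop = FALSE]

  X <- dataset$X
  if (spec$site_correction == "leaky")
    X <- leaky_combat(X, dataset$site, eb = spec$combat_eb)
  if (spec$covariate_regression == "leaky")
    X <- leaky_covariates(X, covs)
  fixed <- NULL
  if (spec$feature_selection == "leaky")
    fixed <- select_features(dataset$X, dataset$y, model$feature_fraction)

  folds <- if (spec$split == "family_aware")
    family_kfold(dataset$family_id, spec$outer_k, seed)
  else
    plain_kfold(n, spec$outer_k, seed)

  p <- ncol(X)
  preds <- rep(NA_real_, n)
  coefs <- matrix(NA_real_, p, length(folds))
  sel_list <- vector("list", length(folds))
  alphas <- rep(NA_real_, length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(n), te)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (spec$site_correction == "cv") {
      cm <- fit_combat(Xtr, dataset$site[tr], eb = spec$combat_eb)
      Xtr <- apply_combat(cm, Xtr, dataset$site[tr])
      Xte <- apply_combat(cm, Xte, dataset$site[te])
    }
    if (spec$covariate_regression == "cv") {
      vm <- fit_covariates(Xtr, covs[tr, , drop = FALSE])
      Xtr <- apply_covariates(vm, Xtr, covs[tr, , drop = FALSE])
      Xte <- apply_covariates(vm, Xte, covs[te, , drop = FALSE])
    }
    fit <- fit_model(Xtr, dataset$y[tr], model, seed = seed + f,
                     fixed_features = fixed)
    preds[te] <- predict(fit, Xte)
    coefs[, f] <- coef(fit)
    sel_list[[f]] <- fit$selected_edges
    alphas[f] <- fit$chosen_alpha %||% NA_real_
  }
  stopifnot(!anyNA(preds))  # every subject predicted exactly once

  structure(list(predictions = preds, observed = dataset$y,
                 r = pearson_r(dataset$y, preds),
                 q2 = q_squared(dataset$y, preds),
                 folds = folds, selected_edges = sel_list,
                 coefficients = coefs, chosen_alpha = alphas,
                 spec = spec, model = model, seed = seed, n = n),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: n = %d, k = %d folds, r = %.3f, q2 = %.3f\n",
              x$n, length(x$folds), x$r, x$q2))
  print(x$spec)
  invisible(x)
}

#' @export
summary.pipeline_result <- function(object, ...) {
  cat(sprintf("Prediction over %d subjects (%d folds)\n",
              object$n, length(object$folds)))
  cat(sprintf("  Pearson r : %.4f\n  q2        : %.4f\n",
              object$r, object$q2))
  cat("  edges selected per fold:",
      paste(lengths(object$selected_edges), collapse = ", "), "\n")
  if (!all(is.na(object$chosen_alpha)))
    cat("  chosen penalty per fold:",
        paste(signif(object$chosen_alpha, 3), collapse = ", "), "\n")
  invisible(object)
}

#' Fold-averaged model coefficients of a pipeline run
#'
#' Per-fold coefficient vectors (already embedded in the full edge space,
#' zeros outside each fold's selected edges) averaged arithmetically over the
#' outer folds -- the coefficient summary used for comparing leaky and
#' non-leaky pipelines.
#'
#' @param object a [run_pipeline()] result.
#' @param ... unused.
#' @return Numeric vector of length `n_edges`.
#' @export
coef.pipeline_result <- function(object, ...) {
  rowMeans(object$coefficients)
}

#' Run several pipeline variants on the same split seed
#'
#' Runs each spec with the identical seed so fold assignments coincide
#' wherever the specs' splitting rules allow, isolating the leakage effect
#' from split noise.
#'
#' @param dataset a [connectome_dataset()].
#' @param specs named list of [pipeline_spec()]s (default all 11 variants).
#' @param model a [model_spec()].
#' @param seed shared split seed.
#' @return A data frame with one row per pipeline (`pipeline`, `r`, `q2`,
#'   `delta_r`, `delta_q2` relative to the first spec) carrying the full
#'   [run_pipeline()] results as attribute `"results"`.
#' @export
run_benchmark <- function(dataset, specs = pipeline_variants(),
                          model = model_spec(), seed = 1) {
  stopifnot(is.list(specs), length(specs) >= 1)
  if (is.null(names(specs)) || any(names(specs) == ""))
    stop_("specs must be a named list")
  results <- lapply(specs, function(s) run_pipeline(dataset, s, model, seed))
  r <- vapply(results, `[[`, numeric(1), "r")
  q2 <- vapply(results, `[[`, numeric(1), "q2")
  out <- data.frame(pipeline = names(specs), r = r, q2 = q2,
                    delta_r = r - r[1], delta_q2 = q2 - q2[1],
                    row.names = NULL)
  attr(out, "results") <- results
  out
}
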