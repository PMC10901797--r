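#' Repeat a pipeline over many cross-validation seeds
#'
#' Runs the same pipeline with split seeds `base_seed + 0, 1, ...` and
#' summarizes by the median -- the convention for reporting connectome
#' prediction performance, since a single k-fold split is noisy.
#'
#' @param dataset a [connectome_dataset()].
#' @param spec a [pipeline_spec()].
#' @param model a [model_spec()].
#' @param n_iters number of k-fold iterations.
#' @param base_seed seed of the first iteration.
#' @param keep_results keep the full [run_pipeline()] objects (default TRUE;
#'   set FALSE to save memory in large sweeps).
#' @return An object of class `pipeline_iterations`: vectors `r` and `q2`
#'   (one entry per iteration), `median_r`, `median_q2`, and `results`
#'   (list, possibly empty).
#' @export
run_iterations <- function(dataset, spec = pipeline_spec(),
                           model = model_spec(), n_iters = 10,
                           base_seed = 1, keep_results = TRUE) {
  seeds <- base_seed + seq_len(n_iters) - 1L
  results <- lapply(seeds, function(s) run_pipeline(dataset, spec, model, s))
  r <- vapply(results, `[[`, numeric(1), "r")
  q2 <- vapply(results, `[[`, numeric(1), "q2")
  structure(list(r = r, q2 = q2,
                 median_r = stats::median(r), median_q2 = stats::median(q2),
                 seeds = seeds, spec = spec,
                 results = if (keep_results) results else list()),
            class = "pipeline_iterations")
}

#' @export
print.pipeline_iterations <- function(x, ...) {
  cat(sprintf("pipeline_iterations: %d iterations, median r = %.3f, median q2 = %.3f\n",
              length(x$r), x$median_r, x$median_q2))
  invisible(x)
}

#' Performance difference between a leaky pipeline and the gold standard
#'
#' Runs both pipelines with the same split seed (fold assignments coincide
#' wherever the two splitting rules agree) and returns
#' `delta_r = r_leaky - r_gold` and `delta_q2 = q2_leaky - q2_gold`, the
#' paired quantities that isolate the leakage effect from split noise.
#'
#' @param dataset a [connectome_dataset()].
#' @param leaky_spec the pipeline under test.
#' @param model a [model_spec()].
#' @param seed shared split seed.
#' @param gold_spec the reference pipeline; defaults to the gold standard
#'   with the same `outer_k`, covariate exclusions and ComBat mode as
#'   `leaky_spec`.
#' @return List with `delta_r`, `delta_q2`, and the two full results
#'   (`leaky`, `gold`).
#' @export
delta_vs_gold <- function(dataset, leaky_spec, model = model_spec(),
                          seed = 1, gold_spec = NULL) {
  if (is.null(gold_spec))
    gold_spec <- pipeline_spec(
      outer_k = leaky_spec$outer_k,
      covariate_exclusions = leaky_spec$covariate_exclusions,
      combat_eb = leaky_spec$combat_eb)
  leaky <- run_pipeline(dataset, leaky_spec, model, seed)
  gold <- run_pipeline(dataset, gold_spec, model, seed)
  list(delta_r = leaky$r - gold$r, delta_q2 = leaky$q2 - gold$q2,
       leaky = leaky, gold = gold)
}

# draw families in random order, adding whole families while the subject
# count stays <= n_target; returns subject indices
resample_families <- function(dataset, n_target, seed) {
  fams <- split(seq_len(n_subjects(dataset)), dataset$family_id)
  if (max(lengths(fams)) > n_target)
    stop_("target size ", n_target, " is smaller than the largest family (",
          max(lengths(fams)), ")")
  fams <- with_seed(seed, sample(fams))
  total <- 0L
  take <- logical(length(fams))
  for (i in seq_along(fams)) {
    sz <- length(fams[[i]])
    if (total + sz <= n_target) {
      take[i] <- TRUE
      total <- total + sz
    }
  }
  sort(unlist(fams[take], use.names = FALSE))
}

#' Leakage effects across subsampled dataset sizes
#'
#' For each target size, draws `n_resamples` family-respecting subsamples
#' (families added in random order while the subject count stays at or below
#' the target -- the actual count is recorded), and for each subsample and
#' iteration computes the paired `delta_r` of every leaky spec against the
#' gold standard. Optionally restricts to sufficiently large sites first, so
#' per-fold ComBat never meets a nearly-empty site after subsampling.
#'
#' @param dataset a [connectome_dataset()].
#' @param sizes target subject counts (each at most `n_subjects`).
#' @param n_resamples subsamples per size.
#' @param n_iters split seeds per subsample.
#' @param leaky_specs named list of [pipeline_spec()]s to compare against the
#'   gold standard.
#' @param model a [model_spec()].
#' @param base_seed base seed; resample and iteration seeds derive from it.
#' @param min_site_count if non-NULL, drop sites with fewer subjects than
#'   this before resampling.
#' @return Data frame with one row per (size, resample, pipeline, iteration):
#'   `size`, `resample`, `n_actual`, `pipeline`, `iteration`, `r_gold`,
#'   `r_leaky`, `delta_r`, `delta_q2`.
#' @export
subsample_experiment <- function(dataset, sizes, n_resamples = 10,
                                 n_iters = 10, leaky_specs, model = model_spec(),
                                 base_seed = 1, min_site_count = NULL) {
  stopifnot(is.list(leaky_specs), !is.null(names(leaky_specs)))
  if (any(sizes > n_subjects(dataset)))
    stop_("sizes must not exceed the dataset size")
  if (!is.null(min_site_count)) {
    counts <- table(dataset$site)
    keep_sites <- names(counts)[counts >= min_site_count]
    dataset <- dataset_rows(dataset, which(dataset$site %in% keep_sites))
  }
  rows <- vector("list", 0)
  for (si in seq_along(sizes)) {
    for (rs in seq_len(n_resamples)) {
      rseed <- base_seed + 7907L * si + 101L * rs
      idx <- resample_families(dataset, sizes[si], rseed)
      d_sub <- dataset_rows(dataset, idx)
      for (it in seq_len(n_iters)) {
        it_seed <- rseed + it
        gold <- run_pipeline(d_sub, pipeline_spec(
          outer_k = leaky_specs[[1]]$outer_k,
          covariate_exclusions = leaky_specs[[1]]$covariate_exclusions,
          combat_eb = leaky_specs[[1]]$combat_eb), model, it_seed)
        for (nm in names(leaky_specs)) {
          leaky <- run_pipeline(d_sub, leaky_specs[[nm]], model, it_seed)
          rows[[length(rows) + 1L]] <- data.frame(
            size = sizes[si], resample = rs, n_actual = length(idx),
            pipeline = nm, iteration = it,
            r_gold = gold$r, r_leaky = leaky$r,
            delta_r = leaky$r - gold$r, delta_q2 = leaky$q2 - gold$q2)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Family-leakage effect as a function of the family fraction
#'
#' For each family fraction, generates a synthetic dataset from the base
#' configuration and computes the paired `delta_r` between the
#' family-ignorant (plain-split) pipeline and the gold standard across split
#' seeds. Reproduces, on simulation, the observation that family leakage
#' grows with the proportion of participants belonging to multi-member
#' families.
#'
#' @param base_config a [synthetic_config()].
#' @param fractions family fractions to sweep over.
#' @param model a [model_spec()].
#' @param n_iters split seeds per fraction.
#' @return Data frame with one row per (fraction, iteration): `fraction`,
#'   `iteration`, `delta_r`, `delta_q2`, `r_gold`, `r_leaky`.
#' @export
family_sweep <- function(base_config, fractions, model = model_spec(),
                         n_iters = 20) {
  cfgs <- family_fraction_grid(base_config, fractions)
  rows <- vector("list", 0)
  for (i in seq_along(cfgs)) {
    d <- generate_dataset(cfgs[[i]])
    for (it in seq_len(n_iters)) {
      dv <- delta_vs_gold(d, pipeline_spec(split = "plain"), model,
                          seed = cfgs[[i]]$seed + 1000L + it)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fractions[i], iteration = it,
        delta_r = dv$delta_r, delta_q2 = dv$delta_q2,
        r_gold = dv$gold$r, r_leaky = dv$leaky$r)
    }
  }
  do.call(rbind, rows)
}
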