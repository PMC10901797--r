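#' Configuration for the synthetic connectome generator
#'
#' Describes a population with the statistical structure the leakage analyses
#' assume: a single latent brain-behavior factor of controllable strength,
#' twin-like two-member families with correlated features and phenotypes,
#' additive and multiplicative site effects, and covariates (age, sex, head
#' motion) that load on both the edge features and the phenotype
#' (confounding).
#'
#' `effect_size` is the population fraction of phenotype variance explained
#' by the latent signal; the phenotype loading is calibrated so that the
#' population R-squared of `y` on the latent factor equals it exactly.
#'
#' @param n_subjects subject count.
#' @param n_nodes node count; `n_nodes*(n_nodes-1)/2` edges.
#' @param effect_size fraction of phenotype variance carried by the latent
#'   signal, in `[0, 1)`.
#' @param n_signal_edges number of edges loading on the latent factor;
#'   default `NULL` means 2% of the edges (at least 1).
#' @param family_fraction fraction of subjects belonging to a two-member
#'   family, in `[0, 1]` (rounded to an even subject count).
#' @param family_rho correlation of the family-shared component in both the
#'   latent signal and the phenotype noise, in `[0, 1]`.
#' @param n_sites number of acquisition sites (balanced random assignment).
#' @param site_shift_sd SD of additive per-site, per-edge shifts.
#' @param site_scale_range range (length-2, positive) of multiplicative
#'   per-site, per-edge scale factors.
#' @param covariate_effects named list over `age`, `sex`, `motion`; each entry
#'   is `c(x = ..., y = ...)` where `x` is the SD of per-edge loadings of the
#'   standardized covariate on the features and `y` its coefficient in the
#'   phenotype. A covariate with both nonzero is a confound.
#' @param noise_sd residual SD for both edge features and phenotype.
#' @param age_range age uniform-draw range in years (shared within family).
#' @param seed RNG seed; generation is byte-reproducible given the config.
#' @return An object of class `synthetic_config`.
#' @seealso [generate_dataset()], [null_dataset()], [family_fraction_grid()]
#' @export
synthetic_config <- function(n_subjects = 200, n_nodes = 100,
                             effect_size = 0.2, n_signal_edges = NULL,
                             family_fraction = 0.25, family_rho = 0.6,
                             n_sites = 2, site_shift_sd = 0.1,
                             site_scale_range = c(0.9, 1.1),
                             covariate_effects = list(
                               age    = c(x = 0.3, y = 0.5),
                               sex    = c(x = 0.1, y = 0.1),
                               motion = c(x = 0.3, y = 0)),
                             noise_sd = 1, age_range = c(8, 22), seed = 1) {
  n_edges <- n_nodes * (n_nodes - 1) / 2
  if (is.null(n_signal_edges)) n_signal_edges <- max(1, round(0.02 * n_edges))
  if (!is_number(effect_size) || effect_size < 0 || effect_size >= 1)
    stop_("effect_size must lie in [0, 1)")
  if (n_signal_edges > n_edges)
    stop_("n_signal_edges (", n_signal_edges, ") exceeds the edge count (",
          n_edges, ")")
  if (family_fraction < 0 || family_fraction > 1)
    stop_("family_fraction must lie in [0, 1]")
  if (family_rho < 0 || family_rho > 1) stop_("family_rho must lie in [0, 1]")
  if (n_subjects < 2 || n_nodes < 2) stop_("need n_subjects >= 2, n_nodes >= 2")
  if (length(site_scale_range) != 2 || any(site_scale_range <= 0) ||
      diff(site_scale_range) < 0)
    stop_("site_scale_range must be an increasing positive interval")
  stopifnot(is.list(covariate_effects),
            all(names(covariate_effects) %in% c("age", "sex", "motion")))
  for (ce in covariate_effects)
    if (!all(c("x", "y") %in% names(ce)))
      stop_("each covariate_effects entry needs named components x and y")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
                 effect_size = effect_size,
                 n_signal_edges = as.integer(n_signal_edges),
                 family_fraction = family_fraction, family_rho = family_rho,
                 n_sites = as.integer(n_sites), site_shift_sd = site_shift_sd,
                 site_scale_range = site_scale_range,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd, age_range = age_range,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# theoretical standardization constants for the raw covariate draws, so the
# population variance calibration of effect_size is exact
.cov_moments <- function(age_range) {
  lm_mean <- exp(-2.2 + 0.5^2 / 2)
  lm_sd <- lm_mean * sqrt(exp(0.5^2) - 1)
  list(age = c(mean(age_range), diff(age_range) / sqrt(12)),
       sex = c(0.5, 0.5),
       motion = c(lm_mean, lm_sd))
}

#' Generate a synthetic connectome dataset
#'
#' Draws a dataset under the generative law described in the package
#' vignette: (1) a standard-normal latent signal per subject, with family
#' pairs sharing a component so the within-pair latent correlation is
#' `family_rho`; (2) covariates -- age uniform on `age_range` and shared
#' within family, sex Bernoulli(0.5), motion log-normal; (3) edge features =
#' latent loadings on the signal edges + per-edge covariate loadings + iid
#' Gaussian noise, then a per-site affine transform (multiplicative scale,
#' additive shift); (4) phenotype = calibrated latent loading + covariate
#' effects + noise whose family-shared component also has correlation
#' `family_rho`. Everything is deterministic given `config$seed`.
#'
#' The returned dataset carries the generative ground truth in `$truth`
#' (latent scores, signal edge indices, loadings), which oracle-style tests
#' and the effect-size recovery check use.
#'
#' @param config a [synthetic_config()].
#' @return A [connectome_dataset()] with a `truth` element.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    p <- config$n_edges
    rho <- config$family_rho

    # families: first m subjects paired (m even), rest singletons
    m <- round(config$family_fraction * n)
    if (m %% 2 == 1) m <- m - 1
    n_pairs <- m %/% 2
    fam_index <- c(rep(seq_len(n_pairs), each = 2),
                   if (n > m) n_pairs + seq_len(n - m))
    n_fam <- n_pairs + (n - m)
    family_id <- sprintf("fam%05d", fam_index)

    # latent signal with family-shared component
    u_fam <- stats::rnorm(n_fam)
    s <- sqrt(rho) * u_fam[fam_index] + sqrt(1 - rho) * stats::rnorm(n)

    # covariates: age shared within family
    age_fam <- stats::runif(n_fam, config$age_range[1], config$age_range[2])
    age <- age_fam[fam_index]
    sex <- stats::rbinom(n, 1, 0.5)
    motion <- stats::rlnorm(n, -2.2, 0.5)
    mom <- .cov_moments(config$age_range)
    Zc <- cbind(age = (age - mom$age[1]) / mom$age[2],
                sex = (sex - mom$sex[1]) / mom$sex[2],
                motion = (motion - mom$motion[1]) / mom$motion[2])

    # edge features
    signal_edges <- sort(sample.int(p, config$n_signal_edges))
    w <- stats::rnorm(config$n_signal_edges, 0, 0.5)
    # edge noise also carries the family-shared component (a heritable
    # connectome): within a pair every edge correlates at family_rho
    if (rho > 0 && n_pairs > 0) {
      shared <- matrix(stats::rnorm(n_fam * p), n_fam, p)
      X <- config$noise_sd *
        (sqrt(rho) * shared[fam_index, , drop = FALSE] +
           sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p))
    } else {
      X <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
    }
    X[, signal_edges] <- X[, signal_edges] + tcrossprod(s, w)
    for (cv in names(config$covariate_effects)) {
      xl <- config$covariate_effects[[cv]][["x"]]
      if (xl != 0)
        X <- X + tcrossprod(Zc[, cv], stats::rnorm(p, 0, xl))
    }

    # site assignment and per-site affine distortion
    site_names <- paste0("site", seq_len(config$n_sites))
    site_idx <- sample(rep_len(seq_len(config$n_sites), n))
    if (config$n_sites > 1 &&
        (config$site_shift_sd > 0 || diff(config$site_scale_range) > 0)) {
      gam <- matrix(stats::rnorm(config$n_sites * p, 0, config$site_shift_sd),
                    config$n_sites, p)
      del <- matrix(stats::runif(config$n_sites * p,
                                 config$site_scale_range[1],
                                 config$site_scale_range[2]),
                    config$n_sites, p)
      X <- X * del[site_idx, , drop = FALSE] + gam[site_idx, , drop = FALSE]
    }

    # phenotype: loading calibrated so population R2(y ~ s) = effect_size
    b <- vapply(config$covariate_effects, function(ce) ce[["y"]], numeric(1))
    var_rest <- sum(b^2) + config$noise_sd^2
    a <- sqrt(config$effect_size / (1 - config$effect_size) * var_rest)
    e_fam <- stats::rnorm(n_fam)
    eps <- sqrt(rho) * e_fam[fam_index] + sqrt(1 - rho) * stats::rnorm(n)
    y <- a * s +
      drop(Zc[, names(config$covariate_effects), drop = FALSE] %*% b) +
      config$noise_sd * eps

    connectome_dataset(
      X = X, y = y,
      covariates = data.frame(age = age, sex = sex, motion = motion),
      site = site_names[site_idx], family_id = family_id,
      truth = list(latent = s, signal_edges = signal_edges, weights = w,
                   latent_loading = a, covariate_loadings = b,
                   config = config))
  })
}

#' Pure-noise dataset with no signal, site, family or covariate structure
#'
#' Convenience wrapper for selection-bias experiments: `X` iid standard
#' normal, `y` iid standard normal independent of `X`, one site, all
#' singleton families, structure-free covariates.
#'
#' @param n_subjects,n_nodes dimensions.
#' @param seed RNG seed.
#' @return A [connectome_dataset()].
#' @export
null_dataset <- function(n_subjects, n_nodes, seed = 1) {
  cfg <- synthetic_config(
    n_subjects = n_subjects, n_nodes = n_nodes,
    effect_size = 0, n_signal_edges = 1,
    family_fraction = 0, family_rho = 0,
    n_sites = 1, site_shift_sd = 0, site_scale_range = c(1, 1),
    covariate_effects = list(age = c(x = 0, y = 0), sex = c(x = 0, y = 0),
                             motion = c(x = 0, y = 0)),
    seed = seed)
  generate_dataset(cfg)
}

#' Configurations differing only in family fraction
#'
#' Builds the grid for the family-leakage sweep: identical configurations
#' except `family_fraction`, with seeds offset per grid point from the base
#' seed.
#'
#' @param base_config a [synthetic_config()].
#' @param fractions numeric vector in `[0, 1]`.
#' @return List of [synthetic_config()] objects.
#' @export
family_fraction_grid <- function(base_config, fractions) {
  stopifnot(inherits(base_config, "synthetic_config"))
  if (any(fractions < 0 | fractions > 1)) stop_("fractions must lie in [0, 1]")
  lapply(seq_along(fractions), function(i) {
    cfg <- unclass(base_config)
    args <- cfg[setdiff(names(cfg), "n_edges")]
    args$family_fraction <- fractions[i]
    args$seed <- base_config$seed + i - 1L
    do.call(synthetic_config, args)
  })
}
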