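# Synthetic EWAS cohorts. Effects are predefined on the Beta scale, mapped to
# the M scale through the base-2 logit, and outcomes are drawn normally on
# the M scale; a fraction c of the total M-scale group difference is carried
# by group-imbalanced confounders (continuous Age, binary Sex).

#' Simulation configuration for synthetic EWAS cohorts
#'
#' The generative model on the M scale is
#' `M = b0 + b1 * Grp + b3 * (Age - age_mean) + b4 * (Sex - sex_prob_placebo) + e`,
#' with `b0 = beta_to_m(beta0_placebo)`, total group difference
#' `dM = beta_to_m(beta0_placebo + delta_beta) - b0`, treatment coefficient
#' `b1 = (1 - confounder_fraction) * dM`, and `b3`, `b4` scaled so the
#' expected Age and Sex imbalances contribute `confounder_split` and
#' `1 - confounder_split` shares of `confounder_fraction * dM`, in the same
#' direction as the treatment effect. Centering the covariates at their
#' Placebo-group expectations makes the Placebo conditional mean exactly `b0`.
#'
#' @param n_per_group Samples per treatment group.
#' @param beta0_placebo Placebo-group Beta-value baseline, in `(0, 1)`.
#' @param delta_beta Predefined Beta-scale treatment effect;
#'   `beta0_placebo + delta_beta` must stay in `(0, 1)`.
#' @param confounder_fraction Fraction `c` in `[0, 1)` of the total M-scale
#'   group difference carried by the confounders.
#' @param confounder_split Share of the confounded part assigned to Age
#'   (the remainder goes to Sex).
#' @param noise_sd_m Residual standard deviation on the M scale.
#' @param n_cpg Number of CpG rows sharing the same design (independent noise).
#' @param precision_phi Beta-distribution precision used by
#'   [simulate_beta_outcome()].
#' @param age_mean,age_sd,age_shift Placebo-group Age mean/SD (years) and the
#'   Treatment-group mean shift creating the imbalance.
#' @param sex_prob_placebo,sex_prob_treatment Group-specific probabilities of
#'   `sex = 1`.
#' @param n_sims Replicate count used by the study drivers.
#' @param seed Optional RNG seed recorded in the config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_per_group = 500, beta0_placebo = 0.101,
                       delta_beta = 0.10, confounder_fraction = 0,
                       confounder_split = 0.5, noise_sd_m = 0.1,
                       n_cpg = 1, precision_phi = 30,
                       age_mean = 50, age_sd = 10, age_shift = 5,
                       sex_prob_placebo = 0.3, sex_prob_treatment = 0.7,
                       n_sims = 200, seed = NULL) {
  cfg <- list(n_per_group = n_per_group, beta0_placebo = beta0_placebo,
              delta_beta = delta_beta,
              confounder_fraction = confounder_fraction,
              confounder_split = confounder_split, noise_sd_m = noise_sd_m,
              n_cpg = n_cpg, precision_phi = precision_phi,
              age_mean = age_mean, age_sd = age_sd, age_shift = age_shift,
              sex_prob_placebo = sex_prob_placebo,
              sex_prob_treatment = sex_prob_treatment,
              n_sims = n_sims, seed = seed)
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config A `sim_config` candidate list.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    if (n_per_group < 1 || n_cpg < 1 || n_sims < 1) {
      stop("counts must be >= 1", call. = FALSE)
    }
    if (!(beta0_placebo > 0 && beta0_placebo < 1)) {
      stop("`beta0_placebo` must lie in (0, 1)", call. = FALSE)
    }
    bt <- beta0_placebo + delta_beta
    if (!(bt > 0 && bt < 1)) {
      stop("invalid config: beta0_placebo + delta_beta = ", bt,
           " is outside (0, 1)", call. = FALSE)
    }
    if (!(confounder_fraction >= 0 && confounder_fraction < 1)) {
      stop("`confounder_fraction` must lie in [0, 1)", call. = FALSE)
    }
    if (!(confounder_split >= 0 && confounder_split <= 1)) {
      stop("`confounder_split` must lie in [0, 1]", call. = FALSE)
    }
    if (noise_sd_m <= 0) stop("`noise_sd_m` must be positive", call. = FALSE)
    if (precision_phi <= 0) stop("`precision_phi` must be positive",
                                 call. = FALSE)
    if (confounder_fraction > 0 &&
        (age_shift == 0 || sex_prob_treatment == sex_prob_placebo)) {
      stop("confounding requires group-imbalanced covariates ",
           "(nonzero age_shift and unequal sex probabilities)", call. = FALSE)
    }
  })
  structure(config, class = "sim_config")
}

# Generative truth implied by a config: all coefficients and the per-method
# targets on both scales.
.cohort_truth <- function(config) {
  b0_m <- beta_to_m(config$beta0_placebo)
  dm_total <- beta_to_m(config$beta0_placebo + config$delta_beta) - b0_m
  c_frac <- config$confounder_fraction
  coef_treatment <- (1 - c_frac) * dm_total
  dm_age <- config$confounder_split * c_frac * dm_total
  dm_sex <- (1 - config$confounder_split) * c_frac * dm_total
  b3 <- if (c_frac > 0) dm_age / config$age_shift else 0
  b4 <- if (c_frac > 0) {
    dm_sex / (config$sex_prob_treatment - config$sex_prob_placebo)
  } else 0
  list(
    beta0_m = b0_m,
    delta_beta_true = config$delta_beta,
    delta_m_total = dm_total,
    delta_m_treatment = coef_treatment,
    delta_m_age = dm_age,
    delta_m_sex = dm_sex,
    coef_treatment = coef_treatment,
    coef_age = b3,
    coef_sex = b4,
    confounder_fraction = c_frac,
    # the treatment-attributable Beta-value difference: what a
    # confounder-adjusted estimator targets (equals delta_beta_true at c = 0)
    delta_beta_target = m_to_beta(b0_m + coef_treatment) - m_to_beta(b0_m)
  )
}

.make_metadata <- function(config) {
  n <- config$n_per_group
  group <- factor(rep(c("Placebo", "Treatment"), each = n),
                  levels = c("Placebo", "Treatment"))
  grp <- as.integer(group == "Treatment")
  age <- stats::rnorm(2 * n, mean = config$age_mean + config$age_shift * grp,
                      sd = config$age_sd)
  p_sex <- ifelse(grp == 1, config$sex_prob_treatment,
                  config$sex_prob_placebo)
  sex <- stats::rbinom(2 * n, 1L, p_sex)
  data.frame(sample_id = sprintf("S%04d", seq_len(2 * n)), group = group,
             age = age, sex = sex, stringsAsFactors = FALSE)
}

#' Simulate an EWAS cohort with normally distributed M-values
#'
#' Draws per-sample M-values from the linear model described in
#' [sim_config()] and returns the methylation matrix (M or Beta scale), the
#' sample metadata, and the generative truth. The Beta-scale matrix is the
#' element-wise [m_to_beta()] image of the same draw.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to the config's seed; `NULL` leaves the RNG
#'   state untouched).
#' @param scale Scale of the returned matrix, `"m"` (native) or `"beta"`.
#' @return A list with elements `matrix` ([methylation_matrix()]),
#'   `metadata` (data frame) and `truth` (list, see [sim_config()]).
#' @export
simulate_cohort <- function(config, seed = config$seed,
                            scale = c("m", "beta")) {
  config <- validate_sim_config(config)
  scale <- match.arg(scale)
  if (!is.null(seed)) set.seed(seed)
  truth <- .cohort_truth(config)
  md <- .make_metadata(config)
  grp <- as.integer(md$group == "Treatment")
  mu <- truth$beta0_m + truth$coef_treatment * grp +
    truth$coef_age * (md$age - config$age_mean) +
    truth$coef_sex * (md$sex - config$sex_prob_placebo)
  n <- length(mu)
  vals <- matrix(rep(mu, each = config$n_cpg), nrow = config$n_cpg) +
    matrix(stats::rnorm(config$n_cpg * n, sd = config$noise_sd_m),
           nrow = config$n_cpg)
  mat <- methylation_matrix(vals, scale = "m",
                            cpg_ids = sprintf("cpg_%04d",
                                              seq_len(config$n_cpg)),
                            sample_ids = md$sample_id)
  if (scale == "beta") mat <- convert_scale(mat, "beta")
  list(matrix = mat, metadata = md, truth = truth)
}

#' Simulate a cohort with beta-distributed Beta-values
#'
#' Used for the beta-regression convergence study: per-sample Beta-values are
#' drawn from beta distributions with group-specific means
#' (`beta0_placebo` and `beta0_placebo + delta_beta`) and common precision
#' `precision_phi` (shape parameters `mu * phi`, `(1 - mu) * phi`). No
#' confounders enter this generator.
#'
#' @inheritParams simulate_cohort
#' @return A list with `matrix` (Beta scale), `metadata`, and `truth`
#'   (group means and precision).
#' @export
simulate_beta_outcome <- function(config, seed = config$seed) {
  config <- validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  md <- .make_metadata(config)
  grp <- as.integer(md$group == "Treatment")
  mu <- ifelse(grp == 1, config$beta0_placebo + config$delta_beta,
               config$beta0_placebo)
  phi <- config$precision_phi
  n <- length(mu)
  vals <- matrix(NA_real_, nrow = config$n_cpg, ncol = n)
  for (i in seq_len(config$n_cpg)) {
    vals[i, ] <- stats::rbeta(n, shape1 = mu * phi, shape2 = (1 - mu) * phi)
  }
  # rbeta can underflow to exactly 0 for very small shape1; keep the open
  # interval contract by nudging onto the clamp boundary
  vals <- pmin(pmax(vals, 1e-12), 1 - 1e-12)
  mat <- methylation_matrix(vals, scale = "beta",
                            cpg_ids = sprintf("cpg_%04d",
                                              seq_len(config$n_cpg)),
                            sample_ids = md$sample_id)
  list(matrix = mat, metadata = md,
       truth = list(mean_placebo = config$beta0_placebo,
                    mean_treatment = config$beta0_placebo + config$delta_beta,
                    precision_phi = phi))
}

#' Fixture matrix emulating the shape of processed array data
#'
#' Real processed matrices show heavy mass of hypo- (near 0) and
#' hyper-methylated (near 1) CpG sites with approximately normal M-values per
#' site. Each row is assigned a stratum (hypo/mid/hyper); values are drawn
#' normally on the M scale around the stratum baseline and back-transformed.
#'
#' @param n_cpg,n_samples Matrix dimensions.
#' @param boundary_mass Fraction of rows in the boundary strata (split evenly
#'   between hypo and hyper).
#' @param m_sd Per-row M-scale spread.
#' @param seed Optional RNG seed.
#' @return A Beta-scale [methylation_matrix()], every value in `(0, 1)`.
#' @export
fixture_matrix <- function(n_cpg, n_samples, boundary_mass = 0.5,
                           m_sd = 0.3, seed = NULL) {
  if (boundary_mass < 0 || boundary_mass > 1) {
    stop("`boundary_mass` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  stratum <- sample(c("hypo", "mid", "hyper"), n_cpg, replace = TRUE,
                    prob = c(boundary_mass / 2, 1 - boundary_mass,
                             boundary_mass / 2))
  base_beta <- numeric(n_cpg)
  base_beta[stratum == "hypo"] <- stats::runif(sum(stratum == "hypo"),
                                               0.01, 0.07)
  base_beta[stratum == "mid"] <- stats::runif(sum(stratum == "mid"),
                                              0.20, 0.80)
  base_beta[stratum == "hyper"] <- stats::runif(sum(stratum == "hyper"),
                                                0.93, 0.99)
  m0 <- beta_to_m(base_beta)
  vals <- m_to_beta(matrix(stats::rnorm(n_cpg * n_samples, mean = m0,
                                        sd = m_sd),
                           nrow = n_cpg))
  methylation_matrix(vals, scale = "beta",
                     cpg_ids = sprintf("cpg_%05d", seq_len(n_cpg)),
                     sample_ids = sprintf("S%04d", seq_len(n_samples)))
}
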