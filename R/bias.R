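# The three simulation studies as reusable experiments: percent-deviation
# bias of the reporting approaches under confounding, beta-regression
# convergence across the Beta-value range, and the permutation analysis of
# attainable (dM, dBeta) pairs on a fixture matrix.

#' Percent-deviation bias study of the reporting approaches
#'
#' For every cell of the (baseline, effect, confounder-fraction) grid and
#' every replicate, simulates one CpG for a fresh cohort, applies the
#' requested reporting approaches, and records the percent deviation of each
#' estimate from the treatment-attributable Beta-value difference
#' (`delta_beta_target`; equals the predefined effect when `c = 0`). The
#' signed convention is `100 * (estimate - target) / target`. Cells whose
#' treatment mean would reach 1 are skipped with a warning and listed in the
#' summary as infeasible.
#'
#' @param beta0_grid Placebo-group baseline Beta-values.
#' @param delta_beta_grid Predefined Beta-scale effects.
#' @param c_values Confounder fractions.
#' @param methods Reporting approaches, any subset of
#'   `c("raw_beta_diff", "m_regression_intercept", "gaussian_beta")`.
#'   The covariate-capable approaches are adjusted for age and sex;
#'   `raw_beta_diff` is unadjusted by construction.
#' @param n_per_group,n_reps Samples per group and replicates per cell.
#' @param noise_sd_m Residual M-scale standard deviation.
#' @param seed RNG seed for the whole study.
#' @return A list with `records` (one row per cell x replicate x method:
#'   grid keys, `estimate`, `delta_beta_target`, `observed_raw_diff`,
#'   `percent_deviation`, `replicate`) and `summary` (per cell x method:
#'   mean/sd/Monte-Carlo SE and 2.5%/97.5% quantiles of the percent
#'   deviation, plus a `feasible` flag).
#' @export
run_bias_study <- function(beta0_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           delta_beta_grid = c(0.005, 0.05, 0.1, 0.2, 0.3),
                           c_values = c(0, 0.1, 0.2),
                           methods = c("raw_beta_diff",
                                       "m_regression_intercept"),
                           n_per_group = 200, n_reps = 200,
                           noise_sd_m = 0.1, seed = 1L) {
  methods <- match.arg(methods, c("raw_beta_diff", "m_regression_intercept",
                                  "gaussian_beta"), several.ok = TRUE)
  grid <- expand.grid(beta0 = beta0_grid, delta_beta = delta_beta_grid,
                      c_frac = c_values, KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  recs <- vector("list", nrow(grid))
  infeasible <- logical(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    b0 <- grid$beta0[g]; db <- grid$delta_beta[g]; cf <- grid$c_frac[g]
    if (b0 + db >= 1) {
      infeasible[g] <- TRUE
      warning(sprintf("skipping infeasible cell beta0 = %g, delta_beta = %g",
                      b0, db), call. = FALSE)
      next
    }
    cfg <- sim_config(n_per_group = n_per_group, beta0_placebo = b0,
                      delta_beta = db, confounder_fraction = cf,
                      noise_sd_m = noise_sd_m, n_cpg = 1)
    cell <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      sim <- simulate_cohort(cfg, seed = NULL)
      target <- sim$truth$delta_beta_target
      beta_mat <- convert_scale(sim$matrix, "beta")
      raw_obs <- raw_beta_diff(beta_mat, sim$metadata)$estimand
      ests <- vapply(methods, function(m) {
        switch(m,
               raw_beta_diff = raw_obs,
               m_regression_intercept = fit_m_with_intercept(
                 sim$matrix, sim$metadata,
                 adjust = c("age", "sex"))$estimand,
               gaussian_beta = fit_gaussian_beta(
                 beta_mat, sim$metadata,
                 adjust = c("age", "sex"))$estimand)
      }, numeric(1))
      cell[[r]] <- data.frame(
        beta0_placebo = b0, delta_beta_true = db, confounder_fraction = cf,
        method = methods, replicate = r, estimate = unname(ests),
        delta_beta_target = target, observed_raw_diff = raw_obs,
        percent_deviation = 100 * (unname(ests) - target) / target,
        stringsAsFactors = FALSE)
    }
    recs[[g]] <- do.call(rbind, cell)
  }
  records <- do.call(rbind, recs)
  feasible_grid <- grid[!infeasible, , drop = FALSE]
  if (is.null(records)) {
    stop("no feasible grid cells", call. = FALSE)
  }
  key <- interaction(records$beta0_placebo, records$delta_beta_true,
                     records$confounder_fraction, records$method, drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, key), function(d) {
    pd <- d$percent_deviation
    data.frame(beta0_placebo = d$beta0_placebo[1],
               delta_beta_true = d$delta_beta_true[1],
               confounder_fraction = d$confounder_fraction[1],
               method = d$method[1], n_reps = nrow(d),
               mean_pct_dev = mean(pd), sd_pct_dev = stats::sd(pd),
               mc_se = stats::sd(pd) / sqrt(nrow(d)),
               q025 = unname(stats::quantile(pd, 0.025)),
               q975 = unname(stats::quantile(pd, 0.975)),
               feasible = TRUE, stringsAsFactors = FALSE)
  }))
  if (any(infeasible)) {
    bad <- grid[infeasible, , drop = FALSE]
    skipped <- do.call(rbind, lapply(seq_len(nrow(bad)), function(i) {
      data.frame(beta0_placebo = bad$beta0[i],
                 delta_beta_true = bad$delta_beta[i],
                 confounder_fraction = bad$c_frac[i],
                 method = NA_character_, n_reps = 0L,
                 mean_pct_dev = NA_real_, sd_pct_dev = NA_real_,
                 mc_se = NA_real_, q025 = NA_real_, q975 = NA_real_,
                 feasible = FALSE, stringsAsFactors = FALSE)
    }))
    agg <- rbind(agg, skipped)
  }
  rownames(agg) <- NULL
  rownames(records) <- NULL
  list(records = records, summary = agg)
}

#' Beta-regression convergence study
#'
#' For each baseline Beta-value, simulates beta-distributed cohorts with a
#' fixed Beta-scale effect and records the fraction of maximum-likelihood
#' beta-regression fits that converge. Convergence collapses as the Placebo
#' mean approaches the distribution boundary, and by the symmetry of the
#' beta distribution the same happens near 1.
#'
#' @param beta0_grid Placebo-group mean Beta-values.
#' @param effect Beta-scale treatment effect (default 0.1).
#' @param n_per_group Samples per group.
#' @param n_reps Replicates per baseline.
#' @param precision_phi Beta-distribution precision of the generator.
#' @param seed RNG seed.
#' @return A data frame: `beta0_placebo`, `effect`, `n_attempted`,
#'   `n_converged`, `rate`.
#' @export
run_convergence_study <- function(beta0_grid = c(0.01, 0.05, 0.1, 0.3,
                                                 0.5, 0.7),
                                  effect = 0.1, n_per_group = 500,
                                  n_reps = 100, precision_phi = 30,
                                  seed = 1L) {
  set.seed(seed)
  out <- lapply(beta0_grid, function(b0) {
    cfg <- sim_config(n_per_group = n_per_group, beta0_placebo = b0,
                      delta_beta = effect, precision_phi = precision_phi,
                      n_cpg = 1)
    conv <- vapply(seq_len(n_reps), function(r) {
      sim <- simulate_beta_outcome(cfg, seed = NULL)
      fit_beta_regression(sim$matrix, sim$metadata)$converged
    }, logical(1))
    data.frame(beta0_placebo = b0, effect = effect, n_attempted = n_reps,
               n_converged = sum(conv), rate = mean(conv))
  })
  do.call(rbind, out)
}

#' Permutation analysis of attainable (dM, dBeta) pairs
#'
#' For each group size and replicate, draws two disjoint random sample sets
#' from the matrix, computes per-CpG differences of group M-value means, and
#' pairs each with the difference of the back-transformed group means on the
#' Beta scale. Every pair necessarily lies inside the theoretical envelope
#' `|dBeta| <= delta_beta_max(|dM|)`.
#'
#' @param matrix A [methylation_matrix()] on either scale.
#' @param group_sizes Per-group sizes to draw (default the classic
#'   5/10/20/50/100 ladder).
#' @param n_reps Replicates per group size.
#' @param seed RNG seed.
#' @param bin_dm,bin_db Histogram bin widths on the dM and dBeta axes.
#' @return A list with `records` (`group_size`, `replicate`, `cpg_id`,
#'   `delta_m`, `delta_beta`) and `histogram` (`dm_bin`, `db_bin` midpoints
#'   with occurrence `count`).
#' @export
run_permutation_study <- function(matrix, group_sizes = c(5, 10, 20, 50, 100),
                                  n_reps = 1000, seed = 1L,
                                  bin_dm = 0.25, bin_db = 0.01) {
  m_mat <- convert_scale(matrix, "m")
  n_samples <- ncol(m_mat)
  if (n_samples < 2 * max(group_sizes)) {
    stop("matrix has ", n_samples, " samples but 2 x max(group_sizes) = ",
         2 * max(group_sizes), " are required", call. = FALSE)
  }
  set.seed(seed)
  V <- unclass(m_mat); attr(V, "scale") <- NULL
  cpg_ids <- rownames(m_mat)
  recs <- vector("list", length(group_sizes) * n_reps)
  k <- 0L
  for (s in group_sizes) {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(n_samples, 2L * s)
      g1 <- idx[seq_len(s)]
      g2 <- idx[s + seq_len(s)]
      m1 <- rowMeans(V[, g1, drop = FALSE])
      m2 <- rowMeans(V[, g2, drop = FALSE])
      k <- k + 1L
      recs[[k]] <- data.frame(
        group_size = s, replicate = r, cpg_id = cpg_ids,
        delta_m = m1 - m2,
        delta_beta = m_to_beta(m1) - m_to_beta(m2),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  dm_bins <- bin_dm * floor(records$delta_m / bin_dm) + bin_dm / 2
  db_bins <- bin_db * floor(records$delta_beta / bin_db) + bin_db / 2
  tab <- as.data.frame(table(dm_bin = dm_bins, db_bin = db_bins),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  histogram <- data.frame(dm_bin = as.numeric(tab$dm_bin),
                          db_bin = as.numeric(tab$db_bin),
                          count = tab$Freq)
  rownames(histogram) <- NULL
  list(records = records, histogram = histogram)
}
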