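# The four reporting approaches: exact noiseless recoveries, agreement with
# reference implementations, estimand behavior under confounding, and the
# null distribution of p-values.

test_that("noiseless two-group data is recovered exactly on both scales", {
  mat_b <- constant_group_matrix(0.2, 0.3, n_per_group = 3)
  md <- toy_metadata(3)
  f1 <- fit_gaussian_beta(mat_b, md)
  expect_equal(f1$intercept, 0.2, tolerance = 1e-12)
  expect_equal(f1$coef_treatment, 0.1, tolerance = 1e-12)
  expect_equal(f1$estimand_kind, "difference")

  f3 <- raw_beta_diff(mat_b, md)
  expect_equal(f3$estimand, 0.1, tolerance = 1e-12)

  # worked-example row: intercept -3.15, effect 1.16 -> delta-Beta 0.10
  mat_m <- constant_group_matrix(-3.15, -3.15 + 1.16, n_per_group = 3,
                                 scale = "m")
  f4 <- fit_m_with_intercept(mat_m, md)
  expect_equal(f4$intercept, -3.15, tolerance = 1e-12)
  expect_equal(round(f4$estimand, 2), 0.10)
  # zero effect maps to a zero difference
  null_m <- constant_group_matrix(-1.2, -1.2, n_per_group = 3, scale = "m")
  expect_equal(fit_m_with_intercept(null_m, md)$estimand, 0)
})

test_that("matrix OLS agrees with stats::lm per CpG", {
  set.seed(42)
  cfg <- sim_config(n_per_group = 40, confounder_fraction = 0.2, n_cpg = 5)
  sim <- simulate_cohort(cfg, seed = 42)
  md <- sim$metadata
  fit <- fit_m_with_intercept(sim$matrix, md, adjust = c("age", "sex"))
  for (i in seq_len(5)) {
    ref <- stats::lm(unclass(sim$matrix)[i, ] ~
                       I(md$group == "Treatment") + scale(md$age) + md$sex)
    expect_equal(fit$coef_treatment[i], unname(coef(ref)[2]),
                 tolerance = 1e-10)
    expect_equal(fit$intercept[i], unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(fit$p_value[i],
                 summary(ref)$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("unadjusted M regression reduces to the group-mean difference", {
  sim <- simulate_cohort(sim_config(n_per_group = 25, n_cpg = 4), seed = 9)
  fit <- fit_m_with_intercept(sim$matrix, sim$metadata)
  grp <- sim$metadata$group == "Treatment"
  v <- unclass(sim$matrix)
  expect_equal(fit$coef_treatment,
               unname(rowMeans(v[, grp]) - rowMeans(v[, !grp])),
               tolerance = 1e-12)
  expect_equal(fit$intercept, unname(rowMeans(v[, !grp])), tolerance = 1e-12)
  expect_equal(fit$anchor_m, fit$intercept, tolerance = 1e-12)
})

test_that("beta regression recovers the symmetric log odds ratio", {
  cfg <- sim_config(n_per_group = 1e4, beta0_placebo = 1 / 3,
                    delta_beta = 1 / 3, precision_phi = 30)
  sim <- simulate_beta_outcome(cfg, seed = 13)
  fit <- fit_beta_regression(sim$matrix, sim$metadata)
  expect_true(fit$converged)
  expect_equal(fit$estimand_kind, "odds_ratio")
  # ln( (2/3 / 1/3) / (1/3 / 2/3) ) = ln 4; SE at this n is ~0.01
  expect_equal(fit$coef_treatment, log(4), tolerance = 0.05)
  expect_gt(fit$estimand, 0)
})

test_that("beta regression matches an independent ML implementation", {
  skip_if_not_installed("glmmTMB")
  cfg <- sim_config(n_per_group = 300, beta0_placebo = 0.3,
                    delta_beta = 0.15, precision_phi = 30)
  sim <- simulate_beta_outcome(cfg, seed = 31)
  fit <- fit_beta_regression(sim$matrix, sim$metadata)
  y <- clamp_beta(as.numeric(unclass(sim$matrix)))
  g <- as.integer(sim$metadata$group == "Treatment")
  ref <- glmmTMB::glmmTMB(y ~ g, family = glmmTMB::beta_family(),
                          data = data.frame(y = y, g = g))
  expect_equal(fit$intercept, unname(glmmTMB::fixef(ref)$cond[1]),
               tolerance = 1e-4)
  expect_equal(fit$coef_treatment, unname(glmmTMB::fixef(ref)$cond[2]),
               tolerance = 1e-4)
  expect_equal(fit$precision_phi, glmmTMB::sigma(ref), tolerance = 1e-3)
})

test_that("null beta regression holds its nominal type-I error rate", {
  cfg <- sim_config(n_per_group = 250, beta0_placebo = 0.4, delta_beta = 0,
                    precision_phi = 30, n_cpg = 1)
  set.seed(17)
  p <- replicate(300, {
    sim <- simulate_beta_outcome(cfg, seed = NULL)
    fit_beta_regression(sim$matrix, sim$metadata)$p_value
  })
  expect_equal(mean(p < 0.05, na.rm = TRUE), 0.05,
               tolerance = 3 * sqrt(0.05 * 0.95 / 300) / 0.05 * 0.05 + 0.02)
})

test_that("p-values of the M regression are uniform under the null", {
  cfg <- sim_config(n_per_group = 50, beta0_placebo = 0.3, delta_beta = 0,
                    noise_sd_m = 0.1, n_cpg = 1)
  set.seed(23)
  p <- replicate(500, {
    sim <- simulate_cohort(cfg, seed = NULL)
    fit_m_with_intercept(sim$matrix, sim$metadata,
                         adjust = c("age", "sex"))$p_value
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("adjustment on the Beta scale is biased near the boundary", {
  # confounded cohorts; linear adjustment on the bounded Beta scale is
  # misspecified, most severely for hypomethylated sites
  run_cell <- function(b0, reps = 150) {
    cfg <- sim_config(n_per_group = 300, beta0_placebo = b0,
                      delta_beta = 0.1, confounder_fraction = 0.2,
                      noise_sd_m = 0.5, n_cpg = 1)
    dev <- replicate(reps, {
      s <- simulate_cohort(cfg, seed = NULL)
      f <- fit_gaussian_beta(convert_scale(s$matrix, "beta"), s$metadata,
                             adjust = c("age", "sex"))
      f$estimand - s$truth$delta_beta_target
    })
    mean(dev)
  }
  set.seed(71)
  expect_gt(abs(run_cell(0.05)), 2 * abs(run_cell(0.5)))
})

test_that("adjusted intercept method beats the raw difference when confounded", {
  cfg <- sim_config(n_per_group = 200, beta0_placebo = 0.3, delta_beta = 0.1,
                    confounder_fraction = 0.2, noise_sd_m = 0.1, n_cpg = 1)
  set.seed(29)
  devs <- replicate(100, {
    s <- simulate_cohort(cfg, seed = NULL)
    adj <- fit_m_with_intercept(s$matrix, s$metadata,
                                adjust = c("age", "sex"))$estimand
    raw <- raw_beta_diff(convert_scale(s$matrix, "beta"),
                         s$metadata)$estimand
    c(adj - s$truth$delta_beta_target, raw - s$truth$delta_beta_target)
  })
  expect_lt(abs(mean(devs[1, ])), abs(mean(devs[2, ])) / 5)
})

test_that("out-of-range predictions and non-convergence are flagged, not fatal", {
  # extreme boundary data with a continuous covariate: predictions escape [0,1]
  md <- toy_metadata(10, age = seq(20, 80, length.out = 20))
  set.seed(2)
  v <- matrix(c(runif(10, 0, 0.02), runif(10, 0.9, 1)), nrow = 1)
  mat <- methylation_matrix(v, scale = "beta",
                            sample_ids = md$sample_id, cpg_ids = "cpg_x")
  f <- fit_gaussian_beta(mat, md, adjust = "age")
  expect_true(is.logical(f$pred_out_of_range))
  # degenerate outcome: all values identical after clamping
  flat <- methylation_matrix(matrix(rep(1e-7, 20), nrow = 1), scale = "beta",
                             sample_ids = md$sample_id, cpg_ids = "cpg_y")
  fb <- fit_beta_regression(flat, md)
  expect_false(isTRUE(fb$converged) && !is.finite(fb$estimand))
  if (!fb$converged) expect_true(is.na(fb$estimand))
  # empty group is an error for the raw difference
  md_one <- md; md_one$group <- factor(rep("Placebo", 20),
                                       levels = c("Placebo", "Treatment"))
  expect_error(raw_beta_diff(mat, md_one), "two levels|non-empty")
})

test_that("the method dispatcher converts scales and adjusts p-values", {
  sim <- simulate_cohort(sim_config(n_per_group = 30, n_cpg = 6), seed = 5)
  f <- fit_method(sim$matrix, sim$metadata, method = "raw_beta_diff",
                  p_adjust = "BH")
  expect_equal(f$p_adj, stats::p.adjust(f$p_value, "BH"))
  f2 <- fit_method(convert_scale(sim$matrix, "beta"), sim$metadata,
                   method = "m_regression_intercept")
  expect_equal(f2$method, rep("m_regression_intercept", 6))
})
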