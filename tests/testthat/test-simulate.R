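# Synthetic-cohort generator: determinism, effect allocation, scale
# consistency, and fixture shape.

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- sim_config(n_per_group = 50, confounder_fraction = 0.2,
                    n_cpg = 3, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  d <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(unclass(a$matrix), unclass(d$matrix)))
  expect_identical(unclass(simulate_beta_outcome(cfg)$matrix),
                   unclass(simulate_beta_outcome(cfg)$matrix))
})

test_that("effect allocation conserves the total M-scale difference", {
  for (cf in c(0, 0.1, 0.2, 0.5)) {
    cfg <- sim_config(beta0_placebo = 0.101, delta_beta = 0.10,
                      confounder_fraction = cf, n_per_group = 10)
    tr <- simulate_cohort(cfg, seed = 1)$truth
    expect_equal(tr$delta_m_treatment + tr$delta_m_age + tr$delta_m_sex,
                 tr$delta_m_total, tolerance = 1e-12)
    expect_equal(tr$delta_m_treatment, (1 - cf) * tr$delta_m_total,
                 tolerance = 1e-12)
    # confounder contributions share the sign of the treatment effect
    expect_gte(tr$delta_m_age * sign(tr$delta_m_total), 0)
    expect_gte(tr$delta_m_sex * sign(tr$delta_m_total), 0)
  }
  # the worked-example cell: total M difference prints as 1.16
  tr <- simulate_cohort(sim_config(beta0_placebo = 0.101, delta_beta = 0.10,
                                   n_per_group = 10), seed = 1)$truth
  expect_equal(round(tr$delta_m_total, 2), 1.16)
})

test_that("null cohorts show no group difference beyond sampling noise", {
  cfg <- sim_config(n_per_group = 500, beta0_placebo = 0.3, delta_beta = 0,
                    confounder_fraction = 0, noise_sd_m = 0.1)
  sim <- simulate_cohort(cfg, seed = 12)
  grp <- sim$metadata$group == "Treatment"
  diff <- mean(unclass(sim$matrix)[, grp]) - mean(unclass(sim$matrix)[, !grp])
  expect_lt(abs(diff), 4 * 0.1 / sqrt(500))
})

test_that("adjusted regression recovers the treatment-attributable share", {
  cfg <- sim_config(n_per_group = 1e4, beta0_placebo = 0.101,
                    delta_beta = 0.10, confounder_fraction = 0.20,
                    noise_sd_m = 0.1)
  sim <- simulate_cohort(cfg, seed = 4)
  fit <- fit_m_with_intercept(sim$matrix, sim$metadata,
                              adjust = c("age", "sex"))
  target <- 0.8 * sim$truth$delta_m_total     # 0.8 x 1.16 = 0.928
  se <- 2 * 0.1 / sqrt(1e4)                   # generous coefficient SE bound
  expect_lt(abs(fit$coef_treatment - target), 4 * se)
  expect_equal(round(target, 3), 0.93, tolerance = 1e-2)
  # the raw difference carries the full, confounded effect
  raw <- raw_beta_diff(convert_scale(sim$matrix, "beta"), sim$metadata)
  expect_gt(raw$estimand, fit$estimand)
})

test_that("M-scale and Beta-scale outputs describe the same draw", {
  cfg <- sim_config(n_per_group = 30, n_cpg = 4, confounder_fraction = 0.1)
  m_sim <- simulate_cohort(cfg, seed = 21, scale = "m")
  b_sim <- simulate_cohort(cfg, seed = 21, scale = "beta")
  expect_equal(m_to_beta(unclass(m_sim$matrix)), unclass(b_sim$matrix),
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(meth_scale(b_sim$matrix), "beta")
})

test_that("beta-distributed outcomes hit the configured group means", {
  cfg <- sim_config(n_per_group = 4000, beta0_placebo = 0.1,
                    delta_beta = 0.1, precision_phi = 30)
  sim <- simulate_beta_outcome(cfg, seed = 8)
  y <- as.numeric(unclass(sim$matrix))
  grp <- sim$metadata$group == "Treatment"
  se_p <- sqrt(0.1 * 0.9 / 31 / 4000)
  se_t <- sqrt(0.2 * 0.8 / 31 / 4000)
  expect_lt(abs(mean(y[!grp]) - 0.1), 3 * se_p)
  expect_lt(abs(mean(y[grp]) - 0.2), 3 * se_t)
  expect_true(all(y > 0 & y < 1))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(beta0_placebo = 0.95, delta_beta = 0.1),
               "outside \\(0, 1\\)")
  expect_error(sim_config(confounder_fraction = 1), "\\[0, 1\\)")
  expect_error(sim_config(noise_sd_m = 0), "positive")
  expect_error(sim_config(confounder_fraction = 0.1, age_shift = 0),
               "imbalanced")
})

test_that("fixture matrices emulate boundary-heavy processed data", {
  mid <- fixture_matrix(200, 10, boundary_mass = 0, seed = 3)
  mid_means <- rowMeans(unclass(mid))
  expect_true(all(mid_means > 0.1 & mid_means < 0.9))

  mixed <- fixture_matrix(400, 10, boundary_mass = 0.5, seed = 3)
  v <- unclass(mixed)
  expect_true(all(v > 0 & v < 1))
  frac_boundary <- mean(rowMeans(v) < 0.1 | rowMeans(v) > 0.9)
  # binomial tolerance around the requested mass
  expect_lt(abs(frac_boundary - 0.5), 4 * sqrt(0.25 / 400) + 0.05)
  # per-row M-values look approximately normal: row skew is mild
  m <- beta_to_m(v)
  skew <- apply(m, 1, function(x) mean((x - mean(x))^3) / stats::sd(x)^3)
  expect_lt(median(abs(skew)), 1)
})
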