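# Shared fixture builders; everything is generated in code at test time.

toy_metadata <- function(n_per_group = 2, age = NULL, sex = NULL) {
  n <- 2 * n_per_group
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    group = factor(rep(c("Placebo", "Treatment"), each = n_per_group),
                   levels = c("Placebo", "Treatment")),
    age = if (is.null(age)) rep(50, n) else age,
    sex = if (is.null(sex)) rep(0L, n) else sex,
    stringsAsFactors = FALSE
  )
}

# two-group matrix with constant value per group (noiseless)
constant_group_matrix <- function(beta_placebo, beta_treatment,
                                  n_per_group = 2, n_cpg = 1,
                                  scale = "beta") {
  vals <- matrix(rep(c(rep(beta_placebo, n_per_group),
                       rep(beta_treatment, n_per_group)), each = n_cpg),
                 nrow = n_cpg)
  methylation_matrix(vals, scale = scale,
                     cpg_ids = sprintf("cpg_%04d", seq_len(n_cpg)),
                     sample_ids = sprintf("S%04d", seq_len(2 * n_per_group)))
}
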