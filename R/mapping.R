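# The non-bijective relationship between M-value differences and Beta-value
# differences: the mustache envelope and the constant-delta-Beta worked
# example table.

#' Maximum Beta-value difference attainable for a given M-value difference
#'
#' Over all Beta-value pairs whose M-values differ by `delta_m`, the
#' Beta-value difference is maximized at the M pair symmetric about zero,
#' giving the closed form
#' `m_to_beta(delta_m / 2) - m_to_beta(-delta_m / 2)`.
#'
#' @param delta_m Non-negative M-value difference(s).
#' @return The maximal Beta-value difference(s), in `[0, 1)`.
#' @examples
#' delta_beta_max(5)  # 0.6996
#' delta_beta_max(2)  # 1/3
#' @export
delta_beta_max <- function(delta_m) {
  .check_finite(delta_m, "delta_m")
  if (any(delta_m < 0)) {
    stop("`delta_m` must be non-negative (the envelope is symmetric; ",
         "pass |delta_m|)", call. = FALSE)
  }
  m_to_beta(delta_m / 2) - m_to_beta(-delta_m / 2)
}

#' Envelope of Beta-value differences compatible with an M-value difference
#'
#' Sweeps a baseline Beta-value `b` over a grid on `[beta_lo, beta_hi]`,
#' forms the partner value `m_to_beta(beta_to_m(b) + delta_m)`, keeps the
#' pairs whose partner stays at or below `beta_hi`, and returns the smallest
#' and largest resulting Beta-value difference. The maximum agrees with the
#' closed form [delta_beta_max()] whenever the symmetric M pair is inside the
#' bounds; the minimum depends on how close the grid gets to the boundary.
#'
#' @param delta_m Single non-negative M-value difference.
#' @param beta_lo,beta_hi Baseline Beta-value bounds, `0 < beta_lo < beta_hi < 1`.
#' @param grid_n Number of baseline grid points (>= 2).
#' @return An object of class `delta_envelope`: a list with `delta_m`,
#'   `min_delta_beta`, `max_delta_beta`, `n_feasible` and `empty`. When no
#'   baseline yields a partner within bounds the envelope is flagged
#'   `empty = TRUE` with `NA` bounds (never a silent zero).
#' @examples
#' delta_beta_range(5, 0.001, 0.999, 1e5)
#' @export
delta_beta_range <- function(delta_m, beta_lo = 0.001, beta_hi = 0.999,
                             grid_n = 1e5) {
  .check_finite(delta_m, "delta_m")
  if (length(delta_m) != 1L || delta_m < 0) {
    stop("`delta_m` must be a single non-negative number", call. = FALSE)
  }
  if (!(beta_lo > 0 && beta_lo < beta_hi && beta_hi < 1)) {
    stop("need 0 < beta_lo < beta_hi < 1", call. = FALSE)
  }
  if (grid_n < 2) stop("`grid_n` must be >= 2", call. = FALSE)
  b <- seq(beta_lo, beta_hi, length.out = as.integer(grid_n))
  partner <- m_to_beta(beta_to_m(b, clamp_eps = min(1e-12, beta_lo / 2)) + delta_m)
  keep <- partner <= beta_hi
  if (!any(keep)) {
    out <- list(delta_m = delta_m, min_delta_beta = NA_real_,
                max_delta_beta = NA_real_, n_feasible = 0L, empty = TRUE)
  } else {
    db <- partner[keep] - b[keep]
    out <- list(delta_m = delta_m, min_delta_beta = min(db),
                max_delta_beta = max(db), n_feasible = sum(keep),
                empty = FALSE)
  }
  class(out) <- "delta_envelope"
  out
}

#' @export
print.delta_envelope <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("delta_envelope: delta_m = %g, empty (no feasible Beta pair)\n",
                x$delta_m))
  } else {
    cat(sprintf(
      "delta_envelope: delta_m = %g, delta_beta in [%.4g, %.4g] (%d grid pairs)\n",
      x$delta_m, x$min_delta_beta, x$max_delta_beta, x$n_feasible))
  }
  invisible(x)
}

#' Worked-example table: constant Beta-value difference, varying M difference
#'
#' For each baseline Placebo Beta-value, adds a constant treatment effect
#' `delta_beta` on the Beta scale and tabulates both groups on the M scale,
#' demonstrating that a single Beta-value difference corresponds to many
#' M-value differences (largest near the boundaries, smallest near 0.5).
#'
#' The `*_printed` columns reproduce journal-style rounding: M-values are
#' rounded to `digits_m` decimals first and `delta_m_printed` is the
#' difference of the rounded group M-values (so e.g. baseline 0.401 prints
#' 0.59 although the full-precision difference rounds to 0.58). The
#' `formula_m` column carries the implied M-scale regression
#' `b0 + b1 * Grp_Treatment`.
#'
#' @param beta_baselines Placebo-group Beta-values in `(0, 1)`.
#' @param delta_beta Constant Beta-scale treatment effect.
#' @param digits_m Decimals for printed M-values (default 2).
#' @param beta_cap Boundary value the treatment Beta-value is capped at when
#'   `baseline + delta_beta` would reach 1 (mirroring the symmetric grid that
#'   starts at `1 - beta_cap`); capped rows report their realized, smaller
#'   difference and are flagged `capped = TRUE`.
#' @return A data frame with one row per baseline: `beta_placebo`,
#'   `m_placebo`, `beta_treatment`, `m_treatment`, `delta_beta` (realized),
#'   `delta_m` (full precision), `delta_m_printed`, `formula_m`, `capped`,
#'   `valid`. Baselines at or beyond `beta_cap` are flagged `valid = FALSE`
#'   with `NA` treatment columns.
#' @examples
#' table4()
#' @export
table4 <- function(beta_baselines = seq(0.001, 0.901, by = 0.1),
                   delta_beta = 0.10, digits_m = 2, beta_cap = 0.999) {
  .check_finite(beta_baselines, "beta_baselines")
  .check_finite(delta_beta, "delta_beta")
  if (any(beta_baselines <= 0) || any(beta_baselines >= 1)) {
    stop("`beta_baselines` must lie in (0, 1)", call. = FALSE)
  }
  bt <- beta_baselines + delta_beta
  capped <- bt >= 1 & beta_baselines < beta_cap
  bt[capped] <- beta_cap
  valid <- bt > 0 & bt < 1 & bt > beta_baselines
  m_p <- beta_to_m(beta_baselines)
  m_t <- rep(NA_real_, length(bt))
  m_t[valid] <- beta_to_m(bt[valid])
  bt[!valid] <- NA_real_
  m_p_r <- round(m_p, digits_m)
  m_t_r <- round(m_t, digits_m)
  dm_printed <- round(m_t_r - m_p_r, digits_m)
  out <- data.frame(
    beta_placebo = beta_baselines,
    m_placebo = m_p,
    beta_treatment = bt,
    m_treatment = m_t,
    delta_beta = bt - beta_baselines,
    delta_m = m_t - m_p,
    delta_m_printed = dm_printed,
    formula_m = ifelse(
      valid,
      sprintf(paste0("%.", digits_m, "f + %.", digits_m, "f * Grp_Treatment"),
              m_p_r, dm_printed),
      NA_character_),
    capped = capped,
    valid = valid,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
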