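# Scalar/vector transformations between array intensities, Beta-values and
# M-values, plus the intercept method. All transforms are vectorized and
# shape-preserving (scalars, vectors, matrices).

.check_finite <- function(x, name) {
  if (!is.numeric(x)) {
    stop("`", name, "` must be numeric", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("`", name, "` contains non-finite values", call. = FALSE)
  }
  invisible(x)
}

#' Convert methylated/unmethylated intensities to a Beta-value
#'
#' Beta-values are the fraction of methylated signal at a CpG site,
#' `max(meth, 0) / (max(meth, 0) + max(unmeth, 0) + offset)`. Negative
#' intensities (possible after background correction) are truncated at zero;
#' the additive offset (100 by default) regularizes low-intensity probes and
#' guarantees the result lies in `[0, 1)`.
#'
#' @param methylated,unmethylated Numeric intensities, any shape; recycled
#'   against each other by the usual rules.
#' @param offset Non-negative regularizing count added to the denominator.
#' @return Beta-values in `[0, 1)`, same shape as the inputs.
#' @examples
#' intensities_to_beta(900, 0)    # 0.9
#' intensities_to_beta(100, 0)    # 0.5
#' @export
intensities_to_beta <- function(methylated, unmethylated, offset = 100) {
  .check_finite(methylated, "methylated")
  .check_finite(unmethylated, "unmethylated")
  .check_finite(offset, "offset")
  if (length(offset) != 1L || offset < 0) {
    stop("`offset` must be a single non-negative number", call. = FALSE)
  }
  meth <- pmax(methylated, 0)
  unmeth <- pmax(unmethylated, 0)
  meth / (meth + unmeth + offset)
}

#' Clamp Beta-values away from the unit-interval boundary
#'
#' Beta-values read from processed files can touch 0 or 1 exactly, where the
#' logit is undefined. Values are clamped into `[eps, 1 - eps]` before any
#' logit transform.
#'
#' @param beta Numeric Beta-values in `[0, 1]`.
#' @param eps Clamp half-width, a small positive fraction.
#' @return Clamped values, same shape.
#' @export
clamp_beta <- function(beta, eps = 1e-6) {
  .check_finite(beta, "beta")
  if (any(beta < 0) || any(beta > 1)) {
    stop("`beta` must lie in [0, 1]", call. = FALSE)
  }
  if (length(eps) != 1L || !is.finite(eps) || eps <= 0 || eps >= 0.5) {
    stop("`eps` must be a single value in (0, 0.5)", call. = FALSE)
  }
  pmin(pmax(beta, eps), 1 - eps)
}

#' Beta-value to M-value (base-2 logit)
#'
#' `M = log2(Beta / (1 - Beta))`. M-values are approximately normally
#' distributed and are the usual outcome scale for linear modelling of array
#' methylation; they are strictly increasing in Beta and equal 0 at
#' Beta = 0.5. Input is clamped by [clamp_beta()] first so file values at
#' exactly 0 or 1 stay finite.
#'
#' @param beta Numeric Beta-values in `[0, 1]`.
#' @param clamp_eps Clamp half-width passed to [clamp_beta()].
#' @return M-values, same shape as `beta`.
#' @examples
#' beta_to_m(0.101)  # -3.15
#' beta_to_m(0.5)    # 0
#' @export
beta_to_m <- function(beta, clamp_eps = 1e-6) {
  b <- clamp_beta(beta, eps = clamp_eps)
  log2(b / (1 - b))
}

#' M-value to Beta-value (inverse base-2 logit)
#'
#' `Beta = 2^M / (1 + 2^M)`, the exact inverse of [beta_to_m()] on the clamped
#' domain. Computed as `1 / (1 + 2^(-M))` so large `|M|` saturates at 0 or 1
#' without overflow.
#'
#' @param m Numeric M-values, any shape.
#' @return Beta-values in `(0, 1)` (0/1 only in the saturated limit).
#' @examples
#' m_to_beta(-3.15)  # 0.101
#' m_to_beta(0)      # 0.5
#' @export
m_to_beta <- function(m) {
  .check_finite(m, "m")
  1 / (1 + 2^(-m))
}

#' Natural-log inverse logit
#'
#' `exp(x) / (1 + exp(x))`. This is the back-transform of the beta-regression
#' mean link (natural-log logit) and is deliberately distinct from the base-2
#' logit pair [beta_to_m()] / [m_to_beta()] used for M-values.
#'
#' @param x Numeric, any shape.
#' @return Probabilities in `(0, 1)`.
#' @export
inverse_logit <- function(x) {
  .check_finite(x, "x")
  1 / (1 + exp(-x))
}

#' The intercept method: M-scale effect to a Beta-value difference
#'
#' Given the intercept `b0` and treatment coefficient `b1` of a Gaussian
#' linear regression on M-values, the confounder-adjusted difference in
#' Beta-values is obtained by back-transforming both group means:
#' `m_to_beta(b0 + b1) - m_to_beta(b0)`. Because the M-to-Beta map is
#' nonlinear, the same `b1` yields different Beta-value differences at
#' different intercepts, which is why the intercept must be retained.
#'
#' @param intercept_m M-scale intercept(s) (the adjusted Placebo-group mean).
#' @param coef_m M-scale treatment coefficient(s).
#' @return A data frame with columns `delta_beta` (the difference estimand, in
#'   `(-1, 1)`), `delta_m` (the M-scale effect), and `kind` (`"difference"`).
#' @examples
#' intercept_method(-3.15, 1.16)  # delta_beta ~ 0.10
#' @export
intercept_method <- function(intercept_m, coef_m) {
  .check_finite(intercept_m, "intercept_m")
  .check_finite(coef_m, "coef_m")
  data.frame(
    delta_beta = m_to_beta(intercept_m + coef_m) - m_to_beta(intercept_m),
    delta_m = coef_m + 0 * intercept_m,
    kind = "difference",
    stringsAsFactors = FALSE
  )
}
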