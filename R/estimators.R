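# Per-CpG implementations of the four estimand-reporting approaches:
#   1 gaussian_beta          OLS on Beta-values, coefficient reported as dBeta
#   2 beta_regression        ML beta regression, effect reported as a ratio
#   3 raw_beta_diff          raw Beta-mean difference, p-value from M scale
#   4 m_regression_intercept OLS on M-values with intercept retrieval
# All share a common design-matrix coding: Treatment dummy 0/1, Age
# standardized, Sex 0/1.

.treatment_level <- function(group) {
  lev <- levels(as.factor(group))
  if (length(lev) != 2L) {
    stop("`group` must have exactly two levels, found: ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  if ("Placebo" %in% lev) setdiff(lev, "Placebo") else lev[2L]
}

.build_design <- function(metadata, adjust = NULL) {
  adjust <- if (is.null(adjust)) character(0) else match.arg(
    adjust, c("age", "sex"), several.ok = TRUE)
  trt <- .treatment_level(metadata$group)
  grp <- as.integer(as.character(metadata$group) == trt)
  X <- cbind(intercept = 1, grp_treatment = grp)
  if ("age" %in% adjust) {
    X <- cbind(X, age = as.numeric(scale(metadata$age)))
  }
  if ("sex" %in% adjust) {
    X <- cbind(X, sex = as.numeric(metadata$sex))
  }
  X
}

# OLS of every matrix row on a shared design. Returns coefficients, standard
# errors, residual df and fitted values; flags the (shared) design as failed
# when rank-deficient.
.ols_multi <- function(Y, X) {
  p <- ncol(X)
  XtX <- crossprod(X)
  ok <- TRUE
  XtXinv <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
  if (is.null(XtXinv) || qr(X)$rank < p) {
    return(list(ok = FALSE, p = p))
  }
  coef <- Y %*% X %*% XtXinv            # n_cpg x p
  fitted <- coef %*% t(X)
  res <- Y - fitted
  df <- nrow(X) - p
  sigma2 <- rowSums(res^2) / df
  se <- sqrt(sigma2 %o% diag(XtXinv))
  colnames(coef) <- colnames(se) <- colnames(X)
  list(ok = TRUE, coef = coef, se = se, df = df, fitted = fitted, p = p)
}

.empty_fit <- function(cpg_ids, method, kind) {
  n <- length(cpg_ids)
  data.frame(cpg_id = cpg_ids, method = method,
             intercept = NA_real_, coef_treatment = NA_real_,
             coef_age = NA_real_, coef_sex = NA_real_,
             p_value = NA_real_, converged = FALSE,
             estimand = NA_real_, estimand_kind = kind,
             stringsAsFactors = FALSE)
}

.coef_or_na <- function(fit, name) {
  if (name %in% colnames(fit$coef)) fit$coef[, name] else NA_real_
}

#' Approach 1: Gaussian linear regression on Beta-values
#'
#' Ordinary least squares of each CpG's Beta-values on treatment (plus
#' optional covariates). The treatment coefficient is reported directly as a
#' Beta-value difference. Fitted values may leave `[0, 1]`; such CpGs are
#' flagged in `pred_out_of_range`, not errored, and estimates near the
#' boundaries can be biased because the outcome is bounded and
#' heteroscedastic.
#'
#' @param matrix Beta-scale [methylation_matrix()].
#' @param metadata Sample metadata with `sample_id`, `group`, `age`, `sex`.
#' @param adjust Covariates to adjust for, subset of `c("age", "sex")`, or
#'   `NULL` for the unadjusted two-group model.
#' @return A data frame, one row per CpG: `cpg_id`, `method`, `intercept`,
#'   `coef_treatment`, `coef_age`, `coef_sex`, `p_value`, `converged`,
#'   `estimand` (Beta-value difference), `estimand_kind`,
#'   `pred_out_of_range`.
#' @export
fit_gaussian_beta <- function(matrix, metadata, adjust = NULL) {
  .assert_scale(matrix, "beta", "fit_gaussian_beta")
  X <- .build_design(metadata, adjust)
  Y <- unclass(matrix); attr(Y, "scale") <- NULL
  fit <- .ols_multi(Y, X)
  if (!fit$ok) return(.empty_fit(rownames(matrix), "gaussian_beta",
                                 "difference"))
  tstat <- fit$coef[, "grp_treatment"] / fit$se[, "grp_treatment"]
  data.frame(
    cpg_id = rownames(matrix), method = "gaussian_beta",
    intercept = fit$coef[, "intercept"],
    coef_treatment = fit$coef[, "grp_treatment"],
    coef_age = .coef_or_na(fit, "age"),
    coef_sex = .coef_or_na(fit, "sex"),
    p_value = 2 * stats::pt(-abs(tstat), df = fit$df),
    converged = TRUE,
    estimand = fit$coef[, "grp_treatment"],
    estimand_kind = "difference",
    pred_out_of_range = apply(fit$fitted < 0 | fit$fitted > 1, 1L, any),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Approach 3: raw Beta-value mean difference with M-scale p-values
#'
#' The estimand is the unadjusted difference of group Beta-value means
#' (Treatment minus Placebo); the p-value comes from the companion
#' unadjusted Gaussian fit on M-values. By construction this estimand cannot
#' be covariate-adjusted, so under group-imbalanced confounding it absorbs
#' the confounder share of the effect.
#'
#' @inheritParams fit_gaussian_beta
#' @param clamp_eps Clamp half-width used for the companion M transform.
#' @return A per-CpG data frame as in [fit_gaussian_beta()].
#' @export
raw_beta_diff <- function(matrix, metadata, clamp_eps = 1e-6) {
  .assert_scale(matrix, "beta", "raw_beta_diff")
  trt <- .treatment_level(metadata$group)
  is_trt <- as.character(metadata$group) == trt
  if (sum(is_trt) == 0L || sum(!is_trt) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  Y <- unclass(matrix); attr(Y, "scale") <- NULL
  est <- rowMeans(Y[, is_trt, drop = FALSE]) -
    rowMeans(Y[, !is_trt, drop = FALSE])
  # companion M-scale fit supplies the p-value
  M <- beta_to_m(Y, clamp_eps = clamp_eps)
  X <- .build_design(metadata, NULL)
  fit <- .ols_multi(M, X)
  pv <- if (fit$ok) {
    2 * stats::pt(-abs(fit$coef[, "grp_treatment"] /
                         fit$se[, "grp_treatment"]), df = fit$df)
  } else NA_real_
  data.frame(
    cpg_id = rownames(matrix), method = "raw_beta_diff",
    intercept = rowMeans(Y[, !is_trt, drop = FALSE]),
    coef_treatment = est,
    coef_age = NA_real_, coef_sex = NA_real_,
    p_value = pv, converged = TRUE,
    estimand = est, estimand_kind = "difference",
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Approach 4: Gaussian regression on M-values with intercept retrieval
#'
#' Ordinary least squares of each CpG's M-values on treatment plus optional
#' covariates, retaining the intercept. The estimand is the intercept-method
#' Beta-value difference: the model-implied Placebo-group mean (the design
#' row averaged over Placebo samples with the treatment term at zero) is
#' back-transformed with and without the treatment coefficient and
#' differenced. With covariates this anchor is the confounder-adjusted
#' Placebo M-value; without covariates it is exactly the reported intercept.
#'
#' @inheritParams fit_gaussian_beta
#' @param matrix M-scale [methylation_matrix()].
#' @return A per-CpG data frame as in [fit_gaussian_beta()], with
#'   `estimand` the confounder-adjusted Beta-value difference and an
#'   additional `anchor_m` column (the adjusted Placebo-group M-value).
#' @export
fit_m_with_intercept <- function(matrix, metadata, adjust = NULL) {
  .assert_scale(matrix, "m", "fit_m_with_intercept")
  X <- .build_design(metadata, adjust)
  Y <- unclass(matrix); attr(Y, "scale") <- NULL
  fit <- .ols_multi(Y, X)
  if (!fit$ok) return(.empty_fit(rownames(matrix), "m_regression_intercept",
                                 "difference"))
  # mean design row over Placebo samples, treatment term zeroed
  xbar_placebo <- colMeans(X[X[, "grp_treatment"] == 0, , drop = FALSE])
  anchor <- drop(fit$coef %*% xbar_placebo)
  b1 <- fit$coef[, "grp_treatment"]
  est <- intercept_method(anchor, b1)
  tstat <- b1 / fit$se[, "grp_treatment"]
  data.frame(
    cpg_id = rownames(matrix), method = "m_regression_intercept",
    intercept = fit$coef[, "intercept"],
    coef_treatment = b1,
    coef_age = .coef_or_na(fit, "age"),
    coef_sex = .coef_or_na(fit, "sex"),
    p_value = 2 * stats::pt(-abs(tstat), df = fit$df),
    converged = TRUE,
    estimand = est$delta_beta,
    estimand_kind = "difference",
    anchor_m = anchor,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# ---- beta regression (ML, logit mean link, constant precision) ----------

# negative log-likelihood and analytic gradient in (coefs, log phi)
.betareg_negll <- function(par, y, X) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  mu <- 1 / (1 + exp(-eta))
  phi <- exp(par[p + 1L])
  ll <- sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  if (!is.finite(ll)) return(.Machine$double.xmax / 2)
  -ll
}

.betareg_grad <- function(par, y, X) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  mu <- 1 / (1 + exp(-eta))
  phi <- exp(par[p + 1L])
  a <- mu * phi
  b <- (1 - mu) * phi
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(a) - digamma(b)
  d_beta <- -phi * drop(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
  d_phi <- -(sum(mu * (ystar - mustar) + log1p(-y) - digamma(b)) +
               length(y) * digamma(phi))
  g <- c(d_beta, d_phi * phi)  # chain rule for log phi
  g[!is.finite(g)] <- 0
  g
}

.betareg_one <- function(y, X, clamp_eps, maxit, reltol) {
  y <- clamp_beta(y, eps = clamp_eps)
  p <- ncol(X)
  # starting values: OLS on the logit scale, method-of-moments precision
  z <- log(y) - log1p(-y)
  start_beta <- tryCatch(qr.solve(X, z), error = function(e) rep(0, p))
  mu0 <- 1 / (1 + exp(-drop(X %*% start_beta)))
  mu0 <- pmin(pmax(mu0, 1e-3), 1 - 1e-3)
  v <- stats::var(y - mu0)
  phi0 <- if (is.finite(v) && v > 0) {
    max(mean(mu0 * (1 - mu0)) / v - 1, 0.1)
  } else 1
  par0 <- c(start_beta, log(phi0))
  opt <- tryCatch(
    stats::optim(par0, .betareg_negll, gr = .betareg_grad, y = y, X = X,
                 method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol),
                 hessian = TRUE),
    error = function(e) NULL)
  fail <- list(converged = FALSE, coef = rep(NA_real_, p),
               se = rep(NA_real_, p), phi = NA_real_)
  if (is.null(opt) || opt$convergence != 0L || any(!is.finite(opt$par))) {
    return(fail)
  }
  H <- opt$hessian
  if (any(!is.finite(H))) return(fail)
  cov <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) <= 0)) {
    return(fail)
  }
  list(converged = TRUE, coef = opt$par[seq_len(p)],
       se = sqrt(diag(cov)[seq_len(p)]), phi = exp(opt$par[p + 1L]))
}

#' Approach 2: beta regression on Beta-values
#'
#' Maximum-likelihood beta regression with a natural-log logit mean link and
#' a constant precision parameter, fitted per CpG by BFGS with analytic
#' gradients (at most `maxit` iterations, relative tolerance `reltol`).
#' The treatment effect `exp(coef_treatment)` is a ratio of group odds of
#' methylation (akin to an odds ratio), not a Beta-value difference.
#' Convergence failure — optimizer non-convergence, non-finite estimates, or
#' a non-positive-definite Hessian — is recorded per CpG in `converged`,
#' never raised as an error; such sites carry no estimand. Values are
#' clamped into the open unit interval before fitting.
#'
#' @inheritParams fit_gaussian_beta
#' @param clamp_eps Clamp half-width applied before fitting.
#' @param maxit,reltol BFGS iteration cap and relative tolerance.
#' @return A per-CpG data frame as in [fit_gaussian_beta()] with
#'   `estimand = exp(coef_treatment)`, `estimand_kind = "odds_ratio"` and an
#'   extra `precision_phi` column.
#' @export
fit_beta_regression <- function(matrix, metadata, adjust = NULL,
                                clamp_eps = 1e-6, maxit = 200,
                                reltol = 1e-8) {
  .assert_scale(matrix, "beta", "fit_beta_regression")
  X <- .build_design(metadata, adjust)
  Y <- unclass(matrix); attr(Y, "scale") <- NULL
  nms <- colnames(X)
  res <- lapply(seq_len(nrow(Y)), function(i) {
    .betareg_one(Y[i, ], X, clamp_eps, maxit, reltol)
  })
  coef_mat <- do.call(rbind, lapply(res, `[[`, "coef"))
  se_mat <- do.call(rbind, lapply(res, `[[`, "se"))
  colnames(coef_mat) <- colnames(se_mat) <- nms
  conv <- vapply(res, `[[`, logical(1), "converged")
  z <- coef_mat[, "grp_treatment"] / se_mat[, "grp_treatment"]
  out <- data.frame(
    cpg_id = rownames(matrix), method = "beta_regression",
    intercept = coef_mat[, "intercept"],
    coef_treatment = coef_mat[, "grp_treatment"],
    coef_age = if ("age" %in% nms) coef_mat[, "age"] else NA_real_,
    coef_sex = if ("sex" %in% nms) coef_mat[, "sex"] else NA_real_,
    p_value = 2 * stats::pnorm(-abs(z)),
    converged = conv,
    estimand = exp(coef_mat[, "grp_treatment"]),
    estimand_kind = "odds_ratio",
    precision_phi = vapply(res, `[[`, numeric(1), "phi"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  # non-converged fits carry no estimand
  out$estimand[!conv] <- NA_real_
  out$p_value[!conv] <- NA_real_
  out
}

#' Fit one of the four reporting approaches by name
#'
#' Dispatcher used by the study drivers and the command-line interface.
#' `matrix` may be on either scale; it is converted to the scale the method
#' requires.
#'
#' @param matrix A [methylation_matrix()] on either scale.
#' @param metadata Sample metadata.
#' @param method One of `"gaussian_beta"`, `"beta_regression"`,
#'   `"raw_beta_diff"`, `"m_regression_intercept"`.
#' @param adjust Covariates to adjust for (ignored by `raw_beta_diff`).
#' @param p_adjust Optional multiple-testing correction method for an added
#'   `p_adj` column (any [stats::p.adjust()] method, e.g. `"BH"`), or `NULL`.
#' @param ... Passed on to the method-specific fitter.
#' @return The per-CpG fit data frame of the selected method.
#' @export
fit_method <- function(matrix, metadata,
                       method = c("gaussian_beta", "beta_regression",
                                  "raw_beta_diff", "m_regression_intercept"),
                       adjust = NULL, p_adjust = NULL, ...) {
  method <- match.arg(method)
  out <- switch(
    method,
    gaussian_beta = fit_gaussian_beta(convert_scale(matrix, "beta"),
                                      metadata, adjust = adjust, ...),
    beta_regression = fit_beta_regression(convert_scale(matrix, "beta"),
                                          metadata, adjust = adjust, ...),
    raw_beta_diff = raw_beta_diff(convert_scale(matrix, "beta"),
                                  metadata, ...),
    m_regression_intercept = fit_m_with_intercept(
      convert_scale(matrix, "m"), metadata, adjust = adjust, ...)
  )
  if (!is.null(p_adjust)) {
    out$p_adj <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out
}
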