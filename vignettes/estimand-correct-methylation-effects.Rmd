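---
title: "Estimand-correct effect estimates for differential DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimand-correct effect estimates for differential DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltameth)
```

## The problem

Array-based DNA methylation is summarized per CpG site as a *Beta-value*,
the fraction of methylated signal,

$$\beta = \frac{\max(M_{\text{eth}}, 0)}{\max(M_{\text{eth}}, 0) +
\max(U_{\text{nmeth}}, 0) + 100},$$

which lives in $[0, 1)$ and is directly interpretable as percent
methylation. Because Beta-values are bounded and heteroscedastic, the
standard modelling scale is the *M-value*, the base-2 logit

$$M = \log_2\!\frac{\beta}{1 - \beta}, \qquad
\beta = \frac{2^M}{1 + 2^M},$$

which is approximately normal and suits ordinary linear modelling. The
difficulty is the *estimand*: the quantity of scientific interest is almost
always a difference in Beta-values between groups,
$\Delta_\beta$, but a linear model on M-values delivers a coefficient
$\Delta_M$ — and the map between the two differences is not a bijection. A
given $\Delta_M$ is compatible with a whole interval of $\Delta_\beta$
values depending on the baseline. `table4()` makes this concrete: holding
$\Delta_\beta = 0.10$ fixed while the Placebo baseline sweeps the unit
interval, $\Delta_M$ ranges from 0.58 (near $\beta = 0.45$) to 6.81 (near
the boundary). `delta_beta_max()` gives the converse closed form: over all
Beta pairs whose M difference equals $d$, the largest attainable
$\Delta_\beta$ is

$$\Delta_\beta^{\max}(d) = \frac{2^{d/2}}{1 + 2^{d/2}} -
\frac{2^{-d/2}}{1 + 2^{-d/2}},$$

attained at the M pair symmetric about zero (0.6996 at $d = 5$).
`delta_beta_range()` traces the full "mustache" envelope on a baseline
grid; its reported minimum depends on how close the grid is allowed to get
to the boundary and is therefore labelled grid-dependent, while the maximum
is exact.

## The four reporting approaches

For each CpG site with two-level treatment `Grp` and optional covariates
the package implements:

1. **`fit_gaussian_beta()`** — OLS directly on Beta-values. The coefficient
   *is* a Beta-value difference, but the model ignores the bounds: fitted
   values can leave $[0,1]$ (flagged per site), and when covariates enter
   linearly on the bounded scale the adjustment is misspecified — the bias
   is largest for hypo-/hypermethylated sites.
2. **`fit_beta_regression()`** — maximum-likelihood beta regression with a
   natural-log logit mean link and constant precision $\phi$. Predictions
   respect $(0,1)$, but the natural effect measure is
   $\exp(\text{coef})$, a ratio of methylation odds — not a difference —
   and must be communicated as such.
3. **`raw_beta_diff()`** — the difference of raw group Beta-means, with the
   p-value taken from the companion unadjusted M-scale fit. By construction
   this estimand cannot be adjusted: under group-imbalanced confounding it
   absorbs the confounder share of the effect.
4. **`fit_m_with_intercept()`** — OLS on M-values retaining the intercept,
   followed by the **intercept method**: back-transform the adjusted
   Placebo anchor $b_0$ and $b_0 + b_1$ to the Beta scale and difference
   them. This yields a confounder-adjusted Beta-value difference, the
   estimand most analyses actually want.

With covariates, the anchor used by the intercept method is the
model-predicted Placebo-group mean — the average Placebo design row with
the treatment term zeroed — rather than the raw intercept at the covariate
origin. By OLS invariance this equals the literal intercept of the same
model with covariates centered at Placebo means; it is what makes the
back-transformed anchor estimate the adjusted Placebo Beta-value, so the
two back-transformed points bracket exactly the treatment effect.
Coefficients are reported on the stated coding scale (Age standardized,
Sex 0/1).

Per-CpG OLS is deliberately plain rather than empirical-Bayes moderated:
variance moderation changes p-values, not coefficients, and the package's
subject is the coefficient-derived estimand. A Benjamini–Hochberg adjusted
p-value column is available through `fit_method(..., p_adjust = "BH")`.

## What the cohort generator emulates

`simulate_cohort()` draws per-sample M-values from

$$M = b_0 + b_1\,\text{Grp} + b_3\,(\text{Age} - \mu_{\text{Age}}) +
b_4\,(\text{Sex} - p_{\text{Sex}}) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma_M^2),$$

with the effect *predefined on the Beta scale*: $b_0 =
\text{beta\_to\_m}(\beta_0)$ and the total group difference $\Delta_M =
\text{beta\_to\_m}(\beta_0 + \Delta_\beta) - b_0$. A fraction $c$ of
$\Delta_M$ is carried by the confounders: the treatment coefficient is
$(1-c)\,\Delta_M$, and Age (Normal, Treatment mean shifted by +5 y) and
Sex (Bernoulli, 0.3 vs 0.7) are group-imbalanced with $b_3$, $b_4$ scaled
so their expected imbalances contribute the remaining $c\,\Delta_M$ in the
same direction (an even split by default). Centering the covariates at
their Placebo expectations makes the Placebo conditional mean exactly
$b_0$, so the generative truth carries both the predefined $\Delta_\beta$
and the *treatment-attributable* target
$\Delta_\beta^{\text{target}} = g(b_0 + (1-c)\Delta_M) - g(b_0)$, which
coincide at $c = 0$.

Parameter defaults and why:

- `noise_sd_m = 0.1`. The residual M-scale spread controls a second-order
  transformation bias of any Beta-scale mean: $E[g(M)] \approx g(\mu) +
  \tfrac12 g''(\mu)\sigma_M^2$. At $\sigma_M = 0.5$ this curvature term
  reaches ~1.5% of a $\Delta_\beta = 0.1$ effect near the boundary, which
  would swamp the phenomenon under study (confounding bias) with a
  transformation artifact and contradict the no-confounder baseline the
  bias study is calibrated against; at $\sigma_M = 0.1$ it is an order of
  magnitude below sampling noise at the study scale, while remaining a
  plausible per-CpG residual spread for processed arrays.
- `confounder_fraction` ∈ {0, 0.10, 0.20} are the studied conditions;
  values up to 1 (exclusive) are accepted.
- `precision_phi = 30` for the beta-distributed generator
  (`simulate_beta_outcome()`), i.e. a between-sample SD of ~0.054 at a mean
  of 0.1 — a realistic per-CpG dispersion for processed arrays.
- Sampling-scale defaults are 200 samples/group and 200 replicates; the
  historical large-cohort configuration (500/group, 5000 replicates) is a
  flag away (`bias-study --full-scale` on the command line).

`fixture_matrix()` emulates only the *shape* of processed data relevant to
the permutation analysis: a controllable mass of hypo-/hypermethylated rows
with approximately normal per-row M-values. It has no probe-type structure,
no batch/chip effects, no cell-composition signal and no correlation
between CpG sites, so passing tests demonstrate the transformation algebra
and estimator behavior, not robustness to those real-data complications.

## The simulation studies

`run_bias_study()` crosses baselines, predefined effects and confounder
fractions, simulates one CpG per replicate, and records each method's
**percent deviation** $100(\hat\Delta - \Delta^{\text{target}}) /
\Delta^{\text{target}}$, signed, against the treatment-attributable target.
Under this convention the raw Beta difference is unbiased at $c = 0$,
biased upward by roughly $c/(1-c)$ of the effect once confounders are
imbalanced (the bias growing from $c = 0.10$ to $0.20$ in every cell),
while the adjusted intercept method stays centered on its target
everywhere. The records also carry the observed raw difference so either
axis convention can be plotted. Infeasible grid cells
($\beta_0 + \Delta_\beta \ge 1$) are skipped with a warning and flagged in
the summary.

`run_convergence_study()` fits the beta regression on beta-distributed
cohorts across a baseline grid and reports convergence rates. A note on
what "non-convergence" means here: our fit declares failure on optimizer
non-convergence, non-finite estimates, or a non-positive-definite Hessian.
Under the default dispersion the clamped likelihood at a baseline of 0.01
with 500 samples per group is still well-posed, and both this
implementation and an independent ML implementation (glmmTMB's beta
family) converge to the same optimum there — so with these defaults the
convergence rate is high even at the boundary, and the often-reported
collapse of beta-regression fitting below a baseline of 0.1 should be
understood as a property of specific scoring algorithms and more extreme
dispersion settings rather than of the likelihood itself. The rate is
reported per baseline either way, and the qualitative monotone pattern
(never worse away from the boundary, mirrored near 1 by the symmetry of
the beta distribution) is part of the property suite.

`run_permutation_study()` draws disjoint random group pairs (sizes 5–100 by
default) from a matrix, computes per-CpG differences of group M-means, and
back-transforms the group means before differencing on the Beta scale —
which guarantees every observed $(\Delta_M, \Delta_\beta)$ pair lies inside
the theoretical envelope, a cross-module invariant the tests assert. Small
groups produce the widest $\Delta_M$ ranges. Replicates per stratum are a
parameter rather than a hard-coded refinement schedule; the 2-D occurrence
histogram uses bin widths of 0.25 ($\Delta_M$) by 0.01 ($\Delta_\beta$).

## Numerical choices and degenerate inputs

- **Clamping.** File Beta-values may touch 0 or 1; all logits clamp into
  $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$ by default and
  configurable everywhere. The intensity formula itself never reaches 1.
- **Two logits.** The M-value transform is the *base-2* logit; the
  beta-regression link is the *natural-log* logit (`inverse_logit()`). They
  agree only at $\beta = 0.5$ and are named apart throughout.
- **Printed rounding.** `table4()` reproduces journal-style rounding, where
  the printed $\Delta_M$ column is the difference of the already-rounded
  group M-values; the full-precision column sits alongside. When a baseline
  plus the constant effect would reach 1, the treatment value is capped at
  the grid boundary (0.999) and the row flagged `capped`.
- **Beta regression.** BFGS on (coefficients, $\log\phi$) with analytic
  gradients, at most 200 iterations, relative tolerance $10^{-8}$;
  starting values from a logit-scale OLS and method-of-moments precision.
  Failures are data, recorded per CpG, never fatal.
- **Antisymmetry at the boundary.** The identity
  $\text{beta\_to\_m}(1-b) = -\text{beta\_to\_m}(b)$ is exact in the
  implementation, but *evaluating* it at $1-b$ in double precision incurs a
  representation error that the logit derivative amplifies to ~$4\times
  10^{-11}$ at $b = 10^{-6}$; the property is therefore asserted at
  $10^{-12}$ on the $10^{-4}$-clamped grid.
- **Degenerate designs.** Rank-deficient designs flag all affected fits
  rather than erroring; empty groups, three-level group columns, duplicate
  identifiers, out-of-range Beta-values and non-numeric matrix cells raise
  descriptive errors naming the offending rows or columns. Missing values
  are rejected outright: the analyses assume complete matrices.

## Problem sizes

The shipped studies use 200 samples/group with 200 replicates per grid cell
for the bias study, 500/group with 100 replicates per baseline for the
convergence study, and a 30×50 fixture with 50 replicates per group size
for the permutation analysis — sizes at which every qualitative conclusion
(no bias at $c = 0$, bias growing with $c$, intercept-method recovery,
envelope containment) is stable across seeds while a full run stays in the
tens of seconds. Larger, cohort-scale configurations are plain arguments.

## Known limitations

- Independence across CpG sites; no DMR-level spatial structure.
- No probe-type normalization, batch correction or cell-composition
  adjustment; inputs are assumed preprocessed.
- The beta regression models constant precision; precision covariates are
  out of scope.
- The confounder mechanism is one consistent operationalization of
  "covariates carry a stated share of the total effect, in the same
  direction"; other allocations (e.g. confounders orthogonal to the
  predefined effect) would flip the sign of the raw-difference deviation,
  which is why the deviation is reported signed with both effect columns.
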