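---
title: "Adaptive monotonic mediation: models, searches, and design choices"
author: "monomed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive monotonic mediation: models, searches, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classical mediation analysis decomposes the effect of a predictor $X$ on an
outcome $Y$ into a natural direct effect and a natural indirect effect
transmitted through a mediator $M$, and almost always assumes all three
relationships are linear. Many dose-response-like relationships in
behavioural and clinical data are monotone but distinctly curved, and
fitting them linearly can produce biased indirect effects, residuals that
fail normality checks, and confidence intervals that miss the truth while
looking precise.

`monomed` implements mediation under *monotonic* relationships: outcome,
mediator, and predictor each enter the model through a single power
transform (a degree-1 fractional polynomial), which preserves monotonicity
for any real exponent while allowing strong curvature:

$$M^{q} = i_M + a\,X^{q'} + U_M, \qquad
  Y^{p} = i_Y + c'\,X^{p'} + b\,M^{q p''} + U_Y .$$

All variables must be strictly positive (shift by a constant otherwise);
the zero power denotes the natural log for outcome-side transforms. The
predictor transform is extended to arbitrary reals as $x^p$ for $x>0$, $0$
at $x=0$, and $\cos(\pi p)\,|x|^p$ for $x<0$, and the exponent $0$ is never
proposed by the searches (its meaning would depend on the surrounding
model); the smallest admissible magnitude is $10^{-4}$ by default.

## The composite likelihood

The two regressions are estimated jointly as one bivariate-normal model for
$(M^q, Y^p)$ per subject, with per-stream variances — optionally log-linear
in power-transformed predictors — and a single cross-stream correlation
$\rho$ (the compound-symmetry-heterogeneous, CSH, structure) or $\rho = 0$.
The per-subject log-likelihood is the usual bivariate normal
$-\tfrac12 u_s^\top \Sigma_s^{-1} u_s - \tfrac12 \log|\Sigma_s| - \log 2\pi$.

Estimation (`fit_composite()`) proceeds by case:

* $\rho = 0$ with constant variances: the likelihood separates and
  stream-wise OLS with ML variances $\mathrm{RSS}/n$ is exact;
* CSH with constant variances: iterated feasible GLS between the streams
  (the seemingly-unrelated-regressions iteration), which converges to the
  MLE because the $2\times2$ covariance is unrestricted;
* non-constant variances: BFGS over the mean coefficients, the
  log-variance coefficients, and $\operatorname{atanh}\rho$, warm-started
  from the constant-variance fit, with a Nelder-Mead fallback.

ML (not REML) variance estimation is used throughout, consistent with the
likelihood-based model scoring below. The log-variance parameterization
keeps every variance positive and $\Sigma_s$ positive definite for
$|\rho|<1$.

One structural point worth knowing: with the *observed* $M^q$ as a
regressor in the outcome stream and $\rho$ free, the likelihood is exactly
flat along a one-parameter ridge — only the combinations
$b + \rho\sigma_Y/\sigma_M$ (and the matching $X$ and intercept
combinations) are identified. The fitter lands on the $\rho$-near-zero
ridge point, which also explains why an independent-errors model always
ties or beats CSH at fixed powers when scored by cross-validation, and why
assessing $\rho = 0$ (step 8 below) typically retains it.

## Scoring models: likelihood cross-validation

Models are compared by the **LCV score**: subjects are randomly assigned to
$k$ folds (both of a subject's measurements stay together), each fold is
scored with its joint likelihood under estimates from the fold's
complement, and the total deleted log-likelihood is normalized by the
number of measurements ($2n$ for the composite model) and exponentiated —
a geometric-mean deleted likelihood. One fold assignment is reused for
every model compared on a data set.

Two models are compared by the **LCV ratio test**: the percent decrease of
the smaller score relative to the larger, against the cutoff
$100\,(1 - e^{-\chi^2_{1;0.95}/(2m)})$ with $m$ the total measurement
count. A decrease above the cutoff is "substantial"; below it, the simpler
model is a parsimonious, competitive alternative. The cutoff is 0.51% at
$m = 374$ and 0.95% at $m = 202$.

Because models with different outcome or mediator powers describe
differently transformed responses, raw likelihoods are not comparable
across powers. The **power-adjusted** score multiplies each subject's
likelihood by the change-of-variables Jacobians $|p|\,y^{p-1}$ and
$|q|\,m^{q-1}$ ($1/y$ and $1/m$ for logs), i.e. it scores every model as a
density for the *untransformed* data. `lcv()` applies the adjustment by
default; at $p = q = 1$ it coincides with the standard score.

The number of folds is chosen (`select_folds()`) as the first local
maximum of the benchmark analysis' LCV score over multiples of five folds,
the benchmark being the constrained expansion at $p = q = 1$ under CSH.

## The adaptive searches

**Single-transform search** (`search_x_power()`): a coarse grid over
$\pm 0.5, \ldots, \pm 3$; outward marching in unit steps if the grid
argmax is on the boundary, until a bracketing local maximum appears; then
per-digit refinement ($\pm0.1, \pm0.01, \ldots$) that stops early when the
three bracketing scores agree within a stopping tolerance. The transform
is admitted unless its best score falls below the base score by more than
an *expansion tolerance* set generously to 2.5 cutoffs, so near-ties still
admit the transform. Two consequences the user should understand: a
genuinely null predictor will usually still be admitted (with an
uninformative exponent), and the decision about whether a pathway exists
belongs to the ratio tests of step 5 below, not to the expansion. The
stopping tolerance defaults to the ratio-test cutoff itself — a
sample-size-adaptive choice that stops refinement on flat score surfaces;
powers are capped at $|p| \le 20$ for numerical sanity on transformed
designs.

**Constrained expansion** (`constrained_expansion()`): from the base model
(intercepts, the $M^q$ term, the covariance structure), both single-term
$X$ expansions are searched; the stream with the larger score is expanded
first (ties go to the outcome stream), then the other stream is searched
from the enlarged model — at most one $X$ transform per stream, either of
which may end up absent.

**Outcome/mediator powers** (`search_outcome_powers()`): from
$(p,q) = (1,1)$, coordinate-wise hill climbs at step 0.5 (each power with
the other at 1, keep the better branch, then climb the other power), then
the same at step 0.1, stopping at one decimal; candidates are capped to
$[-5, 5]$, where transforms are numerically degenerate beyond that on
typical data. Every candidate $(p,q)$ re-runs the constrained expansion
and is scored by power-adjusted LCV. In repeated simulations the selected
powers scatter by about $\pm0.1$ around the truth — that is the sampling
variability of the LCV optimum itself (the staged climb reproduces an
exhaustive grid argmax), so single-run selections should be read at that
resolution.

**Variance and covariate models** (`search_variance_model()`,
`search_covariates()`): greedy expansion over power-transformed candidates
($X$ in each stream, $M$ in the outcome stream, covariates in means and
variances), then contraction removing terms whose removal costs less than
the cutoff, with intercepts protected, ties broken by removing the most
recently added term, and the $X$ powers re-refined after each removal.

`monomed()` orchestrates these as an eleven-step protocol (fold selection;
$(p,q)$ search; nonlinearity, linearity-in-$X$, and constant-indirect
ratio tests; pathway tests for $a = 0$, $b = 0$, $c' = 0$; variance
models; covariates; $\rho = 0$ assessment; retransformation $p'' \ne 1$;
residual diagnostics; effects with bootstrap CIs), any subset of which can
be run.

## Effects and bootstrap confidence intervals

For $p'' = 1$ the instantaneous natural direct and indirect effects are
$c'p'x^{p'-1}$ and $b\,a\,q'x^{q'-1}$ (with $x^{-1}$ replacing the
derivative factor at a zero exponent); closed forms for $p'' = 2, 3$
include the mediator-error second moment, estimated by the fitted
mediator-stream variance (averaged over subjects under non-constant
variance models). The total effect is their sum and the relative indirect
effect their ratio, undefined where the total is zero.

`bootstrap_nie()` resamples subjects with replacement (both streams move
together, preserving the bivariate error structure), refits with **all
powers frozen**, and forms the 95% interval for the slope product $a^*b^*$
— plain percentile or, by default, bias-corrected percentile
($z_0 = \Phi^{-1}(\text{prop. of resamples below } \widehat{ab})$, bounds
at $\Phi(2z_0 \pm 1.96)$); no acceleration term is used, and non-integer
percentile ranks are interpolated linearly (quantile type 7). The bounds
are carried to each grid point through the fitted indirect-effect
multiplier and re-sorted in case a negative multiplier flips orientation.
The normalized width
$W = 1 - \min(|L|,|U|)/\max(|L|,|U|)$ is constant over the grid; smaller
$W$ means a relatively more precise interval.

## Moderated mediation

For a discrete moderator $Z$ (continuous moderators should be binned into
tertiles/quartiles first), intercepts, $X$ slopes and powers, and the
mediator slope may all differ by level, with $p$ and $q$ shared
(`fit_moderated()`). Per-level $X$ candidates compete jointly for
inclusion order by LCV gain. Component tests
(`moderation_component_tests()`) replace each per-level pathway with a
shared term (re-searching its power) or drop a single level's term, and
compare by ratio test. Levels need at least 10 subjects by default;
variance models are not moderated (an analysis moderating only the means
mirrors standard practice), and covariate effects stay unmoderated.

## The simulation generators

`simulate_mediation()` inverts the generating model exactly:
$M^q = i_M + aX^{q'} + \sigma_M U_M$,
$Y^p = i_Y + c'X^{p'} + bM^q + \sigma_Y U_Y$ with correlated standard
normal errors, back-transformed to the data scale. Draws whose transformed
values cannot be inverted on the positive domain are redrawn, and a
rejection rate above 20% errors with advice to rescale — so the stated
model is exact on retained draws rather than truncated.

Its defaults are the package's benchmark evaluation design: 101 subjects,
$X$ equally spaced on $[1, 10]$ (0.09 apart), $M = 1 + X + U_M$,
$Y^{0.4} = (5 + X + M + U_Y)/25$, hence true powers
$p = 0.4, q = p' = q' = 1$ and a true constant instantaneous indirect
effect $ab = 1/25 = 0.04$. The normalizer 25 is treated as a fixed
constant of the design so the true coefficients stay $1/25$. What this
generator emulates is a clean, correctly specified monotone mediation
structure with normal errors and a deterministic predictor grid; it does
not emulate measurement error in $X$, non-normal or skewed errors,
clustered subjects, or confounding of the $M$-$Y$ relationship — passing
tests on it demonstrate internal correctness of the estimator and
searches, not robustness to those real-data features.

## Problem sizes and numerical choices

The package's own evaluation (its test suite and the acceptance script)
runs the full power search on the 101-subject benchmark design with
$k = 15$ folds, power recovery on $n = 300$ wide-range designs with
$k = 5$, and bootstrap coverage over 50 regenerated data sets at
$B = 500$ resamples — sizes chosen to exercise every code path at
desk scale. Coverage of the constant indirect effect by the BC interval
sits in the nominal band (90-99%), while the deliberately misspecified
linear model's interval covers far less, illustrating the bias the
monotonic model removes.

Other numerical choices: fold assignment is uniform-multinomial over folds
(unequal fold sizes are expected; a balanced option exists but is off by
default), redrawn only if a fold is empty; deleted fits that fail
disqualify the score (flagged) rather than silently degrading it; the SUR
iteration stops at a $10^{-10}$ relative coefficient change; BFGS runs
with `reltol = 1e-12` and falls back to Nelder-Mead; all randomness
(folds, bootstrap, simulation) flows from named integer seeds through a
deterministic splitter so components re-run independently and
reproducibly.

## Known limitations

Single mediator, continuous positive variables only; covariance structures
beyond CSH/independent are out of scope, as are information-criterion
alternatives to LCV, analytic (Sobel-type) standard errors, and
quantile-regression fallbacks for data whose normality problems
transformation cannot fix. Instantaneous-effect formulas for retransformed
mediator terms cover $p'' \in \{1,2,3\}$; other values fit but refuse to
produce effect curves. Outcome-side transforms require positive values and
leave the shift constant to the user.
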