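---
title: "Methods: fractional-polynomial quantile regression with Bayesian variable selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractional-polynomial quantile regression with Bayesian variable selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantfp)
```

## The model and its assumptions

`quantfp` estimates conditional quantile surfaces
$Q_\tau(y \mid x) = B(x)'\beta$ where the design $B(x)$ stacks
fractional-polynomial (FP) transforms of strictly positive continuous
predictors and integer-coded categorical predictors. An FP of degree $m$
uses sorted powers $p_1 \le \dots \le p_m$ from the canonical set
$S = \{-2, -1, -\tfrac12, 0, \tfrac12, 1, 2, 3\}$, with $x^{(0)} = \log x$
(the Box–Tidwell convention) and repeated powers generating
$x^{p}\log x$ terms (Royston and Altman, 1994). This package *fits*
user-specified powers; automatic power search in the style of the
function-selection procedure of Royston and Sauerbrei is out of scope.

Estimation uses the asymmetric Laplace (AL) working likelihood
$f(\epsilon) = \tau(1-\tau)/\sigma\, e^{-\rho_\tau(\epsilon)/\sigma}$, whose
maximisation is equivalent to minimising the check loss
$\sum_i \rho_\tau(y_i - B_i'\beta)$ (Koenker and Bassett, 1978; Yu and
Moyeed, 2001). The AL is a *working* model: the fitted surface is a
consistent quantile estimate under much weaker conditions, but credible
intervals inherit the usual caveats of misspecified-likelihood Bayes.

### The scale-mixture parameterisation

All samplers rest on the normal–exponential mixture
$$\epsilon_i = (1-2\tau)\,v_i + \sqrt{2\sigma v_i}\, z_i,\qquad
  v_i \sim \mathrm{Exp}\{\tau(1-\tau)/\sigma\},\quad z_i \sim N(0,1).$$
Two equivalent scalings of the latent circulate in the literature (the
other attaches $\theta_1 = (1-2\tau)/\{\tau(1-\tau)\}$ and
$\theta_2 = 2/\{\tau(1-\tau)\}$ to a latent with rate $1/\sigma$; the two
are related by $v \mapsto \tau(1-\tau) v$). We fix the convention above
because it is the unique one jointly consistent with the exponential rate
$\tau(1-\tau)/\sigma$, the GIG latent conditional with parameters
$(0, 1/(2\sigma), \cdot)$, the $\mathrm{IG}(3n/2,\cdot)$ scale conditional
and the stated coefficient conditional. `dald_mixture()` verifies the
representation against the closed-form density by quadrature, and the test
suite asserts the identity on a grid of $(\epsilon, \sigma, \tau)$ to
$10^{-6}$. Wherever update formulas are quoted with a location loading on
$v$, that loading is $(1-2\tau)$ in this scaling.

## The three-stage estimator

The selection fitter (`bqrvs_fit()`) follows the three-stage scheme of
Dao, Wang and Ghosh (2022).

**Stage 1 (EM posterior modes).** With the latents as missing data, the
E-step has closed-form expectations $E[1/v_i] = 1/\Delta_{3i}$ and
$E[v_i] = \Delta_{2i}$ with $\Delta_{3i} = |y_i - B_i'\beta|$ and
$\Delta_{2i} = \Delta_{3i} + 2\sigma$; the M-step is a weighted least
squares for $\beta$ and a rational update for $\sigma$ whose denominator
$2(3n+2)$ absorbs the scale-invariant prior $p(\sigma)\propto 1/\sigma$,
so the fixed point $(\tilde\beta, \tilde\sigma)$ is the joint posterior
mode (at the fixed point $\tilde\sigma = \sum_i \rho_\tau(r_i)/(n+1)$).
The $\beta$-step is simultaneously a majorise–minimise step for the check
loss, which gives a monotonicity property the tests assert. Defaults:
tolerance $10^{-8}$ on the maximum relative parameter change, at most 1000
iterations, and two replications restarting from normally perturbed
initial coefficients, keeping the higher-posterior mode (the restart
strategy is our reading of an otherwise unspecified "replication").

**Stage 2 (g-prior Gibbs with importance weights).** The
quantile-specific Zellner g-prior is
$\beta \mid \sigma, v \sim N\{0,\, 2\sigma g\, (B'VB)^{-1}\}$,
$V = \mathrm{diag}(1/v_i)$, $p(\sigma) \propto 1/\sigma$. One iteration
updates, in fixed order,

* $v_i \sim \mathrm{GIG}\{0,\ 1/(2\sigma),\ d_i/(2\sigma)\}$ with
  $d_i = (y_i - B_i'\beta)^2 + (B_i'\beta)^2/g$,
* $\sigma \mid y, v \sim \mathrm{IG}\{3n/2,\ u'VH_v u/4 +
  \tau(1-\tau)\textstyle\sum_i v_i\}$ with $u = y - (1-2\tau)v$ and
  $H_v = I - \tfrac{g}{g+1} B (B'VB)^{-1} B'V$ (the coefficients are
  integrated out, so sampling $\sigma$ then $\beta$ is a valid blocked
  draw),
* $\beta \mid y, \sigma, v \sim N\{\tfrac{g}{g+1}(B'VB)^{-1}B'Vu,\
  2\sigma \tfrac{g}{g+1}(B'VB)^{-1}\}$.

The exponential-prior contribution to the $\sigma$ scale is written here
as $\tau(1-\tau)\sum v_i = (2/\theta_2)\sum v_i$; this is the form the
1-D grid-normalisation oracle and the joint-distribution test validate
(a literal $2\theta_2\sum v_i$ variant is selectable via
`sigma_scale_literal` for comparison and fails those checks, being
dimensionally inconsistent with the exponential rate).

The GIG latent step treats the g-prior normaliser $|B'VB|^{1/2}$ as if it
factorised over observations — that is what makes the conditional a clean
product of $\lambda = 0$ GIGs. The importance weight
$w = p(\beta,\sigma,v\mid y)\,/\,\{p(\beta\mid\cdot)\,p(\sigma\mid\cdot)\,
\hat\pi(v)\}$, with $\hat\pi(v)$ the product of GIG densities built at the
EM modes, adjusts for this approximation; algebraically it reduces to
$p(y \mid \gamma = \text{full}, v)/\hat\pi(v)$, an identity the tests
assert to machine precision. Weights are computed in log space and
exponentiated after subtracting the running maximum. Two practical
consequences, documented deliberately:

* the normalised-weight effective sample size decays quickly with $n$
  (the weight compares an $n$-dimensional product approximation with the
  true latent posterior), so *coefficient* summaries default to the chain
  draws — the chain tracks the exact posterior up to the slowly varying
  determinant coupling — with importance-weighted summaries available via
  `summarize_draws(weighted = TRUE)`; the weights' operational role is
  stage-3 draw selection;
* `sample_latent_v(exact = TRUE)` provides a Metropolis-within-Gibbs
  latent update whose acceptance ratio restores the determinant term
  exactly. The joint-distribution (Geweke-style) acceptance test runs the
  sampler in this exact mode, under a proper conjugate
  $\mathrm{IG}(a_0, b_0)$ prior on $\sigma$ exposed as optional
  `prior_shape`/`prior_rate` arguments (their default $(0,0)$ is
  $p(\sigma) \propto 1/\sigma$).

Defaults mirror the study configuration: $g = 1000$, $R = 5000$
iterations with 2500 burn-in for the selection model, and $R = 10000$
with 1000 burn-in for the diffuse-prior comparison sampler.

**Stage 3 (stochastic model search).** $S$ latent vectors are drawn from
the retained stage-2 draws by weighted sampling *without* replacement —
implemented exactly via the Gumbel-top-$k$ trick on log-weights
($O(R\log R)$, seedable). For each selected $v$, a binary indicator
$\gamma$ over design columns is updated by one systematic-scan Gibbs
sweep under the posterior $p(\gamma \mid y, v) \propto
p(y\mid\gamma,v)\,p(\gamma)$; the indicator is carried across the $S$
steps (re-initialising per step would also be valid; carrying gives the
sweep chain time to mix and is what the enumeration oracle validates).
The prior is the Beta–Bernoulli family with
$\pi \sim \mathrm{Beta}(\tfrac12,\tfrac12)$ marginalised out:
$p(\gamma) \propto \mathrm{B}(\sum\gamma_d + \tfrac12,\,
D - \sum\gamma_d + \tfrac12)$.

Integrating $\beta$ (g-prior) and $\sigma$ (including the $n$ exponential
latent densities, which carry $\sigma^{-n} e^{-\tau(1-\tau)\sum v_i/\sigma}$)
out of the mixture likelihood gives the closed-form log marginal
likelihood
$$\log p(y\mid\gamma, v) = -\tfrac n2\log(4\pi) - \tfrac12\sum_i \log v_i
  - \tfrac{D_\gamma}{2}\log(1+g) + \log\Gamma(\tfrac{3n}2)
  - \tfrac{3n}2 \log\{Q_\gamma/4 + \tau(1-\tau)\textstyle\sum_i v_i\},$$
with $Q_\gamma = u'V H_{v(\gamma)} u$. This *is* a $2n$-df multivariate-t
in $y$ with location $(1-2\tau)v$; the scale matrix sometimes quoted for
it carries a stray $\sigma$ and a missing $1/n$, which the derivation
resolves — we ship the derived form and accept it only because it matches
an independent three-dimensional quadrature oracle to $10^{-3}$ in log
(an acceptance test). The $|B'VB|$-determinant identity
$|V^{-1} + gB_\gamma \Sigma_{v\gamma}^{-1}B_\gamma'| =
(\prod_i v_i)(1+g)^{D_\gamma}$ keeps evaluation $O(nD_\gamma^2)$. The
empty model is handled as the pure-noise case $Q = u'Vu$, keeping the
indicator chain irreducible.

The marginal inclusion probability of column $d$ is the average of the
retained $\gamma_d$ after discarding `S_burn` steps; predictors with
MIP $\ge 0.9$ are selected (threshold configurable). Defaults
$S = 1250$, `S_burn` $= 500$.

## Comparison fitters

`fit_qr_fp()` minimises the check loss by MM/IRLS iterations (the same
majorisation as the EM $\beta$-step, with the absolute-residual floor
tightened to $10^{-11}$), which converges to the linear-programming
solution on full-rank problems; its intervals are nonparametric bootstrap
percentiles (999 resamples by default) — a deliberately solver-agnostic
choice, since rank-inversion intervals are specific to particular QR
implementations. `fit_bqr_fp()` is the diffuse-prior AL Gibbs sampler
(flat $\beta$, $p(\sigma)\propto 1/\sigma$), in the lineage of Reed and
Yu; its latent conditional is a $\lambda = \tfrac12$ GIG, sampled exactly
as the reciprocal of an inverse-Gaussian variate.

## Numerical choices

* **GIG sampling.** $\lambda = 0$: rejection on the log scale
  $t = \log(x\sqrt{c/d})$, where the density $\propto e^{-\omega\cosh t}$
  is symmetric log-concave; the envelope is uniform on $[-t_0, t_0]$
  ($t_0 = \operatorname{acosh}(1 + 1/\omega)$) with exponential tails of
  slope $\omega\sinh t_0$, giving uniformly bounded expected rejections
  over all $\omega$. $\lambda = \tfrac12$: Michael–Schucany–Haas.
  Moments are tested against modified-Bessel closed forms.
* **Floors.** Absolute residuals in EM/MM weights: $10^{-8}$ (EM) and
  $10^{-11}$ (final MM polish); GIG parameter $d_i$: $10^{-10}$ before
  division by $2\sigma$ (relevant only when residual and fit vanish
  simultaneously). All surfaced as arguments.
* **Ill-conditioning.** Singular weighted cross-products get a
  scale-aware ridge jitter $10^{-8}\,\overline{\mathrm{diag}}$; stage-3
  declares active sets collinear when a Cholesky pivot falls below
  $10^{-10}$ of the largest diagonal, naming the offending columns.
* **Intervals.** Equal-tailed, using the type-7 (linear interpolation)
  empirical quantile rule, fixed for bit-reproducibility. Effective
  sample size uses the initial-positive-sequence truncation.
* **Reproducibility.** Every stochastic entry point takes a `seed`; all
  draws flow from R's global RNG in a fixed order, so identical
  configurations are bit-identical.
* **No standardisation.** Predictors are *not* centred or scaled before
  transformation — FP powers are not location-invariant, so
  standardisation would change the estimand; the design matrix is built
  from the raw positive values, and non-positive values are an error
  (with an explicit user-supplied shift as the documented escape hatch,
  never a silent one).
* **Categorical coding.** A single integer-coded column per factor by
  default (one coefficient per factor, matching the seven-column
  blood-pressure design); optional dummy expansion via
  `fp_spec(dummy = TRUE)`. No intercept by default, matching the model
  display this design reproduces; `intercept = TRUE` adds one.

## The synthetic generator

`sim_config()`/`simulate_bp()` emulate the structure of the 2007–2008
NHANES adult blood-pressure analysis sample: n = 4609 by default;
log-normal BMI (median 27 kg/m², σ-log 0.2, hence strictly positive and
right-skewed); uniform ages 20–80; five-level ethnicity, two-level
gender and six-level marital status with the study's marginal
frequencies; both responses generated from the FP quantile model with
AL errors at the analysis τ, so the fitted model is correctly specified
and parameter recovery isolates sampler defects from misspecification.
True coefficients default to the magnitudes of the fitted median models
(SBP and DBP), and σ* = 5 / 4 mmHg gives residual spreads around 14 / 11
mmHg. Alternative error families (`normal`, `two_piece_t`), re-centred so
their τ-quantile is zero, support robustness experiments.

What the generator does *not* emulate: survey weights, stratified/cluster
sampling, nonresponse, measurement rounding, or dependence between
predictors beyond their marginals. Passing recovery tests therefore shows
the estimator is correct *under its own assumptions*, not that those
assumptions hold in survey data.

## Problem sizes used by the test suite

The suite sizes simulations to exercise each property sharply: the
joint-distribution check at n = 20, D = 2 (5,000 prior replicates vs a
25,000-step chain); the enumeration oracle at D = 4, n = 30 with $10^4$
sweeps (total variation < 0.02); quadrature oracles at n = 3; parameter
recovery at n = 500, D = 7 with R = 2000 at τ ∈ {0.5, 0.75, 0.95}; and
operating characteristics over 20 seeded replications at n = 500 with one
inert column, with active-column effects fixed in advance at a partial
signal-to-noise of roughly t = 10 so that "active" genuinely means
detectable at that sample size. With near-collinear FP pairs (here
cor(BMI, √BMI) ≈ 0.999) individual MIPs of weak terms are intrinsically
moderate — visible in the worked example, where the weak Age-pair terms
sit below the 0.9 threshold; this mirrors how such near-collinear
non-linear terms behave in the real analyses this design reproduces.

## Known limitations

* The AL working likelihood yields point estimation that is robust, but
  interval calibration under misspecification is not guaranteed.
* Importance weights degenerate as n grows (see above); stage 3 is robust
  to this by design (without-replacement selection), but weighted
  coefficient summaries at n in the thousands should not be trusted.
* FP power *search* is out of scope; powers are user-specified.
* Survey-design features (weights, strata) are not modelled.

## References

* Box, G. E. P. and Tidwell, P. W. (1962). Transformation of the
  independent variables. *Technometrics* 4, 531–550.
* Dao, M., Wang, M. and Ghosh, S. (2022). Bayesian variable selection
  with quantile-dependent priors. (Three-stage EM/Gibbs/importance
  reweighting scheme for quantile regression.)
* Koenker, R. and Bassett, G. (1978). Regression quantiles.
  *Econometrica* 46, 33–50.
* Michael, J. R., Schucany, W. R. and Haas, R. W. (1976). Generating
  random variates using transformations with multiple roots.
  *The American Statistician* 30, 88–90.
* Rea, L. M. and Parker, R. A. (2014). *Designing and Conducting Survey
  Research: A Comprehensive Guide.* Jossey-Bass.
* Reed, C. and Yu, K. (2009). A partially collapsed Gibbs sampler for
  Bayesian quantile regression.
* Royston, P. and Altman, D. G. (1994). Regression using fractional
  polynomials of continuous covariates. *Applied Statistics* 43, 429–467.
* Yu, K. and Moyeed, R. A. (2001). Bayesian quantile regression.
  *Statistics & Probability Letters* 54, 437–447.
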