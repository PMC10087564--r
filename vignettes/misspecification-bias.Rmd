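---
title: "Large-sample bias of IPW and AIPW estimators under model misspecification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Large-sample bias of IPW and AIPW estimators under model misspecification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipwbias)
```

## The estimation problem

With observational data $(T_i, X_i, Y_i)$, $i = 1, \dots, n$ — a binary
treatment $T$, covariates $X$ and an outcome $Y$ — the average causal effect
is $\Delta = E[Y(1) - Y(0)]$, the mean difference of the two potential
outcomes. Under no unmeasured confounding and overlap, $\Delta$ is
identified through the propensity score $e(X) = P(T = 1 \mid X)$ and three
prototypical estimators are in wide use:

* the simple (Horvitz–Thompson) IPW estimator
  $\hat\Delta_{IPW1} = n^{-1}\sum T_i Y_i / \hat e(X_i) -
   n^{-1}\sum (1 - T_i) Y_i / (1 - \hat e(X_i))$,
* the normalized (Hájek) IPW estimator $\hat\Delta_{IPW2}$, which divides
  each arm's weighted outcome sum by the sum of its weights, and
* the augmented IPW (AIPW) estimator
  $\hat\Delta_{AIPW} = n^{-1}\sum [T_i Y_i - (T_i - \hat e(X_i))\hat\mu_1(X_i)]/\hat e(X_i)
   - n^{-1}\sum [(1 - T_i) Y_i + (T_i - \hat e(X_i))\hat\mu_0(X_i)]/(1 - \hat e(X_i))$,
  which augments the weights with outcome-regression (OR) predictions
  $\hat\mu_t(X)$ of $E[Y(t) \mid X]$ and is *doubly robust*: consistent if
  either the propensity model or the outcome model is correctly specified.

In practice the parametric working models for $e(X)$ and $\mu_t(X)$ are
adjustment devices, not believable descriptions of the data-generating
process, so the interesting regime is the one where **all** working models
are misspecified. A misspecified quasi-maximum-likelihood or least-squares
fit still converges to well-defined limiting coefficients
$\beta^*, \alpha_t^*$, hence to limiting surfaces $e^*(X) = e(X, \beta^*)$
and $\mu_t^*(X) = \mu_t(X, \alpha_t^*)$, and each estimator converges to a
well-defined limit that is generally not $\Delta$. This package computes
those limits and the resulting large-sample biases, and evaluates the
conditions under which one estimator's bias beats another's.

## The bias calculus

Write $r_1(X) = e(X)/e^*(X)$ for the treated-arm *PS-model ratio* — the
multiplicative error of the limiting propensity model — and
$r_0(X) = (1 - e(X))/(1 - e^*(X))$ for its control-arm counterpart. The
probability-limit biases are

$$\mathrm{Bias}(\hat\Delta^*_{IPW1}) = E[r_1\mu_1(X)] - E[r_0\mu_0(X)] - (\mu_1 - \mu_0),$$
$$\mathrm{Bias}(\hat\Delta^*_{IPW2}) = \frac{E[r_1\mu_1(X)]}{E[r_1]} -
  \frac{E[r_0\mu_0(X)]}{E[r_0]} - (\mu_1 - \mu_0),$$
$$\mathrm{Bias}(\hat\Delta^*_{AIPW}) = E[(r_1 - 1)(\mu_1(X) - \mu_1^*(X))]
  - E[(r_0 - 1)(\mu_0(X) - \mu_0^*(X))].$$

`bias_functionals()` evaluates each of these, their treated-arm
(`bias1_*`) and control-arm (`bias2_*`) components, the ratio means
$E[r_1], E[r_0]$, and the covariances $\mathrm{cov}(r_1, \mu_1(X))$ etc.
that drive the comparisons. Two exact identities are useful both
scientifically and as internal consistency checks (the test suite asserts
them to $10^{-10}$):

$$\mathrm{Bias}_1(\hat\Delta^*_{IPW1}) = \mathrm{cov}(r_1, \mu_1(X)) +
  (E[r_1] - 1)\mu_1, \qquad
  \mathrm{Bias}_1(\hat\Delta^*_{IPW2}) = \frac{\mathrm{cov}(r_1, \mu_1(X))}{E[r_1]}.$$

The second identity shows why normalization protects against
misspecification: the Hájek component bias depends *only* on the
covariance, scaled down by the ratio mean, while the Horvitz–Thompson bias
picks up the full level error $(E[r_1] - 1)\mu_1$. If $\mu_1(X)$ is
constant the Hájek component bias is exactly zero.

**Sign convention for Bias2.** The control-arm component is signed as the
control arm's *contribution to the total bias*, i.e.
$\mathrm{Bias}_2(\hat\Delta^*_{IPW1}) = -(E[r_0\mu_0(X)] - \mu_0)$ and
analogously for the other estimators, so that
`bias == bias1 + bias2` holds exactly for every estimator. The mirrored
comparison theory for the control arm replaces $r_1$ by $r_0$ and $\mu_1$
by $\mu_0$ throughout, and `condition_report()` evaluates both arms.

### Comparison conditions

With $a = E[(r_1 - 1)\mu_1(X)]$ (which equals
$\mathrm{Bias}_1(\hat\Delta^*_{IPW1})$), $b = E[(r_1 - 1)\mu_1^*(X)]$,
$c = \mathrm{cov}(r_1, \mu_1(X))$ and $R = E[r_1]$, `condition_report()`
evaluates, per arm:

* **Normalization**: $|c| < R\,|a|$, which is necessary *and* sufficient
  for $|\mathrm{Bias}_1(IPW2)| < |\mathrm{Bias}_1(IPW1)|$.
* **AIPW vs simple IPW**: necessary condition $|b| < 2|a|$; sufficient
  condition $|b| < 2|a|$ with $a$ and $b$ of the same sign. (Indeed
  $\mathrm{Bias}_1(AIPW) = a - b$, so $b$ strictly between $0$ and $2a$ is
  exactly $|a - b| < |a|$.)
* **AIPW vs normalized IPW**: the interval condition
  $a - |c|/R < b < a + |c|/R$, which is in fact *equivalent* to
  $|\mathrm{Bias}_1(AIPW)| < |\mathrm{Bias}_1(IPW2)|$; and an upper-bound
  variant (same sign of $a$ and $c$, plus $|b| < |a| + |c|/R$) that is
  reported for completeness.

**Caveat on the last condition.** The upper-bound variant omits the
interval's lower bound and is therefore *not* sufficient on its own: when
the misspecified outcome surface undershoots badly ($b < a - |c|/R$, as
happens in the quadratic-omission simulation designs below, where
$a \approx 0.46$, $|c|/R \approx 0.09$, $b \approx 0.15$), the condition's
clauses hold while AIPW's component bias exceeds the Hájek one. The test
suite therefore asserts implication only for the genuinely sufficient
conditions and asserts the interval condition as an equivalence;
`condition_report()` always reports the realized orderings alongside the
verdicts so the two can be compared directly.

## Probability limits of misspecified working models

`limit_parameters()` offers two routes to $(\beta^*, \alpha_t^*)$:

* `population_score` solves the population estimating equation
  $E[\psi(\beta^*)] = 0$ by tensor-product quadrature over the covariate
  law. For the propensity model each quadrature node contributes a
  response-1 pseudo-observation with mass $w\,e(x)$ and a response-0 one
  with mass $w\,(1 - e(x))$; for arm-$t$ outcome models the node weight is
  $w\,e(x)$ (arm 1) or $w\,(1 - e(x))$ (arm 0) and the response is the
  conditional mean $\mu_t(x)$ — valid because the quasi-likelihood score is
  linear in the response. This route is exact up to solver tolerance and is
  the default wherever the covariate law is a product of one-dimensional
  components.
* `large_n_fit` draws one seeded sample of size $N$ (default $10^6$) and
  fits the working model to it; it is the only route for dependent
  covariate blocks and is also what `run_asymptotic_approximation()` uses,
  mirroring how a large-sample numerical approximation would be done in
  practice.

The two routes agree within Monte-Carlo error on every product-law design
(asserted in the tests), and outcome-model limits are invariant to the
gaussian noise standard deviation, since additive mean-zero noise drops out
of the least-squares limit.

Outcome working models are fitted arm-wise and unweighted, matching how the
AIPW estimator is used in practice; the induced $\alpha_t^*$ therefore
depends on that arm's covariate distribution (the $e(X)$- or
$(1-e(X))$-weighting above).

Working models carry an explicit sign convention. `"standard"` means
$e = \mathrm{linkinv}(\eta)$; `"complement"` means
$e = \mathrm{linkinv}(-\eta)$, so a design written as
$e(X) = \{1 + \exp(\eta)\}^{-1}$ can be encoded with its printed linear
predictor. Complement fits are performed in the standard convention and the
coefficients negated on the way out, so reported parameters match the
printed form.

## The built-in designs

`make_design()` catalogues one analytic example and three simulation
suites; each bundle pairs the data-generating truth with the misspecified
working models a data analyst might plausibly have chosen.

* **`example2`** — one covariate $X \sim U(-2, 2)$, complement-convention
  logistic truth $e(X) = \{1 + \exp(1 + 0.5X - 0.1X^2)\}^{-1}$ and
  $\mu_1(X) = 3.5 + X + 0.7X^2$; the misspecified models drop the
  quadratic. The limiting fits are
  $e^*(X) = \{1 + \exp(0.874 + 0.519X)\}^{-1}$ and
  $\mu_1^*(X) = 4.418 + 0.760X$. All treated-arm functionals are available
  in closed quadrature form in seconds; the control arm is identically zero
  and unused. Note that the functionals are sensitive to the limiting
  coefficients at the second decimal: rounding them to two decimals before
  evaluating shifts several functionals by about $0.01$, so the package
  always evaluates limits at full precision.
* **`sim1A`–`sim1C`** — $X_1 \sim U(1, 4)$, $X_2 \sim \mathrm{Poisson}(3)$,
  $X_3 \sim \mathrm{Bernoulli}(0.4)$ with quadratic logistic PS and
  gaussian OR truths ($C$: cauchit PS and gamma OR). The coefficient
  vectors are mapped to terms variable-by-variable (intercept, $X_1$,
  $X_1^2$, $X_2$, $X_2^2$, $X_3$): this is the only mapping that keeps the
  propensity score bounded away from 0 and 1 — the alternatives place
  coefficients $0.7$ or $-0.9$ on a quadratic term and degenerate the
  design — and under it omitting one quadratic (Design A) produces the
  intended *mild* misspecification. The gaussian noise sd (1 by default)
  and gamma shape (2, with scale matched pointwise to the mean) are
  package choices; every limit and bias functional is invariant to the
  former.
* **`sim2A`–`sim2C`** — $X_1, X_2, X_4 \sim N(0,1)$, $X_3 \sim U(0,1)$
  with quadratic logistic PS and gaussian OR truths shared by all three;
  coefficients map to (intercept, first-order, quadratic) terms, which
  reproduces the marginal means $E[\mu_1(X)] = 3.533$,
  $E[\mu_0(X)] = 1.333$ analytically. Design A omits the quadratics;
  Designs B and C additionally collapse the regressors into sums. Overlap
  is deliberately poor in the tails, which is what makes the simple IPW
  bias large here.
* **`sim3A`–`sim3C`** — correlated bivariate-normal pairs
  $(X_1, X_2) \sim N_2((2,4), \Sigma)$,
  $(X_3, X_4) \sim N_2((4,2), \Sigma)$ with
  $\Sigma = \begin{pmatrix}1 & 0.2\\ 0.2 & 1\end{pmatrix}$, plus
  $X_5 = X_1^2$; logistic PS with design-specific coefficients giving good
  (A) to poor (C) overlap; Poisson outcome with an **identity** link
  (marginal means $9.9$ and $8.9$ analytically), so the OR truth is a count
  model whose mean is linear. Misspecified models replace the covariates
  with nonlinear transforms $M_1 = \exp(0.1 X_1)$,
  $M_2 = X_2(1 + X_1) + 10$, $M_3 = (0.04X_3 + 0.6)^2$,
  $M_4 = (X_4 + 20)^2$. Design C's near-one propensity scores make the
  control-arm ratio $r_0$ explode, which is exactly the mechanism by which
  lack of overlap converts model error into bias.

`sample_design()` draws i.i.d. rows $X$, $T \mid X \sim
\mathrm{Bernoulli}(e(X))$, $Y(t) \mid X$ from the outcome family with mean
$\mu_t(X)$, and $Y = T\,Y(1) + (1 - T)\,Y(0)$, keeping both potential
outcomes and the true propensity alongside — simulation-only luxuries that
make every downstream claim testable. What the generator deliberately does
*not* emulate: unmeasured confounding, measurement error, missingness,
clustering, or treatment-effect heterogeneity beyond what the two mean
surfaces encode. Passing tests therefore certify the estimators and the
bias calculus under the stated laws, not robustness to those further
real-data complications.

## Numerical choices

* **Quadrature.** Gauss–Legendre nodes for uniform components and
  Gauss–Hermite for normal ones: 201 nodes for a single continuous
  dimension, 35 per dimension in products (exact for the polynomial
  surfaces used here and accurate to ~$10^{-7}$ for the ratio functionals,
  cross-checked against adaptive integration in the tests). Poisson
  components are truncated at cumulative mass $1 - 10^{-9}$: beyond that,
  tail counts saturate any fitted logistic surface to exactly 0/1 in double
  precision while contributing nothing to the integrals. Bernoulli
  components are enumerated.
* **Fitting.** IRLS with relative tolerance $10^{-10}$ and at most 100
  iterations; non-convergence and separation are flagged, never silently
  returned. Identity-link Poisson/gamma fits start from the weighted
  least-squares solution to keep the mean admissible.
* **Positivity.** Estimated propensity scores are clipped nowhere; values
  reaching 0/1 raise errors. Overlap under misspecification is checked on a
  fixed-seed sample of the covariate law (its effective support) rather
  than on quadrature tail nodes.
* **Seeds.** Every stochastic routine takes an explicit seed; replicate $r$
  of a Monte-Carlo study uses `base_seed + r`, and identical inputs
  reproduce every draw bit for bit.
* **Standard errors.** The sandwich route stacks the estimating equations
  for $(\mu_1, \mu_0, \beta)$ — plus the arm-wise outcome scores for AIPW —
  and differentiates the stacked system numerically (central differences);
  working-model parameters are treated as estimated, not plugged in as
  known. The bootstrap refits every working model per resample and errors
  out if more than 5% of refits fail. The two agree within 15% on the
  designs tested.
* **Large-sample approximation.** `run_asymptotic_approximation()` fits the
  misspecified models on one $N = 10^6$ sample and evaluates the
  functionals as empirical means over the same sample by default (a
  `fresh_sample` switch is provided); it also reports the realized
  estimator biases with influence-function Monte-Carlo standard errors. At
  $N = 10^6$ the functional means carry a Monte-Carlo standard error of
  roughly $0.005$ and the realized estimator biases roughly $0.015$ on the
  `sim2A` design; numbers quoted at three decimals from a single run should
  be read with that granularity in mind.

## Problem sizes used by the test suite

The tests run the full pipeline at reduced but statistically meaningful
sizes: working-model consistency at $n = 2\times 10^5$, quadrature–Monte
Carlo agreement at $n = 2\times 10^5$, one $N = 10^6$ large-sample
approximation, and a correct-specification study at $n = 5000$ with 1000
replicates. Monte-Carlo assertions use four standard-error tolerances
computed from the runs themselves.

## Known limitations

* The calculus targets probability limits; finite-sample bias (exact
  expectations) is out of scope, and at small $n$ with poor overlap the
  realized orderings can differ from the asymptotic ones.
* The quadrature route requires a product law; dependent covariate blocks
  (the `sim3` designs) use Monte-Carlo integration and large-sample fits.
* Only the catalogued parametric families (binomial logit/probit/cauchit;
  gaussian, Poisson, gamma with identity/log links) are supported;
  regularized, nonparametric, or balancing-weight approaches are
  deliberately out of scope, as are trimmed or stabilized weights — the
  point of the package is the untrimmed estimators' behaviour.
* The upper-bound comparison condition discussed above is reported as
  catalogued but is not a mathematically sufficient condition; rely on the
  interval condition (an equivalence) or on the reported realized
  orderings.
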