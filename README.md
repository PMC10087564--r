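# ipwbias

Large-sample bias of IPW and AIPW estimators of average causal effects
when **all** working models are misspecified.

## The problem

Semiparametric estimators of the average causal effect
Δ = E[Y(1) − Y(0)] lean on parametric working models for the propensity
score e(X) = P(T = 1 | X) and/or the outcome regressions
μ_t(X) = E[Y(t) | X]. In observational practice those models are
confounding-adjustment devices, not credible descriptions of the
data-generating process — so the realistic regime is the one in which the
propensity model *and* the outcome models are wrong. A misspecified
quasi-maximum-likelihood fit still converges to well-defined limiting
coefficients, hence to limiting surfaces e\*(X) and μ_t\*(X), and each
estimator converges to a limit that is generally not Δ.

`ipwbias` implements that misspecification calculus for three prototypical
estimators — the simple (Horvitz–Thompson) IPW estimator Δ̂\_IPW1, the
normalized (Hájek) IPW estimator Δ̂\_IPW2, and the doubly robust augmented
IPW estimator Δ̂\_AIPW. Writing r₁(X) = e(X)/e\*(X) and
r₀(X) = (1 − e(X))/(1 − e\*(X)) for the propensity-model ratios, the
large-sample biases are

    Bias(IPW1) = E[r₁ μ₁(X)] − E[r₀ μ₀(X)] − (μ₁ − μ₀)
    Bias(IPW2) = E[r₁ μ₁(X)]/E[r₁] − E[r₀ μ₀(X)]/E[r₀] − (μ₁ − μ₀)
    Bias(AIPW) = E[(r₁ − 1)(μ₁(X) − μ₁*(X))] − E[(r₀ − 1)(μ₀(X) − μ₀*(X))]

with arm-wise components satisfying, exactly,

    Bias₁(IPW1) = cov(r₁, μ₁(X)) + (E[r₁] − 1) μ₁
    Bias₁(IPW2) = cov(r₁, μ₁(X)) / E[r₁]

so normalization suppresses the level error (E[r₁] − 1) μ₁, and AIPW
trades the true surface μ₁(X) for the gap μ₁(X) − μ₁\*(X). The package
evaluates these functionals (by Gauss–Legendre/Hermite quadrature for
product covariate laws, Monte Carlo otherwise), the probability limits
themselves (population score equations or large-sample fits), the
necessary/sufficient conditions that order the estimators' component
biases, the estimators with sandwich/bootstrap standard errors, overlap
and balance diagnostics, and replication engines for finite-sample and
large-sample studies. A catalogue of data-generating designs
(`make_design()`) makes everything runnable without any external data.

## Worked example

The one-covariate analytic design: X ~ Uniform(−2, 2), logistic truth
e(X) = {1 + exp(1 + 0.5X − 0.1X²)}⁻¹, treated-arm outcome surface
μ₁(X) = 3.5 + X + 0.7X², with working models that omit the quadratic
term in both the propensity and the outcome model.

```r
library(ipwbias)

bundle <- make_design("example2")
pair   <- limit_pair(bundle)          # population-score limits e*, mu1*
dec    <- bias_functionals(pair, method = "quadrature")

glance(dec)
#> # A tibble: 1 × 6
#>   design   bias_ipw1 bias_ipw2 bias_aipw method     n_eval
#>   <chr>        <dbl>     <dbl>     <dbl> <chr>       <int>
#> 1 example2     0.149     0.108    0.0811 quadrature    201

dplyr::filter(tidy(dec), grepl("bias1|cov_ratio1|ratio1", parameter))
#> # A tibble: 6 × 2
#>   parameter            value
#>   <chr>                <dbl>
#> 1 bias1_ipw1          0.149
#> 2 bias1_ipw2          0.108
#> 3 bias1_aipw          0.0811
#> 4 ratio1_mean         1.01
#> 5 cov_ratio1_mu1      0.109
#> 6 cov_ratio1_mu1_star 0.0280
```

Reading: the misspecified propensity limit distorts the treated-arm
weights by the ratio r₁ with mean 1.009; the covariance between that
ratio and μ₁(X) is 0.109, so the simple IPW estimator picks up a
treated-arm bias of 0.149 while normalization shrinks it to
0.109/1.009 = 0.108 and the outcome augmentation shrinks it further to
0.081 — two wrong models beating one here, because the outcome
misspecification is moderate.

```r
dplyr::filter(condition_report(dec), arm == "treated")[, 1:3]
#>   condition                       holds ordering_holds
#> 1 normalization_reduces_bias      TRUE  TRUE
#> 2 aipw_vs_ipw1_necessary          TRUE  TRUE
#> 3 aipw_vs_ipw1_sufficient         TRUE  TRUE
#> 4 aipw_vs_ipw2_necessary_interval TRUE  TRUE
#> 5 aipw_vs_ipw2_sufficient         TRUE  TRUE

double_robustness_check(pair, method = "quadrature")
#> # A tibble: 3 × 2
#>   scenario          bias_aipw
#>   <chr>                 <dbl>
#> 1 ps_corrected         0
#> 2 or_corrected         0
#> 3 both_misspecified    0.0811
```

The applied workflow on any dataset (CSV path or data frame):

```r
s <- sample_design(make_design("sim2A")$design, n = 1392, seed = 23)
applied_analysis(s, ps_formula = T ~ X1 + X2 + X3,
                 or_formula = Y ~ X1 + X3 + X4, se_method = "sandwich")
#> <applied_analysis>
#>   estimator estimate    se conf.low conf.high
#> 1      ipw1     3.11 0.243     2.63      3.59
#> 2      ipw2     2.60 0.141     2.32      2.88
#> 3      aipw     2.61 0.132     2.35      2.87
#> Balance: 1 of 4 covariates above the |SMD| threshold.
```

(The true effect in this design is Δ = 2.2; the quadratic-omission
misspecification biases all three estimators upward, the simple IPW
estimator most.)

`autoplot()` methods draw the bias decomposition, the mirror overlap
histogram and a balance (love) plot; `plot_model_ratio()` draws e, e\*,
their ratio and the outcome surfaces for one-covariate designs. A thin
command-line wrapper lives in `inst/cli/causalbias.R` with subcommands
`estimate`, `bias-report`, `simulate` and `asymptotic`.

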