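# The bias calculus: probability-limit biases of the three estimators when
# the working models are misspecified, their arm-wise components, the
# covariance decompositions, and the necessary/sufficient comparison
# conditions.
#
# Notation (treated arm): r1 = e(X)/e*(X) is the PS-model ratio, the
# multiplicative error of the limiting misspecified propensity model;
# r0 = (1-e(X))/(1-e*(X)) is its control-arm counterpart. The large-sample
# biases are
#   Bias(IPW1) = E[r1 mu1(X)] - E[r0 mu0(X)] - (mu1 - mu0)
#   Bias(IPW2) = E[r1 mu1(X)]/E[r1] - E[r0 mu0(X)]/E[r0] - (mu1 - mu0)
#   Bias(AIPW) = E[(r1 - 1)(mu1(X) - mu1*(X))] - E[(r0 - 1)(mu0(X) - mu0*(X))]
# and Bias1/Bias2 are the treated/control-arm components, signed so that
# Bias = Bias1 + Bias2 exactly for each estimator.

#' Pair a truth with its misspecified limiting models
#'
#' Bundles a [population_design()] (housing e(X) and mu_t(X)) with limiting
#' misspecified models e*(X) and mu_t*(X). Overlap under misspecification --
#' e*(X) bounded away from 0 and 1 -- is checked numerically on a probe set.
#'
#' @param design A [population_design()].
#' @param ps_limit A `working_model_limit` (or any fit) for the propensity
#'   model; its predictions are e*(X).
#' @param or0_limit,or1_limit Limiting outcome models per arm (mu_t*(X)).
#' @param check Check the misspecified-overlap assumption numerically.
#' @return Object of class `misspec_pair`.
#' @export
misspecified_pair <- function(design, ps_limit, or0_limit = NULL,
                              or1_limit = NULL, check = TRUE) {
  stopifnot(inherits(design, "population_design"),
            inherits(ps_limit, "working_model_fit"))
  if (check) {
    # probe the effective support of the law with a fixed-seed sample; tail
    # grid points of unbounded laws can push any logistic limit to 0/1 in
    # floating point without mattering for the functionals
    set.seed(20260101)
    probe <- sample_law(design$covariates, 1e4)
    es <- predict(ps_limit, probe)
    check_probability(es, what = "limiting misspecified e*(X)")
  }
  structure(list(design = design, ps_limit = ps_limit,
                 or0_limit = or0_limit, or1_limit = or1_limit),
            class = "misspec_pair")
}

#' Compute the misspecified limits for a registered design bundle
#'
#' Convenience wrapper: computes [limit_parameters()] for the bundle's
#' misspecified PS and OR specs and returns the [misspecified_pair()].
#'
#' @param bundle A [make_design()] bundle.
#' @param method,N,nodes,seed Passed to [limit_parameters()]; the default
#'   method is population-score quadrature when the covariate law supports
#'   it and a large-sample fit otherwise.
#' @return A `misspec_pair`.
#' @export
limit_pair <- function(bundle, method = NULL, N = 1e6, nodes = NULL, seed = 1) {
  stopifnot(inherits(bundle, "design_bundle"))
  method <- method %||%
    (if (law_has_quadrature(bundle$design$covariates)) "population_score" else "large_n_fit")
  lp <- function(spec) limit_parameters(bundle$design, spec, method = method,
                                        N = N, nodes = nodes, seed = seed)
  misspecified_pair(bundle$design,
                    ps_limit = lp(bundle$misspec$ps),
                    or0_limit = lp(bundle$misspec$or0),
                    or1_limit = lp(bundle$misspec$or1))
}

# Evaluation set (points + probability weights) for population expectations.
bias_eval_set <- function(pair, method, nodes, n, seed, points = NULL,
                          weights = NULL) {
  if (!is.null(points)) {
    w <- weights %||% rep(1 / nrow(points), nrow(points))
    return(list(X = points, w = w, method = "montecarlo", n = nrow(points)))
  }
  law <- pair$design$covariates
  if (method == "auto") {
    method <- if (law_has_quadrature(law)) "quadrature" else "montecarlo"
  }
  if (method == "quadrature") {
    g <- quad_grid(law, nodes = nodes)
    list(X = g$points, w = g$weights, method = "quadrature", n = nrow(g$points))
  } else {
    set.seed(as.integer(seed))
    X <- sample_law(law, n)
    list(X = X, w = rep(1 / n, n), method = "montecarlo", n = n)
  }
}

# All ingredient surfaces evaluated on a point set.
pair_surfaces <- function(pair, X) {
  e <- ps_eval(pair$design$ps, X)
  es <- predict(pair$ps_limit, X)
  check_probability(es, what = "e*(X) on the evaluation set")
  list(
    e = e, es = es,
    mu1 = mu_eval(pair$design$outcome, X, 1L),
    mu0 = mu_eval(pair$design$outcome, X, 0L),
    mu1s = if (!is.null(pair$or1_limit)) predict(pair$or1_limit, X),
    mu0s = if (!is.null(pair$or0_limit)) predict(pair$or0_limit, X)
  )
}

#' Large-sample bias functionals of the (A)IPW estimators
#'
#' Evaluates, as population expectations under the covariate law, the
#' probability-limit biases of the three estimators, their treated-arm
#' (Bias1) and control-arm (Bias2) components, the PS-model ratio means,
#' the covariances between the ratios and the true/misspecified conditional
#' outcomes, and the scaled-product ingredients of the comparison
#' conditions. Bias2 is signed as the control-arm contribution to total
#' bias, so `bias = bias1 + bias2` holds exactly for every estimator.
#'
#' @param pair A [misspecified_pair()].
#' @param method `"auto"`, `"quadrature"` (product laws) or `"montecarlo"`.
#' @param nodes Quadrature nodes per continuous dimension.
#' @param n Monte Carlo draws.
#' @param seed Monte Carlo seed.
#' @param points,weights Optional explicit evaluation set (used to evaluate
#'   the functionals on an existing large sample).
#' @return Object of class `bias_decomposition`: a named list of
#'   functionals; see [tidy.bias_decomposition()].
#' @export
bias_functionals <- function(pair, method = c("auto", "quadrature", "montecarlo"),
                             nodes = NULL, n = 1e6, seed = 1, points = NULL,
                             weights = NULL) {
  stopifnot(inherits(pair, "misspec_pair"))
  method <- match.arg(method)
  ev <- bias_eval_set(pair, method, nodes, n, seed, points, weights)
  sf <- pair_surfaces(pair, ev$X)
  E <- function(v) sum(ev$w * v)
  r1 <- sf$e / sf$es
  r0 <- (1 - sf$e) / (1 - sf$es)
  mu1 <- E(sf$mu1)
  mu0 <- E(sf$mu0)
  R1 <- E(r1)
  R0 <- E(r0)
  have_or <- !is.null(sf$mu1s) && !is.null(sf$mu0s)
  out <- list(
    mu1 = mu1, mu0 = mu0, delta = mu1 - mu0,
    mu1_star = if (have_or) E(sf$mu1s) else NA_real_,
    mu0_star = if (have_or) E(sf$mu0s) else NA_real_,
    ratio1_mean = R1, ratio0_mean = R0,
    cov_ratio1_mu1 = E(r1 * sf$mu1) - R1 * mu1,
    cov_ratio0_mu0 = E(r0 * sf$mu0) - R0 * mu0,
    cov_ratio1_mu1_star = if (have_or) E(r1 * sf$mu1s) - R1 * E(sf$mu1s) else NA_real_,
    cov_ratio0_mu0_star = if (have_or) E(r0 * sf$mu0s) - R0 * E(sf$mu0s) else NA_real_,
    # E[(r - 1) mu(X)] products and the (E[r] - 1) * mu scalings
    e_term_mu1 = E((r1 - 1) * sf$mu1),
    e_term_mu0 = E((r0 - 1) * sf$mu0),
    e_term_mu1_star = if (have_or) E((r1 - 1) * sf$mu1s) else NA_real_,
    e_term_mu0_star = if (have_or) E((r0 - 1) * sf$mu0s) else NA_real_,
    e_scaled_mu1 = (R1 - 1) * mu1,
    e_scaled_mu0 = (R0 - 1) * mu0,
    # component biases, Eqs (7)-(9) and control-arm mirrors
    bias1_ipw1 = E(r1 * sf$mu1) - mu1,
    bias1_ipw2 = E(r1 * sf$mu1) / R1 - mu1,
    bias1_aipw = if (have_or) E((r1 - 1) * (sf$mu1 - sf$mu1s)) else NA_real_,
    bias2_ipw1 = -(E(r0 * sf$mu0) - mu0),
    bias2_ipw2 = -(E(r0 * sf$mu0) / R0 - mu0),
    bias2_aipw = if (have_or) -E((r0 - 1) * (sf$mu0 - sf$mu0s)) else NA_real_,
    # total biases, Eqs (4)-(6), computed directly from their definitions
    bias_ipw1 = E(r1 * sf$mu1) - E(r0 * sf$mu0) - (mu1 - mu0),
    bias_ipw2 = E(r1 * sf$mu1) / R1 - E(r0 * sf$mu0) / R0 - (mu1 - mu0),
    bias_aipw = if (have_or) {
      E((sf$e - sf$es) * (sf$mu1 - sf$mu1s) / sf$es) +
        E((sf$e - sf$es) * (sf$mu0 - sf$mu0s) / (1 - sf$es))
    } else NA_real_
  )
  structure(c(out, list(method = ev$method, n_eval = ev$n,
                        design = pair$design$name)),
            class = "bias_decomposition")
}

decomposition_parameters <- c(
  "mu1", "mu1_star", "mu0", "mu0_star",
  "bias_ipw1", "bias_ipw2", "bias_aipw",
  "bias1_ipw1", "bias1_ipw2", "bias1_aipw",
  "ratio1_mean", "cov_ratio1_mu1", "cov_ratio1_mu1_star",
  "e_scaled_mu1", "e_term_mu1", "e_term_mu1_star",
  "bias2_ipw1", "bias2_ipw2", "bias2_aipw",
  "ratio0_mean", "cov_ratio0_mu0", "cov_ratio0_mu0_star",
  "e_scaled_mu0", "e_term_mu0", "e_term_mu0_star"
)

#' @rdname tidy.ace_estimate
#' @method tidy bias_decomposition
#' @export
tidy.bias_decomposition <- function(x, ...) {
  tibble(parameter = decomposition_parameters,
         value = vapply(decomposition_parameters, function(p) x[[p]], numeric(1)))
}

#' @rdname tidy.ace_estimate
#' @method glance bias_decomposition
#' @export
glance.bias_decomposition <- function(x, ...) {
  tibble(design = x$design, bias_ipw1 = x$bias_ipw1, bias_ipw2 = x$bias_ipw2,
         bias_aipw = x$bias_aipw, method = x$method, n_eval = x$n_eval)
}

#' @export
print.bias_decomposition <- function(x, ...) {
  cat("<bias_decomposition> design:", x$design, " method:", x$method,
      " (n =", x$n_eval, ")\n")
  print(as.data.frame(tidy(x)), digits = 4)
  invisible(x)
}

#' Double-robustness verification
#'
#' Recomputes the AIPW bias functional with (a) the propensity limit
#' replaced by the truth, (b) the outcome limits replaced by the truth, and
#' (c) both models misspecified. (a) and (b) must be zero: correcting either
#' model removes the AIPW large-sample bias.
#'
#' @inheritParams bias_functionals
#' @return Tibble with `scenario` and `bias_aipw`.
#' @export
double_robustness_check <- function(pair, method = "auto", nodes = NULL,
                                    n = 1e6, seed = 1) {
  stopifnot(inherits(pair, "misspec_pair"))
  ev <- bias_eval_set(pair, match.arg(method, c("auto", "quadrature", "montecarlo")),
                      nodes, n, seed)
  sf <- pair_surfaces(pair, ev$X)
  if (is.null(sf$mu1s) || is.null(sf$mu0s)) {
    abort("Both outcome limits are required for the double-robustness check.")
  }
  E <- function(v) sum(ev$w * v)
  bias_aipw <- function(e, es, mu1, mu1s, mu0, mu0s) {
    E((e - es) * (mu1 - mu1s) / es) + E((e - es) * (mu0 - mu0s) / (1 - es))
  }
  tibble(
    scenario = c("ps_corrected", "or_corrected", "both_misspecified"),
    bias_aipw = c(
      bias_aipw(sf$e, sf$e, sf$mu1, sf$mu1s, sf$mu0, sf$mu0s),
      bias_aipw(sf$e, sf$es, sf$mu1, sf$mu1, sf$mu0, sf$mu0),
      bias_aipw(sf$e, sf$es, sf$mu1, sf$mu1s, sf$mu0, sf$mu0s)
    )
  )
}

# Condition evaluations for one arm given (a, b, cv, R, bias1_ipw1/2/aipw).
arm_conditions <- function(a, b, cv, R, b1_ipw1, b1_ipw2, b1_aipw, arm) {
  same_sign <- function(u, v) (u > 0 && v > 0) || (u < 0 && v < 0)
  tibble(
    arm = arm,
    condition = c("normalization_reduces_bias",
                  "aipw_vs_ipw1_necessary",
                  "aipw_vs_ipw1_sufficient",
                  "aipw_vs_ipw2_necessary_interval",
                  "aipw_vs_ipw2_sufficient"),
    holds = c(
      abs(cv) < R * abs(b1_ipw1),
      abs(b) < 2 * abs(a),
      abs(b) < 2 * abs(a) && same_sign(a, b),
      (a - abs(cv) / R < b) && (b < a + abs(cv) / R),
      same_sign(a, cv) && abs(b) < abs(a) + abs(cv) / R
    ),
    lhs = c(abs(cv), abs(b), abs(b), a - abs(cv) / R, abs(b)),
    rhs = c(R * abs(b1_ipw1), 2 * abs(a), 2 * abs(a), a + abs(cv) / R,
            abs(a) + abs(cv) / R),
    implied_ordering = c("|Bias1(IPW2)| < |Bias1(IPW1)|",
                         "|Bias1(AIPW)| < |Bias1(IPW1)|",
                         "|Bias1(AIPW)| < |Bias1(IPW1)|",
                         "|Bias1(AIPW)| < |Bias1(IPW2)|",
                         "|Bias1(AIPW)| < |Bias1(IPW2)|"),
    ordering_holds = c(
      abs(b1_ipw2) < abs(b1_ipw1),
      rep(abs(b1_aipw) < abs(b1_ipw1), 2),
      rep(abs(b1_aipw) < abs(b1_ipw2), 2)
    )
  )
}

#' Evaluate the bias-comparison conditions
#'
#' Evaluates, from a [bias_functionals()] decomposition alone, the
#' sufficient-and-necessary condition under which normalization reduces the
#' treated-arm component bias, the necessary and sufficient conditions for
#' the AIPW component bias to be smaller than the simple IPW one, and the
#' interval (necessary) and sufficient conditions for AIPW versus the
#' normalized IPW estimator -- together with the realized component-bias
#' orderings. The control-arm mirrors (replace the ratio e/e* by
#' (1-e)/(1-e*) and mu1 by mu0) are reported as `arm = "control"`.
#'
#' @param decomposition A `bias_decomposition`.
#' @return A tibble of class `condition_report` with one row per condition
#'   and arm: the verdict (`holds`), its numeric ingredients (`lhs`, `rhs`)
#'   and the realized component-bias ordering it speaks to.
#' @export
condition_report <- function(decomposition) {
  stopifnot(inherits(decomposition, "bias_decomposition"))
  d <- decomposition
  out <- dplyr::bind_rows(
    arm_conditions(d$e_term_mu1, d$e_term_mu1_star, d$cov_ratio1_mu1,
                   d$ratio1_mean, d$bias1_ipw1, d$bias1_ipw2, d$bias1_aipw,
                   arm = "treated"),
    arm_conditions(d$e_term_mu0, d$e_term_mu0_star, d$cov_ratio0_mu0,
                   d$ratio0_mean, -d$bias2_ipw1, -d$bias2_ipw2, -d$bias2_aipw,
                   arm = "control")
  )
  class(out) <- c("condition_report", class(out))
  out
}

#' Empirical cross-check of the bias functionals
#'
#' Draws one large sample from the design, applies each estimator using the
#' limiting models' predictions (not refitted), and returns the realized
#' deviation from the true average causal effect together with its
#' Monte-Carlo standard error. By construction this should agree with
#' [bias_functionals()] within Monte-Carlo error.
#'
#' @inheritParams bias_functionals
#' @param n Sample size (>= 1e5 recommended).
#' @return Tibble with `estimator`, `bias`, `mc_se`.
#' @export
empirical_bias_oracle <- function(pair, n = 1e6, seed = 1) {
  stopifnot(inherits(pair, "misspec_pair"))
  s <- sample_design(pair$design, n, seed)
  sf <- pair_surfaces(pair, s)
  delta <- true_mean_effect(pair$design, method = "auto", n = n,
                            seed = seed + 1)$delta
  t <- s$T
  y <- s$Y
  have_or <- !is.null(sf$mu1s) && !is.null(sf$mu0s)
  inf1 <- t * y / sf$es - (1 - t) * y / (1 - sf$es)
  ests <- list(
    ipw1 = delta_ipw1(t, y, sf$es),
    ipw2 = delta_ipw2(t, y, sf$es),
    aipw = if (have_or) delta_aipw(t, y, sf$es, sf$mu0s, sf$mu1s) else NA_real_
  )
  infa <- if (have_or) {
    (t * y - (t - sf$es) * sf$mu1s) / sf$es -
      ((1 - t) * y + (t - sf$es) * sf$mu0s) / (1 - sf$es)
  } else rep(NA_real_, n)
  w1 <- t / sf$es
  w0 <- (1 - t) / (1 - sf$es)
  inf2 <- w1 * (y - sum(w1 * y) / sum(w1)) / mean(w1) -
    w0 * (y - sum(w0 * y) / sum(w0)) / mean(w0)
  tibble(
    estimator = c("ipw1", "ipw2", "aipw"),
    bias = c(ests$ipw1 - delta, ests$ipw2 - delta, ests$aipw - delta),
    mc_se = c(sd(inf1), sd(inf2), sd(infa)) / sqrt(n)
  )
}
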