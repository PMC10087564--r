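# The bias calculus: functionals against an independent adaptive-quadrature
# oracle, exact algebraic identities, double robustness, and the comparison
# conditions.

# Independent oracle for the one-covariate analytic design: adaptive
# integration with stats::integrate over the printed model forms, nothing
# shared with the package's Gauss-Legendre path.
example2_oracle <- function() {
  e <- function(x) 1 / (1 + exp(1 + 0.5 * x - 0.1 * x^2))
  es <- function(x) 1 / (1 + exp(0.87 + 0.52 * x))
  mu1 <- function(x) 3.5 + x + 0.7 * x^2
  mu1s <- function(x) 4.42 + 0.76 * x
  E <- function(f) stats::integrate(function(x) f(x) / 4, -2, 2,
                                    rel.tol = 1e-10)$value
  r1 <- function(x) e(x) / es(x)
  m1 <- E(mu1)
  R1 <- E(r1)
  list(
    ratio1_mean = R1,
    mu1 = m1,
    cov_ratio1_mu1 = E(function(x) r1(x) * mu1(x)) - R1 * m1,
    cov_ratio1_mu1_star = E(function(x) r1(x) * mu1s(x)) - R1 * E(mu1s),
    bias1_ipw1 = E(function(x) r1(x) * mu1(x)) - m1,
    bias1_ipw2 = E(function(x) r1(x) * mu1(x)) / R1 - m1,
    bias1_aipw = E(function(x) (r1(x) - 1) * (mu1(x) - mu1s(x))),
    e_term_mu1_star = E(function(x) (r1(x) - 1) * mu1s(x))
  )
}

printed_example2_pair <- function() {
  b <- make_design("example2")
  misspecified_pair(
    b$design,
    ps_limit = limit_model(b$misspec$ps, c(0.87, 0.52)),
    or0_limit = limit_model(b$misspec$or0, c(0, 0)),
    or1_limit = limit_model(b$misspec$or1, c(4.42, 0.76))
  )
}

test_that("Gauss-Legendre functionals match an independent adaptive oracle", {
  d <- bias_functionals(printed_example2_pair(), method = "quadrature")
  orc <- example2_oracle()
  for (nm in names(orc)) {
    expect_equal(d[[nm]], orc[[nm]], tolerance = 1e-7, label = nm)
  }
})

test_that("the component-bias identities hold to numerical precision", {
  pairs <- list(
    quad = bias_functionals(limit_pair(make_design("example2")), method = "quadrature"),
    mc = bias_functionals(limit_pair(make_design("sim2A")), method = "montecarlo",
                          n = 5e4, seed = 3)
  )
  for (d in pairs) {
    # Bias1(IPW1) = cov(r1, mu1) + (E[r1] - 1) mu1
    expect_equal(d$bias1_ipw1, d$cov_ratio1_mu1 + (d$ratio1_mean - 1) * d$mu1,
                 tolerance = 1e-10)
    # Bias1(IPW2) = cov(r1, mu1) / E[r1]
    expect_equal(d$bias1_ipw2, d$cov_ratio1_mu1 / d$ratio1_mean,
                 tolerance = 1e-10)
    # additivity: total bias = treated + control components, per estimator
    expect_equal(d$bias_ipw1, d$bias1_ipw1 + d$bias2_ipw1, tolerance = 1e-10)
    expect_equal(d$bias_ipw2, d$bias1_ipw2 + d$bias2_ipw2, tolerance = 1e-10)
    expect_equal(d$bias_aipw, d$bias1_aipw + d$bias2_aipw, tolerance = 1e-10)
    # scaled-product identity E[(r1 - 1) mu1(X)] = Bias1(IPW1)
    expect_equal(d$e_term_mu1, d$bias1_ipw1, tolerance = 1e-10)
  }
})

test_that("a correctly specified propensity limit gives zero IPW bias", {
  b <- make_design("example2")
  pair <- misspecified_pair(
    b$design,
    ps_limit = limit_parameters(b$design, b$true_specs$ps, method = "population_score"),
    or0_limit = limit_model(b$misspec$or0, c(0, 0)),
    or1_limit = limit_model(b$misspec$or1, c(4.42, 0.76))
  )
  d <- bias_functionals(pair, method = "quadrature")
  expect_equal(d$bias_ipw1, 0, tolerance = 1e-8)
  expect_equal(d$bias_ipw2, 0, tolerance = 1e-8)
  expect_equal(d$bias_aipw, 0, tolerance = 1e-8)  # double robustness, PS side
})

test_that("constant mu1 makes the normalized IPW treated component vanish", {
  des <- toy_constant_mu1_design()
  spec <- wm_spec("ps", c("1", "X"))  # omits the quadratic: misspecified
  pair <- misspecified_pair(
    des,
    ps_limit = limit_parameters(des, spec, method = "population_score"),
    or0_limit = limit_model(wm_spec("or0", c("1", "X")), c(1, 1)),
    or1_limit = limit_model(wm_spec("or1", c("1", "X")), c(5, 0))
  )
  d <- bias_functionals(pair, method = "quadrature")
  expect_gt(abs(d$bias1_ipw1), 1e-4)      # the simple IPW component is not 0
  expect_equal(d$bias1_ipw2, 0, tolerance = 1e-12)
})

test_that("double robustness: correcting either model removes the AIPW bias", {
  pair <- limit_pair(make_design("example2"))
  dr <- double_robustness_check(pair, method = "quadrature")
  expect_equal(dr$bias_aipw[dr$scenario == "ps_corrected"], 0, tolerance = 1e-10)
  expect_equal(dr$bias_aipw[dr$scenario == "or_corrected"], 0, tolerance = 1e-10)
  expect_gt(abs(dr$bias_aipw[dr$scenario == "both_misspecified"]), 0.05)
  expect_equal(dr$bias_aipw[dr$scenario == "both_misspecified"],
               bias_functionals(pair, method = "quadrature")$bias_aipw,
               tolerance = 1e-10)
})

test_that("necessary/sufficient conditions are consistent with the realized orderings", {
  for (nm in c("example2", "sim1A", "sim1B", "sim2A", "sim2B", "sim2C")) {
    b <- make_design(nm)
    pair <- limit_pair(b, N = 2e5)
    d <- if (ipwbias:::law_has_quadrature(b$design$covariates)) {
      bias_functionals(pair, method = "quadrature")
    } else {
      bias_functionals(pair, method = "montecarlo", n = 2e5, seed = 1)
    }
    cr <- condition_report(d)
    # the AIPW-vs-IPW1 sufficient condition implies its ordering
    suff <- cr[cr$condition == "aipw_vs_ipw1_sufficient", ]
    expect_true(all(!suff$holds | suff$ordering_holds),
                label = paste(nm, "sufficient => ordering"))
    # realized orderings imply the necessary conditions
    nec <- cr[grepl("necessary", cr$condition), ]
    expect_true(all(!nec$ordering_holds | nec$holds),
                label = paste(nm, "ordering => necessary"))
    # the normalization condition and the AIPW-vs-IPW2 interval condition
    # are equivalences
    for (cond in c("normalization_reduces_bias", "aipw_vs_ipw2_necessary_interval")) {
      eqv <- cr[cr$condition == cond, ]
      expect_identical(eqv$holds, eqv$ordering_holds, label = paste(nm, cond))
    }
  }
})

test_that("quadrature and Monte Carlo functionals agree on product-law designs", {
  for (nm in c("example2", "sim1A")) {
    pair <- limit_pair(make_design(nm))
    q <- bias_functionals(pair, method = "quadrature")
    m <- bias_functionals(pair, method = "montecarlo", n = 2e5, seed = 7)
    expect_lt(abs(q$bias_ipw1 - m$bias_ipw1), 0.03)
    expect_lt(abs(q$bias_ipw2 - m$bias_ipw2), 0.03)
    expect_lt(abs(q$bias_aipw - m$bias_aipw), 0.03)
    expect_lt(abs(q$ratio1_mean - m$ratio1_mean), 0.02)
  }
})

test_that("the empirical oracle reproduces the analytic functionals", {
  pair <- limit_pair(make_design("example2"))
  d <- bias_functionals(pair, method = "quadrature")
  emp <- empirical_bias_oracle(pair, n = 2e5, seed = 3)
  analytic <- c(d$bias_ipw1, d$bias_ipw2, d$bias_aipw)
  expect_true(all(abs(emp$bias - analytic) < 4 * emp$mc_se))
  # correct-specification pair: realized bias is Monte-Carlo zero
  b <- make_design("example2")
  pair_true <- misspecified_pair(
    b$design,
    ps_limit = limit_parameters(b$design, b$true_specs$ps, method = "population_score"),
    or0_limit = limit_parameters(b$design, b$true_specs$or0, method = "population_score"),
    or1_limit = limit_parameters(b$design, b$true_specs$or1, method = "population_score")
  )
  emp_true <- empirical_bias_oracle(pair_true, n = 2e5, seed = 5)
  expect_true(all(abs(emp_true$bias) < 4 * emp_true$mc_se))
})

test_that("positivity failures in the limit model are reported", {
  des <- toy_constant_mu1_design()
  bad <- limit_model(wm_spec("ps", c("1", "X")), c(40, 0.1))
  expect_error(misspecified_pair(des, bad), "positivity|outside")
})
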