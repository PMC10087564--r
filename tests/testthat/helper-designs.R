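# Small synthetic designs used across the tests.

# Randomized design: constant propensity p, linear outcomes in one covariate.
toy_randomized_design <- function(p = 0.5) {
  population_design(
    "toy_randomized",
    covariate_law(cov_uniform("X", -1, 1)),
    ps_truth(linear_predictor("1", qlogis(p))),
    or_truth(linear_predictor(c("1", "X"), c(1, 1)),
             linear_predictor(c("1", "X"), c(3, 1)))
  )
}

# Degenerate effect: identical arms, so delta = 0.
toy_null_design <- function() {
  population_design(
    "toy_null",
    covariate_law(cov_uniform("X", 0, 1)),
    ps_truth(linear_predictor(c("1", "X"), c(-0.3, 0.6))),
    or_truth(linear_predictor(c("1", "X"), c(2, 1)),
             linear_predictor(c("1", "X"), c(2, 1)))
  )
}

# Constant treated-arm outcome with a misspecified PS: the normalized IPW
# treated-arm component bias must vanish identically.
toy_constant_mu1_design <- function() {
  population_design(
    "toy_constant_mu1",
    covariate_law(cov_uniform("X", -2, 2)),
    ps_truth(linear_predictor(c("1", "X", "I(X^2)"), c(0.2, 0.8, -0.3))),
    or_truth(linear_predictor(c("1", "X"), c(1, 1)),
             linear_predictor("1", 5))
  )
}

# A small i.i.d. dataset with known propensities for estimator arithmetic.
toy_sample <- function(n = 200, seed = 42, p = 0.4) {
  set.seed(seed)
  tibble::tibble(
    X = rnorm(n),
    T = rbinom(n, 1, p),
    Y = rnorm(n, 2 + X)
  )
}

expect_design_bundle <- function(b) {
  expect_s3_class(b, "design_bundle")
  expect_s3_class(b$design, "population_design")
  expect_s3_class(b$misspec$ps, "wm_spec")
}
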