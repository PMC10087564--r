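# Point estimators: exact arithmetic, algebraic identities, standard errors
# and the overlap/balance diagnostics.

test_that("estimators reproduce direct arithmetic on tiny samples", {
  d <- tibble::tibble(T = c(1, 0), Y = c(2, 1))
  expect_equal(ipw1(d, c(0.5, 0.5))$estimate, (4 - 2) / 2)
  expect_equal(ipw2(d, c(0.5, 0.5))$estimate, 1)
  d1 <- tibble::tibble(T = 1, Y = 5)
  expect_equal(aipw(d1, 0.5, mu0_hat = 1, mu1_hat = 3)$estimate,
               (5 - 0.5 * 3) / 0.5 - (0.5 * 1) / 0.5)
})

test_that("AIPW with zero augmentation equals simple IPW row for row", {
  s <- toy_sample(300)
  e <- plogis(0.3 * s$X)
  z <- rep(0, nrow(s))
  expect_identical(aipw(s, e, z, z)$estimate, ipw1(s, e)$estimate)
})

test_that("constant propensity collapses the Hajek estimator to arm means", {
  s <- toy_sample(251)
  arm_diff <- mean(s$Y[s$T == 1]) - mean(s$Y[s$T == 0])
  for (p in c(0.2, 0.5, 0.8)) {
    expect_equal(ipw2(s, rep(p, nrow(s)))$estimate, arm_diff, tolerance = 1e-12)
  }
  # randomized design with e = 0.5: ipw1 equals the 2TY identity
  expect_equal(ipw1(s, rep(0.5, nrow(s)))$estimate,
               mean(2 * s$T * s$Y) - mean(2 * (1 - s$T) * s$Y), tolerance = 1e-12)
})

test_that("outcome shifts: ipw2 is invariant, ipw1 shifts by the weight imbalance", {
  s <- toy_sample(400, seed = 9)
  e <- plogis(0.5 * s$X - 0.2)
  cshift <- 3.7
  s2 <- s
  s2$Y <- s$Y + cshift
  expect_equal(ipw2(s2, e)$estimate, ipw2(s, e)$estimate, tolerance = 1e-10)
  imbalance <- mean(s$T / e) - mean((1 - s$T) / (1 - e))
  expect_equal(ipw1(s2, e)$estimate, ipw1(s, e)$estimate + cshift * imbalance,
               tolerance = 1e-10)
})

test_that("positivity violations raise errors instead of being repaired", {
  s <- toy_sample(50)
  e <- rep(0.5, nrow(s))
  e[3] <- 0
  expect_error(ipw1(s, e), "positivity")
  e[3] <- 1
  expect_error(ipw2(s, e), "positivity")
  expect_error(aipw(s, e, e, e), "positivity")
  s_one_arm <- s
  s_one_arm$T <- 0
  expect_error(ipw2(s_one_arm, rep(0.4, nrow(s))), "non-empty")
})

test_that("sandwich and bootstrap standard errors agree on a sim2 sample", {
  b <- make_design("sim2A")
  s <- sample_design(b$design, 2000, seed = 11)
  ps_fit <- fit_ps(s, b$misspec$ps)
  or_fits <- list(or0 = fit_or(s, b$misspec$or0), or1 = fit_or(s, b$misspec$or1))
  for (est in c("ipw1", "ipw2", "aipw")) {
    sw <- standard_error(s, est, ps_fit, or_fits, method = "sandwich")
    bs <- standard_error(s, est, ps_fit, or_fits, method = "bootstrap",
                         B = 500, seed = 21)
    expect_gt(sw, 0)
    expect_lt(abs(sw - bs) / sw, 0.15)
  }
})

test_that("standard errors are scale equivariant and shrink like 1/sqrt(n)", {
  b <- make_design("sim2A")
  s <- sample_design(b$design, 1500, seed = 13)
  ps_fit <- fit_ps(s, b$misspec$ps)
  s_scaled <- s
  s_scaled$Y <- 10 * s$Y
  s_scaled$Y0 <- 10 * s$Y0
  s_scaled$Y1 <- 10 * s$Y1
  sw1 <- standard_error(s, "ipw1", ps_fit, method = "sandwich")
  sw10 <- standard_error(s_scaled, "ipw1", ps_fit, method = "sandwich")
  expect_equal(sw10, 10 * sw1, tolerance = 1e-6)
  bs1 <- standard_error(s, "ipw2", ps_fit, method = "bootstrap", B = 60, seed = 5)
  bs10 <- standard_error(s_scaled, "ipw2", ps_fit, method = "bootstrap",
                         B = 60, seed = 5)
  expect_equal(bs10, 10 * bs1, tolerance = 1e-10)

  # repeated-sampling check: doubling n shrinks the SE by about 1/sqrt(2)
  ratio <- mean(sapply(1:4, function(r) {
    sa <- sample_design(b$design, 1000, seed = 100 + r)
    sb <- sample_design(b$design, 2000, seed = 200 + r)
    standard_error(sb, "ipw2", fit_ps(sb, b$misspec$ps), method = "sandwich") /
      standard_error(sa, "ipw2", fit_ps(sa, b$misspec$ps), method = "sandwich")
  }))
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.15)
})

test_that("balance report handles exact balance and constant covariates", {
  d <- tibble::tibble(X = c(1, 1), W = c(2, 2), T = c(1, 0), Y = c(0, 0))
  br <- balance_report(d, c(0.5, 0.5))
  expect_equal(br$smd_unweighted, c(0, 0))
  expect_equal(br$smd_weighted, c(0, 0))
  expect_true(all(br$balanced))
})

test_that("true propensity weights balance the covariates", {
  s <- sample_design(make_design("sim2A")$design, 1e5, seed = 17)
  br <- balance_report(s, s$e_true)
  expect_true(all(abs(br$smd_weighted) < 0.05))
  expect_true(any(abs(br$smd_unweighted) > 0.2))  # confounding is real
})

test_that("overlap report counts positivity violations per arm", {
  s <- sample_design(make_design("sim2A")$design, 5000, seed = 19)
  ov <- overlap_report(s, s$e_true, threshold = 0.1)
  expect_equal(nrow(ov), 2)
  expect_true(all(ov$n_below + ov$n_above <= ov$n))
  expect_true(all(ov$min >= 0 & ov$max <= 1))
  strict <- overlap_report(s, s$e_true, threshold = 0.45)
  expect_true(all(strict$n_below >= ov$n_below))
})
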