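# Replication engines and the applied single-dataset workflow.

test_that("a smoke-sized study satisfies the exact MSE identity", {
  res <- run_finite_sample_study(make_design("sim2A"), n = 300, replications = 2,
                                 regime = "false", base_seed = 5)
  expect_s3_class(res, "simulation_result")
  draws <- attr(res, "draws")
  delta <- attr(res, "delta")
  for (i in seq_len(nrow(res))) {
    err <- draws[, res$estimator[i]] - delta
    expect_equal(res$mse[i], mean(err^2), tolerance = 1e-12)
    expect_equal(res$mse[i],
                 res$bias[i]^2 + res$sd[i]^2 * (nrow(draws) - 1) / nrow(draws),
                 tolerance = 1e-12)
    expect_gte(res$mse[i] + 1e-12, res$bias[i]^2)
  }
})

test_that("studies are bit-for-bit reproducible under the same base seed", {
  r1 <- run_finite_sample_study(make_design("sim1A"), n = 400, replications = 5,
                                regime = "true", base_seed = 42)
  r2 <- run_finite_sample_study(make_design("sim1A"), n = 400, replications = 5,
                                regime = "true", base_seed = 42)
  expect_identical(attr(r1, "draws"), attr(r2, "draws"))
  r3 <- run_finite_sample_study(make_design("sim1A"), n = 400, replications = 5,
                                regime = "true", base_seed = 43)
  expect_false(identical(attr(r1, "draws"), attr(r3, "draws")))
})

test_that("correctly specified fits are unbiased in a small study", {
  res <- run_finite_sample_study(make_design("sim2A"), n = 1000,
                                 replications = 80, regime = "true",
                                 base_seed = 7)
  expect_true(all(abs(res$bias) < 4 * res$mc_se_bias))
})

test_that("gamma/cauchit truths (sim1C) and dependent laws (sim3A) run end to end", {
  res <- run_finite_sample_study(make_design("sim1C"), n = 500, replications = 4,
                                 regime = "true", base_seed = 11)
  expect_true(all(is.finite(res$bias)))
  res3 <- run_finite_sample_study(make_design("sim3A"), n = 500, replications = 4,
                                  regime = "false", base_seed = 12)
  expect_true(all(is.finite(res3$bias)))
})

test_that("the large-sample approximation matches its own quadrature limits", {
  at <- run_asymptotic_approximation(make_design("example2"), N = 1e5, seed = 2)
  q <- bias_functionals(limit_pair(make_design("example2")), method = "quadrature")
  # functional rows on the N-sample vs population quadrature
  expect_lt(abs(at$decomposition$bias_ipw1 - q$bias_ipw1), 0.05)
  expect_lt(abs(at$decomposition$bias_aipw - q$bias_aipw), 0.05)
  # realized estimator biases agree with the functionals within 4 MC SEs
  expect_true(all(abs(at$realized$bias -
                        c(at$decomposition$bias_ipw1, at$decomposition$bias_ipw2,
                          at$decomposition$bias_aipw)) < 4 * at$realized$mc_se))
})

test_that("normalization and augmentation shrink the misspecification bias in sim1", {
  for (nm in c("sim1A", "sim1B")) {
    at <- run_asymptotic_approximation(make_design(nm), N = 2e5, seed = 3)
    b <- setNames(at$realized$bias, at$realized$estimator)
    expect_lt(abs(b["ipw2"]), abs(b["ipw1"]))
    expect_lt(abs(b["aipw"]), abs(b["ipw1"]))
  }
})

test_that("the applied workflow runs end to end on a generated CSV", {
  s <- sample_design(make_design("sim2A")$design, 1392, seed = 23)
  path <- file.path(tempdir(), "sim2_sample.csv")
  write_sample_csv(s[, c("X1", "X2", "X3", "X4", "T", "Y")], path)
  aa <- applied_analysis(path, ps_formula = T ~ X1 + X2 + X3,
                         or_formula = Y ~ X1 + X3 + X4, se_method = "sandwich")
  expect_equal(nrow(aa$estimates), 3)
  expect_true(all(is.finite(aa$estimates$se)))
  expect_true(all(aa$estimates$conf.low < aa$estimates$conf.high))
  expect_s3_class(aa$balance, "balance_report")
  expect_s3_class(aa$overlap, "overlap_report")
  unlink(path)
})

test_that("dropping the outcome model degenerates AIPW to simple IPW", {
  s <- sample_design(make_design("sim2A")$design, 800, seed = 29)
  aa <- applied_analysis(s, ps_formula = T ~ X1 + X2 + X3, or_formula = NULL,
                         se_method = "none")
  est <- setNames(aa$estimates$estimate, aa$estimates$estimator)
  expect_identical(est[["aipw"]], est[["ipw1"]])
})

test_that("factor covariates are expanded in the applied workflow", {
  s <- sample_design(make_design("sim2A")$design, 900, seed = 31)
  s$grp <- factor(sample(c("a", "b", "c"), nrow(s), replace = TRUE))
  aa <- applied_analysis(s, ps_formula = T ~ X1 + grp, or_formula = Y ~ X1 + grp,
                         se_method = "none")
  expect_equal(nrow(aa$estimates), 3)
  expect_true(any(grepl("grp", aa$balance$covariate)))
})

test_that("configuration errors in the applied workflow are informative", {
  s <- sample_design(make_design("sim2A")$design, 200, seed = 37)
  expect_error(applied_analysis(s, ps_formula = T ~ X1 + MISSING), "Missing covariate")
  s_bad <- s
  s_bad$T <- s_bad$T + 1
  expect_error(applied_analysis(s_bad, ps_formula = T ~ X1), "binary")
})

test_that("design bundles round-trip through YAML", {
  for (nm in c("example2", "sim3B")) {
    b <- make_design(nm)
    path <- file.path(tempdir(), paste0(nm, ".yaml"))
    design_to_yaml(b, path)
    b2 <- design_from_yaml(path)
    expect_identical(sample_design(b$design, 40, seed = 3),
                     sample_design(b2$design, 40, seed = 3))
    expect_identical(b$misspec$ps$terms, b2$misspec$ps$terms)
    unlink(path)
  }
})

test_that("result objects produce plots and tidy output", {
  pair <- limit_pair(make_design("example2"))
  d <- bias_functionals(pair, method = "quadrature")
  td <- tidy(d)
  expect_equal(nrow(td), 25)
  expect_s3_class(autoplot(d), "ggplot")
  expect_s3_class(plot_model_ratio(pair), "ggplot")
  s <- sample_design(make_design("sim2A")$design, 2000, seed = 41)
  expect_s3_class(autoplot(overlap_report(s, s$e_true)), "ggplot")
  expect_s3_class(autoplot(balance_report(s, s$e_true)), "ggplot")
})
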