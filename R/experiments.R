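# Replication engines: finite-sample Monte Carlo studies of the three
# estimators, the large-sample numerical approximation of their asymptotic
# biases, and the applied single-dataset workflow.

fit_working_set <- function(s, specs) {
  ps <- suppressWarnings(fit_ps(s, specs$ps))
  or0 <- suppressWarnings(fit_or(s, specs$or0))
  or1 <- suppressWarnings(fit_or(s, specs$or1))
  list(ps = ps, or0 = or0, or1 = or1)
}

estimators_on_sample <- function(s, fits) {
  e <- predict(fits$ps, s)
  if (any(e <= 0 | e >= 1)) abort("Fitted propensity scores reached 0/1.")
  m0 <- predict(fits$or0, s)
  m1 <- predict(fits$or1, s)
  c(ipw1 = delta_ipw1(s$T, s$Y, e),
    ipw2 = delta_ipw2(s$T, s$Y, e),
    aipw = delta_aipw(s$T, s$Y, e, m0, m1))
}

#' Finite-sample Monte Carlo study of the estimators
#'
#' Repeatedly draws samples of size `n` from a design, fits the working
#' models of the chosen regime (`"true"` = correctly specified formulas,
#' `"false"` = the bundle's misspecified ones), computes the three
#' estimators, and aggregates bias, SD and MSE against the true average
#' causal effect. Replicate r uses seed `base_seed + r`. Per-replicate fit
#' failures are counted; more than 1% aborts the run. Infinite or NaN
#' estimates (possible under extreme weights) propagate into the summary
#' cells rather than being dropped.
#'
#' @param bundle A [make_design()] bundle.
#' @param n Sample size per replicate.
#' @param replications Number of Monte Carlo replicates (>= 2).
#' @param regime `"false"` (misspecified working models) or `"true"`.
#' @param base_seed Base seed.
#' @return A tibble of class `simulation_result`: one row per estimator
#'   with `bias`, `sd`, `mse` and their Monte-Carlo standard errors.
#' @export
run_finite_sample_study <- function(bundle, n, replications = 1000,
                                    regime = c("false", "true"),
                                    base_seed = 1) {
  stopifnot(inherits(bundle, "design_bundle"), replications >= 2)
  regime <- match.arg(regime)
  specs <- if (regime == "true") bundle$true_specs else bundle$misspec
  delta <- true_mean_effect(bundle$design, method = "auto",
                            seed = base_seed)$delta
  draws <- matrix(NA_real_, nrow = replications, ncol = 3,
                  dimnames = list(NULL, c("ipw1", "ipw2", "aipw")))
  failures <- 0L
  for (r in seq_len(replications)) {
    res <- tryCatch({
      s <- sample_design(bundle$design, n, seed = base_seed + r)
      estimators_on_sample(s, fit_working_set(s, specs))
    }, error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else draws[r, ] <- res
  }
  if (failures > 0.01 * replications) {
    abort(sprintf("%d of %d replicates failed to fit (> 1%%); run aborted.",
                  failures, replications))
  }
  summarize_est <- function(est) {
    d <- draws[, est]
    err <- d - delta
    tibble(
      estimator = est,
      bias = mean(err, na.rm = TRUE),
      sd = sd(d, na.rm = TRUE),
      mse = mean(err^2, na.rm = TRUE),
      mc_se_bias = sd(d, na.rm = TRUE) / sqrt(sum(!is.na(d))),
      mc_se_mse = sd(err^2, na.rm = TRUE) / sqrt(sum(!is.na(d)))
    )
  }
  out <- dplyr::bind_rows(lapply(colnames(draws), summarize_est))
  out$design <- bundle$design$name
  out$regime <- regime
  out$n <- n
  out$replications <- replications
  out$failures <- failures
  attr(out, "delta") <- delta
  attr(out, "draws") <- draws
  class(out) <- c("simulation_result", class(out))
  out
}

#' Large-sample numerical approximation of the asymptotic biases
#'
#' Draws one sample of size `N` from the design, fits the bundle's
#' misspecified working models on it (the large-n route to the probability
#' limits), and evaluates the full bias decomposition -- every ratio mean,
#' covariance and component bias -- as empirical means over the same sample
#' (or a fresh one). The realized estimator biases (each estimator computed
#' on the sample with the fitted predictions, minus the true effect) are
#' reported alongside with influence-function Monte-Carlo standard errors.
#'
#' @param bundle A [make_design()] bundle.
#' @param N Approximation sample size (>= 1e5).
#' @param seed Seed.
#' @param fresh_sample Evaluate the functionals on a fresh sample (seed + 1)
#'   instead of the fitting sample.
#' @return Object of class `asymptotic_table` with elements `decomposition`
#'   (a [bias_functionals()] result), `realized` (tibble of realized
#'   estimator biases with `mc_se`), `fits`, `delta`, `N`, `seed`.
#' @export
run_asymptotic_approximation <- function(bundle, N = 1e6, seed = 1,
                                         fresh_sample = FALSE) {
  stopifnot(inherits(bundle, "design_bundle"))
  if (N < 1e5) abort("`N` must be at least 1e5 for the asymptotic approximation.")
  s <- sample_design(bundle$design, N, seed = seed)
  fits <- fit_working_set(s, bundle$misspec)
  pair <- misspecified_pair(bundle$design, fits$ps, fits$or0, fits$or1,
                            check = FALSE)
  ev <- if (fresh_sample) sample_design(bundle$design, N, seed = seed + 1) else s
  decomp <- bias_functionals(pair, points = ev[bundle$design$covariates$names])
  delta <- true_mean_effect(bundle$design, method = "auto", n = N,
                            seed = seed + 2)$delta
  e <- predict(fits$ps, ev)
  m0 <- predict(fits$or0, ev)
  m1 <- predict(fits$or1, ev)
  t <- ev$T
  y <- ev$Y
  w1 <- t / e
  w0 <- (1 - t) / (1 - e)
  inf <- cbind(
    ipw1 = t * y / e - (1 - t) * y / (1 - e),
    ipw2 = w1 * (y - sum(w1 * y) / sum(w1)) / mean(w1) -
      w0 * (y - sum(w0 * y) / sum(w0)) / mean(w0),
    aipw = (t * y - (t - e) * m1) / e - ((1 - t) * y + (t - e) * m0) / (1 - e)
  )
  realized <- tibble(
    estimator = c("ipw1", "ipw2", "aipw"),
    bias = c(delta_ipw1(t, y, e), delta_ipw2(t, y, e),
             delta_aipw(t, y, e, m0, m1)) - delta,
    mc_se = apply(inf, 2, sd) / sqrt(nrow(ev))
  )
  structure(list(design = bundle$design$name, decomposition = decomp,
                 realized = realized, fits = fits, delta = delta, N = N,
                 seed = seed),
            class = "asymptotic_table")
}

#' @rdname tidy.ace_estimate
#' @method tidy asymptotic_table
#' @export
tidy.asymptotic_table <- function(x, ...) tidy(x$decomposition)

#' @rdname tidy.ace_estimate
#' @method glance asymptotic_table
#' @export
glance.asymptotic_table <- function(x, ...) {
  tibble(design = x$design, N = x$N, seed = x$seed, delta = x$delta,
         bias_ipw1 = x$realized$bias[1], bias_ipw2 = x$realized$bias[2],
         bias_aipw = x$realized$bias[3])
}

#' @export
print.asymptotic_table <- function(x, ...) {
  cat("<asymptotic_table> design:", x$design, " N:", format(x$N, big.mark = ","), "\n")
  cat("Realized estimator biases (estimator on the N-sample minus true delta):\n")
  print(as.data.frame(x$realized), digits = 3)
  cat("Bias decomposition (plug-in functional means):\n")
  print(as.data.frame(tidy(x$decomposition)), digits = 3)
  invisible(x)
}

#' Applied (A)IPW analysis of a single dataset
#'
#' The observational-study workflow: fit a logistic propensity-score model
#' and (optionally) arm-wise linear outcome models from formulas, compute
#' the three estimators with standard errors and 95% confidence intervals,
#' and attach overlap and covariate-balance diagnostics. Factor covariates
#' are expanded to dummies internally. With `or_formula = NULL` the AIPW
#' augmentation is switched off (predictions identically zero), in which
#' case AIPW coincides with the simple IPW estimator.
#'
#' @param data A data frame, or path to a CSV file.
#' @param ps_formula Formula for the propensity model, e.g. `T ~ X1 + X2`.
#' @param or_formula Formula for the outcome models (fitted separately per
#'   arm), or `NULL` for no augmentation.
#' @param estimators Subset of `c("ipw1", "ipw2", "aipw")`.
#' @param se_method `"sandwich"`, `"bootstrap"` or `"none"`.
#' @param B,seed Bootstrap parameters.
#' @param treatment,outcome Column names (defaulted from the formulas).
#' @param balance_threshold,overlap_threshold Diagnostic thresholds.
#' @return A list of class `applied_analysis`: `estimates` (tibble shaped
#'   like a results table: estimator, estimate, s.e., 95% CI), `balance`,
#'   `overlap`, and the fitted working models.
#' @export
applied_analysis <- function(data, ps_formula, or_formula = NULL,
                             estimators = c("ipw1", "ipw2", "aipw"),
                             se_method = c("sandwich", "bootstrap", "none"),
                             B = 500, seed = 1,
                             treatment = NULL, outcome = NULL,
                             balance_threshold = 0.10,
                             overlap_threshold = 0.1) {
  se_method <- match.arg(se_method)
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (is.character(data)) data <- readr::read_csv(data, show_col_types = FALSE)
  data <- as_tibble(data)
  treatment <- treatment %||% all.vars(ps_formula)[1]
  outcome <- outcome %||% (if (!is.null(or_formula)) all.vars(or_formula)[1] else "Y")
  if (!treatment %in% names(data)) abort(sprintf("Treatment column '%s' missing.", treatment))
  if (!outcome %in% names(data)) abort(sprintf("Outcome column '%s' missing.", outcome))
  if (!all(data[[treatment]] %in% c(0, 1))) abort("Treatment must be binary 0/1.")

  # expand factors/characters into numeric dummy columns once, so working
  # model terms are plain numeric expressions
  rhs_vars <- union(all.vars(ps_formula)[-1],
                    if (!is.null(or_formula)) all.vars(or_formula)[-1] else character(0))
  missing_cols <- setdiff(rhs_vars, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Missing covariate column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  expand <- function(f) {
    mm <- model.matrix(stats::update(f, NULL ~ .), data = data)
    mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    colnames(mm) <- make.names(colnames(mm))
    mm
  }
  ps_mm <- expand(ps_formula)
  or_mm <- if (!is.null(or_formula)) expand(or_formula) else NULL
  work <- dplyr::bind_cols(
    data[c(treatment, outcome)],
    as_tibble(ps_mm),
    if (!is.null(or_mm)) as_tibble(or_mm[, setdiff(colnames(or_mm), colnames(ps_mm)), drop = FALSE])
  )
  ps_spec <- wm_spec("ps", c("1", colnames(ps_mm)), link = "logit")
  ps_fit <- fit_ps(work, ps_spec, treatment = treatment)
  e_hat <- predict(ps_fit, work)
  or_fits <- NULL
  if (!is.null(or_mm)) {
    or_fits <- list(
      or0 = fit_or(work, wm_spec("or0", c("1", colnames(or_mm))),
                   treatment = treatment, outcome = outcome),
      or1 = fit_or(work, wm_spec("or1", c("1", colnames(or_mm))),
                   treatment = treatment, outcome = outcome)
    )
    m0 <- predict(or_fits$or0, work)
    m1 <- predict(or_fits$or1, work)
  } else {
    m0 <- m1 <- rep(0, nrow(work))
  }
  one <- function(est) {
    obj <- switch(est,
      ipw1 = ipw1(work, e_hat, treatment = treatment, outcome = outcome),
      ipw2 = ipw2(work, e_hat, treatment = treatment, outcome = outcome),
      aipw = aipw(work, e_hat, m0, m1, treatment = treatment, outcome = outcome)
    )
    if (se_method != "none" && !(est == "aipw" && is.null(or_fits))) {
      obj$se <- standard_error(work, est, ps_fit, or_fits, method = se_method,
                               B = B, seed = seed, treatment = treatment,
                               outcome = outcome)
      obj$conf.low <- obj$estimate - 1.96 * obj$se
      obj$conf.high <- obj$estimate + 1.96 * obj$se
    }
    tidy(obj)
  }
  estimates <- dplyr::bind_rows(lapply(estimators, one))
  structure(list(
    estimates = estimates,
    balance = balance_report(work, e_hat, threshold = balance_threshold,
                             treatment = treatment, outcome = outcome),
    overlap = overlap_report(work, e_hat, threshold = overlap_threshold,
                             treatment = treatment),
    ps_fit = ps_fit, or_fits = or_fits
  ), class = "applied_analysis")
}

#' @export
print.applied_analysis <- function(x, ...) {
  cat("<applied_analysis>\n")
  print(as.data.frame(x$estimates), digits = 3)
  n_unbal <- sum(!x$balance$balanced)
  cat(sprintf("Balance: %d of %d covariates above the |SMD| threshold.\n",
              n_unbal, nrow(x$balance)))
  invisible(x)
}
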