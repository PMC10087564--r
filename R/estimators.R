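# Point estimators of the average causal effect: simple (Horvitz-Thompson)
# IPW, normalized (Hajek) IPW, and the prototypical augmented IPW (AIPW)
# doubly robust estimator, with sandwich and bootstrap standard errors.

validate_estimator_inputs <- function(data, e_hat, treatment, outcome,
                                      need_arms = TRUE) {
  t <- data[[treatment]]
  y <- data[[outcome]]
  if (is.null(t) || is.null(y)) {
    abort(sprintf("Columns '%s' and '%s' are required.", treatment, outcome))
  }
  if (!all(t %in% c(0, 1))) abort("Treatment must be binary 0/1.")
  if (length(e_hat) != nrow(data)) {
    abort("`e_hat` must have one propensity score per row.")
  }
  if (any(!is.finite(e_hat)) || any(e_hat <= 0) || any(e_hat >= 1)) {
    abort("Estimated propensity scores must lie strictly inside (0, 1): positivity fails.")
  }
  if (need_arms && (sum(t) == 0 || sum(1 - t) == 0)) {
    abort("Both treatment arms must be non-empty.")
  }
  list(t = as.numeric(t), y = as.numeric(y), e = as.numeric(e_hat))
}

delta_ipw1 <- function(t, y, e) mean(t * y / e) - mean((1 - t) * y / (1 - e))

delta_ipw2 <- function(t, y, e) {
  sum(t * y / e) / sum(t / e) - sum((1 - t) * y / (1 - e)) / sum((1 - t) / (1 - e))
}

delta_aipw <- function(t, y, e, mu0, mu1) {
  mean((t * y - (t - e) * mu1) / e) - mean(((1 - t) * y + (t - e) * mu0) / (1 - e))
}

new_ace_estimate <- function(estimator, delta, n, t, e, se = NA_real_) {
  w1 <- 1 / e
  w0 <- 1 / (1 - e)
  rng <- function(w) if (length(w)) c(min(w), mean(w), max(w)) else rep(NA_real_, 3)
  s1 <- rng(w1[t == 1])
  s0 <- rng(w0[t == 0])
  wsum <- tibble(
    arm = c("treated", "control"),
    weight = c("1/e", "1/(1-e)"),
    min = c(s1[1], s0[1]), mean = c(s1[2], s0[2]), max = c(s1[3], s0[3])
  )
  structure(list(estimator = estimator, estimate = delta, se = se,
                 conf.low = delta - 1.96 * se, conf.high = delta + 1.96 * se,
                 n = n, weights = wsum),
            class = "ace_estimate")
}

#' IPW and AIPW estimators of the average causal effect
#'
#' `ipw1()` is the simple inverse-probability-weighting estimator
#' (unnormalized Horvitz-Thompson weights), `ipw2()` its normalized (Hajek)
#' version, and `aipw()` the augmented IPW estimator that combines the
#' weights with outcome-regression predictions and is consistent if either
#' the propensity-score model or the outcome model is correct. Weights are
#' never trimmed or renormalized beyond what each estimator's definition
#' prescribes; propensity scores of exactly 0 or 1 are an error, not a
#' repair.
#'
#' @param data Data frame with binary treatment and outcome columns.
#' @param e_hat Numeric vector of estimated propensity scores, one per row,
#'   strictly inside (0, 1).
#' @param mu0_hat,mu1_hat Numeric vectors of outcome-regression predictions
#'   per row for the control and treated arm.
#' @param treatment,outcome Column names.
#' @return An object of class `ace_estimate`; see [tidy.ace_estimate()].
#' @examples
#' d <- data.frame(T = c(1, 0), Y = c(2, 1))
#' tidy(ipw1(d, e_hat = c(0.5, 0.5)))
#' @export
ipw1 <- function(data, e_hat, treatment = "T", outcome = "Y") {
  v <- validate_estimator_inputs(data, e_hat, treatment, outcome,
                                 need_arms = FALSE)
  new_ace_estimate("ipw1", delta_ipw1(v$t, v$y, v$e), nrow(data), v$t, v$e)
}

#' @rdname ipw1
#' @export
ipw2 <- function(data, e_hat, treatment = "T", outcome = "Y") {
  v <- validate_estimator_inputs(data, e_hat, treatment, outcome)
  new_ace_estimate("ipw2", delta_ipw2(v$t, v$y, v$e), nrow(data), v$t, v$e)
}

#' @rdname ipw1
#' @export
aipw <- function(data, e_hat, mu0_hat, mu1_hat, treatment = "T", outcome = "Y") {
  v <- validate_estimator_inputs(data, e_hat, treatment, outcome,
                                 need_arms = FALSE)
  stopifnot(length(mu0_hat) == nrow(data), length(mu1_hat) == nrow(data))
  new_ace_estimate("aipw", delta_aipw(v$t, v$y, v$e, mu0_hat, mu1_hat),
                   nrow(data), v$t, v$e)
}

#' Tidy methods for estimates, fits and decompositions
#'
#' Broom-style one-row (or long) tibbles for the package's result objects.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ace_estimate
#' @export
tidy.ace_estimate <- function(x, ...) {
  tibble(estimator = x$estimator, estimate = x$estimate, se = x$se,
         conf.low = x$conf.low, conf.high = x$conf.high)
}

#' @rdname tidy.ace_estimate
#' @method glance ace_estimate
#' @export
glance.ace_estimate <- function(x, ...) {
  tibble(estimator = x$estimator, estimate = x$estimate, se = x$se, n = x$n)
}

#' @export
print.ace_estimate <- function(x, ...) {
  cat("<ace_estimate>", x$estimator, "\n")
  print(tidy(x))
  invisible(x)
}

# ---- standard errors --------------------------------------------------------

# Per-observation estimating functions stacked for M-estimation. theta is
# (mu1, mu0, beta[, alpha1, alpha0]) in the fits' own parameterizations.
stacked_psi <- function(data, estimator, ps_fit, or_fits, treatment, outcome) {
  t <- data[[treatment]]
  y <- data[[outcome]]
  Xp <- eval_terms(ps_fit$spec$terms, data)
  s <- convention_sign(ps_fit$spec$convention)
  linv <- link_inv(ps_fit$spec$link)
  dmu <- link_mu_eta(ps_fit$spec$link)
  p <- ncol(Xp)
  or_parts <- NULL
  if (estimator == "aipw") {
    or_parts <- lapply(or_fits, function(f) {
      list(X = eval_terms(f$spec$terms, data), fam = glm_family(f$spec),
           linv = link_inv(f$spec$link), dmu = link_mu_eta(f$spec$link))
    })
  }
  function(theta) {
    mu1 <- theta[1L]
    mu0 <- theta[2L]
    beta <- theta[2L + seq_len(p)]
    eta <- s * drop(Xp %*% beta)
    e <- linv(eta)
    e <- pmin(pmax(e, 1e-12), 1 - 1e-12)
    score_ps <- ((t - e) / (e * (1 - e)) * dmu(eta) * s) * Xp
    if (estimator == "ipw1") {
      psi_mu <- cbind(t * y / e - mu1, (1 - t) * y / (1 - e) - mu0)
      return(cbind(psi_mu, score_ps))
    }
    if (estimator == "ipw2") {
      psi_mu <- cbind(t * (y - mu1) / e, (1 - t) * (y - mu0) / (1 - e))
      return(cbind(psi_mu, score_ps))
    }
    q1 <- length(or_fits$or1$coefficients)
    q0 <- length(or_fits$or0$coefficients)
    a1 <- theta[2L + p + seq_len(q1)]
    a0 <- theta[2L + p + q1 + seq_len(q0)]
    f1 <- or_parts$or1
    f0 <- or_parts$or0
    eta1 <- drop(f1$X %*% a1)
    eta0 <- drop(f0$X %*% a0)
    m1 <- f1$linv(eta1)
    m0 <- f0$linv(eta0)
    v1 <- f1$fam$variance(m1)
    v0 <- f0$fam$variance(m0)
    score_or1 <- (t * (y - m1) * f1$dmu(eta1) / v1) * f1$X
    score_or0 <- ((1 - t) * (y - m0) * f0$dmu(eta0) / v0) * f0$X
    psi_mu <- cbind((t * y - (t - e) * m1) / e - mu1,
                    ((1 - t) * y + (t - e) * m0) / (1 - e) - mu0)
    cbind(psi_mu, score_ps, score_or1, score_or0)
  }
}

num_jacobian <- function(f, x, eps = 1e-6) {
  k <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), k)
  for (j in seq_len(k)) {
    h <- eps * (abs(x[j]) + eps)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

se_sandwich <- function(data, estimator, ps_fit, or_fits, treatment, outcome) {
  t <- data[[treatment]]
  y <- data[[outcome]]
  e <- predict(ps_fit, data)
  n <- nrow(data)
  if (estimator == "aipw") {
    m1 <- predict(or_fits$or1, data)
    m0 <- predict(or_fits$or0, data)
    mu1 <- mean((t * y - (t - e) * m1) / e)
    mu0 <- mean(((1 - t) * y + (t - e) * m0) / (1 - e))
    theta <- c(mu1, mu0, ps_fit$coefficients,
               or_fits$or1$coefficients, or_fits$or0$coefficients)
  } else if (estimator == "ipw1") {
    theta <- c(mean(t * y / e), mean((1 - t) * y / (1 - e)), ps_fit$coefficients)
  } else {
    theta <- c(sum(t * y / e) / sum(t / e),
               sum((1 - t) * y / (1 - e)) / sum((1 - t) / (1 - e)),
               ps_fit$coefficients)
  }
  psi <- stacked_psi(data, estimator, ps_fit, or_fits, treatment, outcome)
  A <- num_jacobian(function(th) colMeans(psi(th)), theta)
  P <- psi(theta)
  B <- crossprod(P) / n
  Ainv <- solve(A)
  V <- Ainv %*% B %*% t(Ainv) / n
  sqrt(V[1, 1] + V[2, 2] - 2 * V[1, 2])
}

se_bootstrap <- function(data, estimator, ps_fit, or_fits, treatment, outcome,
                         B, seed) {
  if (B < 50) abort("Bootstrap needs B >= 50 replicates.")
  set.seed(as.integer(seed))
  n <- nrow(data)
  deltas <- rep(NA_real_, B)
  failures <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    d <- data[idx, , drop = FALSE]
    deltas[b] <- tryCatch({
      pf <- suppressWarnings(fit_ps(d, ps_fit$spec, treatment = treatment))
      e <- predict(pf, d)
      if (any(e <= 0 | e >= 1)) stop("positivity")
      tt <- d[[treatment]]
      yy <- d[[outcome]]
      switch(estimator,
        ipw1 = delta_ipw1(tt, yy, e),
        ipw2 = delta_ipw2(tt, yy, e),
        aipw = {
          f1 <- suppressWarnings(fit_or(d, or_fits$or1$spec, treatment = treatment,
                                        outcome = outcome))
          f0 <- suppressWarnings(fit_or(d, or_fits$or0$spec, treatment = treatment,
                                        outcome = outcome))
          delta_aipw(tt, yy, e, predict(f0, d), predict(f1, d))
        }
      )
    }, error = function(err) NA_real_)
    if (is.na(deltas[b])) failures <- failures + 1L
  }
  if (failures > 0.05 * B) {
    abort(sprintf("Bootstrap refit failed in %d of %d replicates (> 5%%).",
                  failures, B))
  }
  sd(deltas, na.rm = TRUE)
}

#' Standard error of an (A)IPW estimate
#'
#' `"sandwich"` stacks the estimating equations for (mu1, mu0, beta) -- and,
#' for AIPW, the arm-wise outcome-model scores -- and returns the
#' delta-method standard error of mu1 - mu0, treating all working-model
#' parameters as estimated. `"bootstrap"` resamples rows with replacement
#' and refits every working model per replicate.
#'
#' @inheritParams ipw1
#' @param estimator `"ipw1"`, `"ipw2"` or `"aipw"`.
#' @param ps_fit A fitted PS working model ([fit_ps()]).
#' @param or_fits For AIPW: `list(or0 = , or1 = )` of fitted outcome models.
#' @param method `"sandwich"` or `"bootstrap"`.
#' @param B Bootstrap replicates (>= 50).
#' @param seed Bootstrap seed.
#' @return A non-negative scalar standard error.
#' @export
standard_error <- function(data, estimator = c("ipw1", "ipw2", "aipw"),
                           ps_fit, or_fits = NULL,
                           method = c("sandwich", "bootstrap"), B = 500,
                           seed = 1, treatment = "T", outcome = "Y") {
  estimator <- match.arg(estimator)
  method <- match.arg(method)
  if (estimator == "aipw" && (is.null(or_fits$or0) || is.null(or_fits$or1))) {
    abort("AIPW standard errors need both outcome-model fits.")
  }
  if (method == "sandwich") {
    se_sandwich(data, estimator, ps_fit, or_fits, treatment, outcome)
  } else {
    se_bootstrap(data, estimator, ps_fit, or_fits, treatment, outcome, B, seed)
  }
}
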