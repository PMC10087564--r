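# Parametric working models for the propensity score and the outcome
# regression: fitting by maximum quasi-likelihood / least squares, and the
# probability limits (beta*, alpha_t*) these fits converge to when the
# working model is wrong.

#' Working model specification
#'
#' A (possibly misspecified) parametric model for the propensity score or
#' for one arm's outcome regression.
#'
#' @param role One of `"ps"`, `"or0"`, `"or1"`.
#' @param terms Character vector of term expressions, intercept `"1"` first.
#' @param link For `ps`: `"logit"`, `"probit"` or `"cauchit"`; for OR:
#'   `"identity"` or `"log"`.
#' @param family OR outcome family: `"gaussian"`, `"poisson"` or `"gamma"`.
#'   PS models are always binary-response (quasi-binomial).
#' @param convention Sign convention for the PS linear predictor; see
#'   [ps_truth()]. Complement-convention fits are performed in the standard
#'   convention and the coefficients negated on the way out, so reported
#'   parameters match the printed form of the model.
#' @return Object of class `wm_spec`.
#' @export
wm_spec <- function(role, terms, link = NULL, family = NULL,
                    convention = "standard") {
  role <- match.arg(role, c("ps", "or0", "or1"))
  stopifnot(is.character(terms), terms[1L] == "1")
  if (role == "ps") {
    link <- match.arg(link %||% "logit", ps_links)
    family <- "binomial"
  } else {
    link <- match.arg(link %||% "identity", or_links)
    family <- match.arg(family %||% "gaussian", c("gaussian", "poisson", "gamma"))
  }
  convention <- match.arg(convention, c("standard", "complement"))
  structure(list(role = role, terms = terms, link = link, family = family,
                 convention = convention),
            class = "wm_spec")
}

#' @export
print.wm_spec <- function(x, ...) {
  cat("<wm_spec> ", x$role, ": ", x$family, "/", x$link,
      if (x$convention == "complement") " (complement)", "\n  terms: ",
      paste(x$terms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Build a wm_spec from a one- or two-sided formula (RHS terms only).
wm_spec_from_formula <- function(formula, role, link = NULL, family = NULL,
                                 convention = "standard") {
  tl <- attr(terms(formula), "term.labels")
  has_int <- attr(terms(formula), "intercept") == 1L
  if (!has_int) abort("Working-model formulas must include an intercept.")
  wm_spec(role, c("1", tl), link = link, family = family,
          convention = convention)
}

glm_family <- function(spec) {
  switch(spec$family,
    binomial = quasibinomial(link = spec$link),
    gaussian = gaussian(link = spec$link),
    poisson = quasipoisson(link = spec$link),
    gamma = Gamma(link = spec$link)
  )
}

# Core weighted quasi-likelihood fit on an explicit design matrix.
fit_wm_matrix <- function(Xm, y, spec, weights = NULL, start = NULL) {
  weights <- weights %||% rep(1, length(y))
  fam <- glm_family(spec)
  if (spec$family == "gaussian" && spec$link == "identity") {
    fit <- lm.wfit(Xm, y, w = weights)
    if (any(is.na(fit$coefficients))) {
      bad <- colnames(Xm)[is.na(fit$coefficients)]
      abort(sprintf("Design matrix is rank deficient; collinear term(s): %s.",
                    paste(bad, collapse = ", ")))
    }
    return(list(coefficients = fit$coefficients, converged = TRUE))
  }
  qrX <- qr(Xm * sqrt(weights))
  if (qrX$rank < ncol(Xm)) {
    bad <- colnames(Xm)[-qrX$pivot[seq_len(qrX$rank)]]
    abort(sprintf("Design matrix is rank deficient; collinear term(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  if (is.null(start) && spec$family %in% c("poisson", "gamma")) {
    # identity-link fits need admissible (positive-mean) starting values
    ystar <- if (spec$link == "log") log(pmax(y, 1e-8)) else y
    start <- qr.coef(qr(Xm * sqrt(weights)), ystar * sqrt(weights))
  }
  fit <- suppressWarnings(glm.fit(
    Xm, y, weights = weights, family = fam, start = start,
    control = list(epsilon = 1e-10, maxit = 100)
  ))
  boundary <- isTRUE(fit$boundary) ||
    (spec$family == "binomial" && any(fit$fitted.values <= 0 | fit$fitted.values >= 1))
  list(coefficients = fit$coefficients,
       converged = isTRUE(fit$converged) && !boundary)
}

new_wm_fit <- function(spec, coefficients, converged, n_used,
                       method = "sample_fit", meta = list()) {
  structure(list(spec = spec, coefficients = coefficients,
                 converged = converged, n_used = n_used, method = method,
                 meta = meta),
            class = c(if (method != "sample_fit") "working_model_limit",
                      "working_model_fit"))
}

#' Fit a propensity-score working model
#'
#' Maximizes the binomial quasi-likelihood of the spec's link for the
#' treatment indicator. Non-convergence and separation (fitted probabilities
#' reaching 0/1) are flagged, not silently returned.
#'
#' @param data A causal sample (data frame with a binary treatment column).
#' @param spec A [wm_spec()] with role `"ps"`.
#' @param treatment Name of the treatment column.
#' @return Object of class `working_model_fit`.
#' @export
fit_ps <- function(data, spec, treatment = "T") {
  stopifnot(inherits(spec, "wm_spec"))
  if (spec$role != "ps") abort("`spec` must have role 'ps'.")
  t <- data[[treatment]]
  if (is.null(t)) abort(sprintf("Column '%s' not found.", treatment))
  if (!all(t %in% c(0, 1))) abort("Treatment must be binary 0/1.")
  if (length(unique(t)) < 2L) abort("Both treatment arms must be present to fit a PS model.")
  Xm <- eval_terms(spec$terms, data)
  fit <- fit_wm_matrix(Xm, t, spec)
  if (!fit$converged) {
    warn("PS fit did not converge or hit the boundary (possible separation).")
  }
  co <- convention_sign(spec$convention) * fit$coefficients
  new_wm_fit(spec, setNames(co, spec$terms), fit$converged, length(t))
}

#' Fit an outcome-regression working model on one arm
#'
#' Ordinary least squares for gaussian/identity specs, quasi-likelihood
#' otherwise, using only the rows with `T == arm`.
#'
#' @inheritParams fit_ps
#' @param arm 0 or 1; defaults to the arm implied by the spec's role.
#' @param outcome Name of the outcome column.
#' @return Object of class `working_model_fit`.
#' @export
fit_or <- function(data, spec, arm = NULL, treatment = "T", outcome = "Y") {
  stopifnot(inherits(spec, "wm_spec"))
  if (!spec$role %in% c("or0", "or1")) abort("`spec` must have role 'or0' or 'or1'.")
  arm <- arm %||% as.integer(substring(spec$role, 3L))
  rows <- data[[treatment]] == arm
  if (sum(rows) < length(spec$terms)) {
    abort(sprintf("Arm %d has %d rows, fewer than the %d model terms.",
                  arm, sum(rows), length(spec$terms)))
  }
  sub <- data[rows, , drop = FALSE]
  Xm <- eval_terms(spec$terms, sub)
  fit <- fit_wm_matrix(Xm, sub[[outcome]], spec)
  if (!fit$converged) warn("OR fit did not converge.")
  new_wm_fit(spec, setNames(fit$coefficients, spec$terms), fit$converged,
             sum(rows))
}

#' Predicted propensity scores or conditional means
#'
#' @param object A `working_model_fit` (or limit model).
#' @param newdata Data frame of covariates.
#' @param ... Unused.
#' @return Numeric vector of fitted e(X) or mu(X) values.
#' @export
predict.working_model_fit <- function(object, newdata, ...) {
  spec <- object$spec
  eta <- drop(eval_terms(spec$terms, newdata) %*% object$coefficients)
  if (spec$role == "ps") {
    link_inv(spec$link)(convention_sign(spec$convention) * eta)
  } else {
    link_inv(spec$link)(eta)
  }
}

#' Probability limit of a working-model fit under a known truth
#'
#' When the working model is misspecified, its quasi-maximum-likelihood
#' estimator still converges to well-defined limiting coefficients. Two
#' numerical routes are provided: `"large_n_fit"` fits the working model to
#' one seeded sample of size `N`; `"population_score"` solves the population
#' estimating equation E\[score\] = 0 by tensor-product quadrature over the
#' covariate law (product laws only). Outcome-model limits are arm-wise:
#' the expectation is weighted by e(X) for arm 1 and 1 - e(X) for arm 0.
#'
#' @param design A [population_design()] (the truth).
#' @param spec A [wm_spec()].
#' @param method `"population_score"` or `"large_n_fit"`.
#' @param N Sample size for `large_n_fit`.
#' @param nodes Quadrature nodes for `population_score`.
#' @param seed Seed for `large_n_fit`.
#' @return A `working_model_limit` (usable with [predict()]).
#' @export
limit_parameters <- function(design, spec,
                             method = c("population_score", "large_n_fit"),
                             N = 1e6, nodes = NULL, seed = 1) {
  stopifnot(inherits(design, "population_design"), inherits(spec, "wm_spec"))
  method <- match.arg(method)
  if (method == "large_n_fit") {
    s <- sample_design(design, N, seed)
    fit <- if (spec$role == "ps") fit_ps(s, spec) else fit_or(s, spec)
    return(new_wm_fit(spec, fit$coefficients, fit$converged, N,
                      method = "large_n_fit", meta = list(N = N, seed = seed)))
  }
  g <- quad_grid(design$covariates, nodes = nodes)
  X <- g$points
  w <- g$weights
  e <- ps_eval(design$ps, X)
  Xm <- eval_terms(spec$terms, X)
  if (spec$role == "ps") {
    # Population score of the binary quasi-likelihood: each node contributes
    # a response-1 pseudo-observation with mass w*e and a response-0 one
    # with mass w*(1-e).
    fit <- fit_wm_matrix(rbind(Xm, Xm), rep(c(1, 0), each = nrow(Xm)), spec,
                         weights = c(w * e, w * (1 - e)))
    co <- convention_sign(spec$convention) * fit$coefficients
  } else {
    arm <- as.integer(substring(spec$role, 3L))
    wt <- if (arm == 1L) w * e else w * (1 - e)
    # The quasi-likelihood score is linear in the response, so replacing Y
    # with its conditional mean mu_t(X) leaves the solution unchanged.
    mu <- mu_eval(design$outcome, X, arm)
    fit <- fit_wm_matrix(Xm, mu, spec, weights = wt)
    co <- fit$coefficients
  }
  new_wm_fit(spec, setNames(co, spec$terms), fit$converged, nrow(X),
             method = "population_score",
             meta = list(nodes = nodes %||% NA_integer_))
}

#' Construct a limit model from known coefficients
#'
#' Useful to encode a limiting model whose coefficients are given (for
#' example, reported values) rather than computed.
#'
#' @param spec A [wm_spec()].
#' @param coefficients Numeric vector aligned with `spec$terms`, in the
#'   spec's own sign convention.
#' @return A `working_model_limit`.
#' @export
limit_model <- function(spec, coefficients) {
  stopifnot(length(coefficients) == length(spec$terms))
  new_wm_fit(spec, setNames(as.numeric(coefficients), spec$terms), TRUE, NA_integer_,
             method = "given")
}

#' @export
print.working_model_fit <- function(x, ...) {
  cat("<", class(x)[1L], "> ", x$spec$role, " (", x$method, ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname tidy.ace_estimate
#' @method tidy working_model_fit
#' @export
tidy.working_model_fit <- function(x, ...) {
  tibble(term = x$spec$terms, estimate = unname(x$coefficients))
}

#' @rdname tidy.ace_estimate
#' @method glance working_model_fit
#' @export
glance.working_model_fit <- function(x, ...) {
  tibble(role = x$spec$role, family = x$spec$family, link = x$spec$link,
         converged = x$converged, n_used = x$n_used, method = x$method)
}

# JSON serialization of a fitted/limit model (spec + coefficients + metadata).
wm_to_json <- function(fit, path = NULL) {
  obj <- list(spec = unclass(fit$spec),
              coefficients = as.list(fit$coefficients),
              converged = fit$converged, n_used = fit$n_used,
              method = fit$method, meta = fit$meta)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  js
}
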