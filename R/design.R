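# Population designs: the data-generating truth for a causal study --
# a covariate law, a true propensity-score surface e(X) and true
# outcome-regression surfaces mu_t(X) -- plus the seeded sampler and the
# true average causal effect.

#' Linear predictor specification
#'
#' An ordered list of covariate transforms with aligned coefficients. The
#' intercept term `"1"` always comes first.
#'
#' @param terms Character vector of term expressions, e.g.
#'   `c("1", "X1", "I(X1^2)")`.
#' @param coefficients Numeric vector, one per term.
#' @return Object of class `lin_pred`.
#' @export
linear_predictor <- function(terms, coefficients) {
  stopifnot(is.character(terms), is.numeric(coefficients))
  if (length(terms) != length(coefficients)) {
    abort("`terms` and `coefficients` must have the same length.")
  }
  if (terms[1L] != "1") abort("The intercept term \"1\" must come first.")
  structure(list(terms = terms, coefficients = as.numeric(coefficients)),
            class = "lin_pred")
}

lp_eval <- function(lp, data) {
  drop(eval_terms(lp$terms, data) %*% lp$coefficients)
}

#' True propensity-score surface
#'
#' @param predictor A [linear_predictor()] housing the true coefficients.
#' @param link One of `"logit"`, `"probit"`, `"cauchit"`.
#' @param convention `"standard"` for e = linkinv(eta) or `"complement"` for
#'   e = linkinv(-eta), so designs written as e = \{1 + exp(eta)\}^-1 can be
#'   encoded with their printed linear predictor.
#' @return Object of class `ps_truth`.
#' @export
ps_truth <- function(predictor, link = "logit", convention = "standard") {
  stopifnot(inherits(predictor, "lin_pred"))
  link <- match.arg(link, ps_links)
  convention <- match.arg(convention, c("standard", "complement"))
  structure(list(predictor = predictor, link = link, convention = convention),
            class = "ps_truth")
}

ps_eval <- function(ps, data) {
  s <- convention_sign(ps$convention)
  link_inv(ps$link)(s * lp_eval(ps$predictor, data))
}

#' True outcome-regression surfaces
#'
#' Arm-wise conditional mean models mu_0(X), mu_1(X) with an outcome family
#' used when drawing potential outcomes.
#'
#' @param predictor0,predictor1 [linear_predictor()]s for the control and
#'   treated arms (housing alpha_0 and alpha_1).
#' @param family One of `"gaussian"`, `"poisson"`, `"gamma"`.
#' @param link `"identity"` or `"log"`.
#' @param sd Gaussian noise standard deviation (default 1).
#' @param shape Gamma shape parameter (default 2); the scale is chosen
#'   pointwise so the mean equals mu_t(X).
#' @return Object of class `or_truth`.
#' @export
or_truth <- function(predictor0, predictor1, family = "gaussian",
                     link = "identity", sd = 1, shape = 2) {
  stopifnot(inherits(predictor0, "lin_pred"), inherits(predictor1, "lin_pred"))
  family <- match.arg(family, c("gaussian", "poisson", "gamma"))
  link <- match.arg(link, or_links)
  stopifnot(sd > 0, shape > 0)
  structure(list(predictor0 = predictor0, predictor1 = predictor1,
                 family = family, link = link, sd = sd, shape = shape),
            class = "or_truth")
}

mu_eval <- function(or, data, arm) {
  lp <- if (arm == 1L) or$predictor1 else or$predictor0
  link_inv(or$link)(lp_eval(lp, data))
}

draw_outcome <- function(or, mu) {
  n <- length(mu)
  switch(or$family,
    gaussian = rnorm(n, mu, or$sd),
    poisson = {
      if (any(mu <= 0)) abort("Poisson outcome mean must be positive on the support.")
      as.numeric(rpois(n, mu))
    },
    gamma = {
      if (any(mu <= 0)) abort("Gamma outcome mean must be positive on the support.")
      rgamma(n, shape = or$shape, scale = mu / or$shape)
    }
  )
}

#' Population design (data-generating truth)
#'
#' @param name Label for the design.
#' @param covariates A [covariate_law()].
#' @param ps A [ps_truth()].
#' @param outcome An [or_truth()].
#' @return Object of class `population_design`.
#' @export
population_design <- function(name, covariates, ps, outcome) {
  stopifnot(inherits(covariates, "covariate_law"), inherits(ps, "ps_truth"),
            inherits(outcome, "or_truth"))
  # every predictor term must resolve against the covariate names
  probe <- as.data.frame(setNames(rep(list(0.5), length(covariates$names)),
                                  covariates$names))
  for (lp in list(ps$predictor, outcome$predictor0, outcome$predictor1)) {
    eval_terms(lp$terms, probe)
  }
  structure(list(name = name, covariates = covariates, ps = ps,
                 outcome = outcome),
            class = "population_design")
}

#' @export
print.population_design <- function(x, ...) {
  cat("<population_design>", x$name, "\n")
  cat("  covariates:", paste(x$covariates$names, collapse = ", "), "\n")
  cat("  PS: ", x$ps$link, " (", x$ps$convention, "), terms: ",
      paste(x$ps$predictor$terms, collapse = ", "), "\n", sep = "")
  cat("  OR: ", x$outcome$family, "/", x$outcome$link, ", terms: ",
      paste(x$outcome$predictor1$terms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Draw a causal sample from a population design
#'
#' Rows are i.i.d.: X from the covariate law, T | X ~ Bernoulli(e(X)),
#' potential outcomes Y(t) | X from the outcome family with mean mu_t(X),
#' and Y = T Y(1) + (1 - T) Y(0). Both potential outcomes and the true
#' propensity score are kept alongside the observed data, which is only
#' possible in simulation and is what makes the bias functionals testable.
#'
#' @param design A [population_design()].
#' @param n Sample size (>= 2).
#' @param seed Integer seed; identical (design, n, seed) give identical
#'   samples.
#' @return A tibble with the covariate columns, `T`, `Y`, `Y0`, `Y1` and
#'   `e_true`.
#' @export
sample_design <- function(design, n, seed) {
  stopifnot(inherits(design, "population_design"))
  if (n < 2) abort("`n` must be at least 2.")
  set.seed(as.integer(seed))
  X <- sample_law(design$covariates, n)
  e <- ps_eval(design$ps, X)
  check_probability(e, what = sprintf("true e(X) in design '%s'", design$name))
  t <- rbinom(n, 1, e)
  mu0 <- mu_eval(design$outcome, X, 0L)
  mu1 <- mu_eval(design$outcome, X, 1L)
  y0 <- draw_outcome(design$outcome, mu0)
  y1 <- draw_outcome(design$outcome, mu1)
  out <- X
  out$T <- t
  out$Y <- t * y1 + (1 - t) * y0
  out$Y0 <- y0
  out$Y1 <- y1
  out$e_true <- e
  out
}

#' True marginal potential-outcome means and average causal effect
#'
#' Computes mu_t = E\[mu_t(X)\] under the covariate law, by tensor-product
#' quadrature for product laws or by Monte Carlo integration over X.
#'
#' @param design A [population_design()].
#' @param method `"auto"` picks quadrature when the law supports it.
#' @param nodes Quadrature nodes per continuous dimension (default 201 for
#'   one continuous dimension, 35 otherwise).
#' @param n Monte Carlo draws when integrating by simulation.
#' @param seed Seed for the Monte Carlo path.
#' @return One-row tibble with `mu1`, `mu0`, `delta` and `method`.
#' @export
true_mean_effect <- function(design, method = c("auto", "quadrature", "montecarlo"),
                             nodes = NULL, n = 1e6, seed = 1) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (law_has_quadrature(design$covariates)) "quadrature" else "montecarlo"
  }
  if (method == "quadrature") {
    g <- quad_grid(design$covariates, nodes = nodes)
    X <- g$points
    w <- g$weights
  } else {
    set.seed(as.integer(seed))
    X <- sample_law(design$covariates, n)
    w <- rep(1 / n, n)
  }
  mu1 <- sum(w * mu_eval(design$outcome, X, 1L))
  mu0 <- sum(w * mu_eval(design$outcome, X, 0L))
  tibble(mu1 = mu1, mu0 = mu0, delta = mu1 - mu0, method = method)
}

# E[e(X)] under the law, used for overlap sanity checks.
true_mean_ps <- function(design, nodes = NULL) {
  g <- quad_grid(design$covariates, nodes = nodes)
  sum(g$weights * ps_eval(design$ps, g$points))
}
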