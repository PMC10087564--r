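# Shared low-level helpers: term evaluation, link functions, conventions.

# Evaluate a character vector of term expressions ("1", "X1", "I(X1^2)",
# "exp(0.10*X1)", "X1:X2") against a data frame, returning the n x k design
# matrix. Terms are ordinary R expressions; "1" is the intercept and ":" is
# read as a numeric product so that formula-style interaction labels work.
eval_terms <- function(terms, data) {
  stopifnot(is.character(terms), length(terms) >= 1L)
  n <- nrow(data)
  cols <- lapply(terms, function(tm) {
    if (identical(tm, "1")) return(rep(1, n))
    tm <- gsub(":", "*", tm, fixed = TRUE)
    expr <- tryCatch(str2lang(tm), error = function(e) {
      abort(sprintf("Term '%s' is not a valid expression.", tm))
    })
    val <- tryCatch(
      eval(expr, envir = data, enclos = baseenv()),
      error = function(e) {
        abort(sprintf(
          "Term '%s' cannot be resolved against columns {%s}.",
          tm, paste(names(data), collapse = ", ")
        ))
      }
    )
    if (length(val) == 1L) val <- rep(val, n)
    if (length(val) != n || !is.numeric(val)) {
      abort(sprintf("Term '%s' did not evaluate to a numeric column.", tm))
    }
    val
  })
  out <- do.call(cbind, cols)
  colnames(out) <- terms
  out
}

ps_links <- c("logit", "probit", "cauchit")
or_links <- c("identity", "log")

link_inv <- function(link) {
  switch(link,
    logit = plogis,
    probit = pnorm,
    cauchit = pcauchy,
    identity = identity,
    log = exp,
    abort(sprintf("Unknown link '%s'.", link))
  )
}

# derivative of the inverse link (d mu / d eta)
link_mu_eta <- function(link) {
  switch(link,
    logit = function(eta) stats::dlogis(eta),
    probit = function(eta) stats::dnorm(eta),
    cauchit = function(eta) stats::dcauchy(eta),
    identity = function(eta) rep(1, length(eta)),
    log = exp,
    abort(sprintf("Unknown link '%s'.", link))
  )
}

# Sign applied to the linear predictor before the inverse link. The standard
# convention is e = linkinv(eta); the complement convention, used when a
# design is written as e = {1 + exp(eta)}^-1, is e = linkinv(-eta).
convention_sign <- function(convention) {
  switch(convention, standard = 1, complement = -1,
         abort(sprintf("Unknown sign convention '%s'.", convention)))
}

check_probability <- function(e, what = "propensity score", tol = 0) {
  bad <- !is.finite(e) | e <= tol | e >= 1 - tol
  if (any(bad)) {
    i <- which(bad)[1L]
    abort(sprintf(
      "%s is numerically outside (0, 1) at point %d (value %.3g); positivity fails.",
      what, i, e[i]
    ))
  }
  invisible(e)
}

`%||%` <- rlang::`%||%`
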