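# Declarative covariate laws: independent 1-d components, bivariate-normal
# blocks, and deterministic transforms of earlier components.

#' Covariate law components
#'
#' Building blocks for a [covariate_law()]: independent one-dimensional
#' distributions, a correlated bivariate-normal block, and deterministic
#' transforms of components defined earlier in the law.
#'
#' @param name,names Component name(s). Each must be unique within the law;
#'   a bivariate block names its two coordinates.
#' @param min,max,mean,sd,lambda,prob Distribution parameters.
#' @param sigma 2x2 symmetric positive-definite covariance matrix.
#' @param expr A character scalar: an R expression in the names of earlier
#'   components, e.g. `"X1^2"`.
#' @return A component descriptor used by [covariate_law()].
#' @name law-components
NULL

#' @rdname law-components
#' @export
cov_uniform <- function(name, min = 0, max = 1) {
  stopifnot(max > min)
  structure(list(type = "uniform", name = name, min = min, max = max),
            class = "law_component")
}

#' @rdname law-components
#' @export
cov_normal <- function(name, mean = 0, sd = 1) {
  stopifnot(sd > 0)
  structure(list(type = "normal", name = name, mean = mean, sd = sd),
            class = "law_component")
}

#' @rdname law-components
#' @export
cov_poisson <- function(name, lambda) {
  stopifnot(lambda > 0)
  structure(list(type = "poisson", name = name, lambda = lambda),
            class = "law_component")
}

#' @rdname law-components
#' @export
cov_bernoulli <- function(name, prob) {
  stopifnot(prob > 0, prob < 1)
  structure(list(type = "bernoulli", name = name, prob = prob),
            class = "law_component")
}

#' @rdname law-components
#' @export
cov_bvnormal <- function(names, mean, sigma) {
  stopifnot(length(names) == 2L, length(mean) == 2L,
            is.matrix(sigma), all(dim(sigma) == 2L))
  if (max(abs(sigma - t(sigma))) > 1e-12 || any(eigen(sigma, only.values = TRUE)$values <= 0)) {
    abort("Bivariate covariance must be symmetric positive-definite.")
  }
  structure(list(type = "bvnormal", name = names, mean = mean, sigma = sigma),
            class = "law_component")
}

#' @rdname law-components
#' @export
cov_transform <- function(name, expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  structure(list(type = "transform", name = name, expr = expr),
            class = "law_component")
}

#' Assemble a covariate law
#'
#' A covariate law is an ordered list of components; transforms may reference
#' only components defined before them.
#'
#' @param ... Components created with [cov_uniform()], [cov_normal()],
#'   [cov_poisson()], [cov_bernoulli()], [cov_bvnormal()], [cov_transform()].
#' @return An object of class `covariate_law`.
#' @export
covariate_law <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && !inherits(comps[[1L]], "law_component")) {
    comps <- comps[[1L]]
  }
  stopifnot(all(vapply(comps, inherits, logical(1), "law_component")))
  seen <- character(0)
  for (cmp in comps) {
    nm <- cmp$name
    if (any(nm %in% seen)) {
      abort(sprintf("Duplicate covariate name '%s'.", nm[nm %in% seen][1L]))
    }
    if (cmp$type == "transform") {
      vars <- all.vars(str2lang(cmp$expr))
      missing <- setdiff(vars, seen)
      if (length(missing)) {
        abort(sprintf(
          "Transform '%s' references undefined component(s): %s.",
          cmp$name, paste(missing, collapse = ", ")
        ))
      }
    }
    seen <- c(seen, nm)
  }
  structure(list(components = comps, names = seen), class = "covariate_law")
}

#' @export
print.covariate_law <- function(x, ...) {
  cat("<covariate_law> with components:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

# Draw n i.i.d. rows from the law (uses the current RNG state).
sample_law <- function(law, n) {
  stopifnot(inherits(law, "covariate_law"))
  out <- vector("list", 0L)
  df <- as.data.frame(matrix(numeric(0), nrow = n, ncol = 0))
  for (cmp in law$components) {
    val <- switch(cmp$type,
      uniform   = runif(n, cmp$min, cmp$max),
      normal    = rnorm(n, cmp$mean, cmp$sd),
      poisson   = rpois(n, cmp$lambda),
      bernoulli = rbinom(n, 1, cmp$prob),
      bvnormal  = MASS::mvrnorm(n, mu = cmp$mean, Sigma = cmp$sigma),
      transform = eval(str2lang(cmp$expr), envir = df, enclos = baseenv())
    )
    if (cmp$type == "bvnormal") {
      if (n == 1L) val <- matrix(val, nrow = 1L)
      df[[cmp$name[1L]]] <- val[, 1L]
      df[[cmp$name[2L]]] <- val[, 2L]
    } else {
      df[[cmp$name]] <- as.numeric(val)
    }
  }
  as_tibble(df)
}

law_has_quadrature <- function(law) {
  !any(vapply(law$components, function(c) c$type == "bvnormal", logical(1)))
}

n_continuous <- function(law) {
  sum(vapply(law$components, function(c) c$type %in% c("uniform", "normal"),
             logical(1)))
}

# Tensor-product quadrature grid for a product law. Returns a tibble of
# points plus a probability-weight vector summing to ~1. Continuous
# components get Gauss-Legendre (uniform) or Gauss-Hermite (normal) nodes;
# Poisson components are truncated at cumulative mass 1 - 1e-9 and
# Bernoulli components enumerated.
quad_grid <- function(law, nodes = NULL, max_nodes = 4e6) {
  if (!law_has_quadrature(law)) {
    abort("Quadrature is unsupported for laws with dependent (bivariate-normal) blocks.")
  }
  d_cont <- n_continuous(law)
  if (is.null(nodes)) nodes <- if (d_cont <= 1L) 201L else 35L
  marginals <- list()
  for (cmp in law$components) {
    if (cmp$type == "transform") next
    m <- switch(cmp$type,
      uniform = {
        gl <- pracma::gaussLegendre(nodes, cmp$min, cmp$max)
        list(x = gl$x, w = gl$w / (cmp$max - cmp$min))
      },
      normal = {
        gh <- pracma::gaussHermite(nodes)
        list(x = cmp$mean + sqrt(2) * cmp$sd * gh$x, w = gh$w / sqrt(pi))
      },
      poisson = {
        # tail mass 1e-9: far-tail counts saturate logistic surfaces to 0/1
        # in floating point while contributing nothing to the integrals
        k <- 0:(qpois(1 - 1e-9, cmp$lambda) + 1L)
        list(x = k, w = dpois(k, cmp$lambda))
      },
      bernoulli = list(x = c(0, 1), w = c(1 - cmp$prob, cmp$prob))
    )
    marginals[[cmp$name]] <- m
  }
  sizes <- vapply(marginals, function(m) length(m$x), integer(1))
  if (prod(sizes) > max_nodes) {
    abort(sprintf(
      "Quadrature grid of %.3g nodes exceeds max_nodes = %.3g; reduce `nodes`.",
      prod(sizes), max_nodes
    ))
  }
  idx <- do.call(expand.grid, lapply(sizes, seq_len))
  df <- as.data.frame(Map(function(m, i) m$x[i], marginals, idx))
  w <- Reduce(`*`, Map(function(m, i) m$w[i], marginals, idx))
  for (cmp in law$components) {
    if (cmp$type == "transform") {
      df[[cmp$name]] <- eval(str2lang(cmp$expr), envir = df, enclos = baseenv())
    }
  }
  list(points = as_tibble(df)[law$names], weights = w)
}
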