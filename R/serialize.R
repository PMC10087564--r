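# YAML/JSON serialization of design bundles and CSV export of samples.

component_to_list <- function(cmp) {
  out <- unclass(cmp)
  if (cmp$type == "bvnormal") out$sigma <- as.numeric(out$sigma)
  out
}

component_from_list <- function(l) {
  switch(l$type,
    uniform = cov_uniform(l$name, l$min, l$max),
    normal = cov_normal(l$name, l$mean, l$sd),
    poisson = cov_poisson(l$name, l$lambda),
    bernoulli = cov_bernoulli(l$name, l$prob),
    bvnormal = cov_bvnormal(unlist(l$name), unlist(l$mean),
                            matrix(unlist(l$sigma), 2, 2)),
    transform = cov_transform(l$name, l$expr),
    abort(sprintf("Unknown covariate component type '%s'.", l$type))
  )
}

lp_to_list <- function(lp) list(terms = lp$terms, coefficients = lp$coefficients)

spec_to_list <- function(sp) unclass(sp)

#' Serialize and restore design bundles
#'
#' A design bundle (truth plus misspecified working-model specs) round-trips
#' through a plain list, YAML or JSON.
#'
#' @param bundle A [make_design()] bundle.
#' @param x A list produced by `design_to_list()`.
#' @param path File path.
#' @return `design_to_list()` a list; `design_from_list()` /
#'   `design_from_yaml()` a `design_bundle`; writers return the path
#'   invisibly.
#' @export
design_to_list <- function(bundle) {
  stopifnot(inherits(bundle, "design_bundle"))
  d <- bundle$design
  list(
    name = d$name,
    covariates = lapply(d$covariates$components, component_to_list),
    ps = list(predictor = lp_to_list(d$ps$predictor), link = d$ps$link,
              convention = d$ps$convention),
    outcome = list(predictor0 = lp_to_list(d$outcome$predictor0),
                   predictor1 = lp_to_list(d$outcome$predictor1),
                   family = d$outcome$family, link = d$outcome$link,
                   sd = d$outcome$sd, shape = d$outcome$shape),
    misspec = lapply(bundle$misspec, spec_to_list)
  )
}

#' @rdname design_to_list
#' @export
design_from_list <- function(x) {
  law <- covariate_law(lapply(x$covariates, component_from_list))
  ps <- ps_truth(linear_predictor(unlist(x$ps$predictor$terms),
                                  unlist(x$ps$predictor$coefficients)),
                 link = x$ps$link, convention = x$ps$convention)
  or <- or_truth(
    linear_predictor(unlist(x$outcome$predictor0$terms),
                     unlist(x$outcome$predictor0$coefficients)),
    linear_predictor(unlist(x$outcome$predictor1$terms),
                     unlist(x$outcome$predictor1$coefficients)),
    family = x$outcome$family, link = x$outcome$link,
    sd = x$outcome$sd, shape = x$outcome$shape
  )
  design <- population_design(x$name, law, ps, or)
  misspec <- lapply(x$misspec, function(sp) {
    wm_spec(sp$role, unlist(sp$terms), link = sp$link, family = sp$family,
            convention = sp$convention)
  })
  new_bundle(design, misspec, truth_specs(design))
}

#' @rdname design_to_list
#' @export
design_to_yaml <- function(bundle, path) {
  yaml::write_yaml(design_to_list(bundle), path)
  invisible(path)
}

#' @rdname design_to_list
#' @export
design_from_yaml <- function(path) design_from_list(yaml::read_yaml(path))

#' Write a generated causal sample to CSV
#'
#' @param sample A [sample_design()] tibble.
#' @param path Output path.
#' @export
write_sample_csv <- function(sample, path) {
  readr::write_csv(sample, path)
  invisible(path)
}
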