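# ggplot2 visualisations for the result objects.

#' @importFrom rlang .data
NULL

#' Plot a bias decomposition
#'
#' Bar chart of the total, treated-arm and control-arm large-sample biases
#' per estimator.
#'
#' @param object A `bias_decomposition`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bias_decomposition
#' @export
autoplot.bias_decomposition <- function(object, ...) {
  d <- tidy(object)
  d <- d[grepl("^bias", d$parameter), ]
  d <- tidyr::separate(d, "parameter", into = c("component", "estimator"),
                       sep = "_(?=[ai])", extra = "merge")
  d$component <- factor(d$component,
                        levels = c("bias", "bias1", "bias2"),
                        labels = c("total", "treated arm", "control arm"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimator, y = .data$value,
                                  fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "large-sample bias",
                  title = paste("Bias decomposition:", object$design)) +
    ggplot2::theme_minimal()
}

#' Mirror histogram of propensity-score overlap
#'
#' @param object An [overlap_report()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlap_report
#' @export
autoplot.overlap_report <- function(object, bins = 40, ...) {
  df <- tibble(
    e = attr(object, "e_hat"),
    arm = ifelse(attr(object, "treatment") == 1, "treated", "control")
  )
  thr <- attr(object, "threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$e)) +
    ggplot2::geom_histogram(data = df[df$arm == "treated", ],
                            ggplot2::aes(y = ggplot2::after_stat(count), fill = "treated"),
                            bins = bins, alpha = 0.7) +
    ggplot2::geom_histogram(data = df[df$arm == "control", ],
                            ggplot2::aes(y = -ggplot2::after_stat(count), fill = "control"),
                            bins = bins, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(thr, 1 - thr), linetype = 2) +
    ggplot2::labs(x = "estimated propensity score", y = "count (control below)",
                  fill = NULL, title = "Propensity-score overlap") +
    ggplot2::theme_minimal()
}

#' Covariate balance (love) plot
#'
#' @param object A [balance_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot balance_report
#' @export
autoplot.balance_report <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object)[, 1:3], -"covariate",
                           names_to = "type", values_to = "smd")
  d$type <- ifelse(d$type == "smd_weighted", "IPW weighted", "unweighted")
  thr <- attr(object, "threshold")
  ggplot2::ggplot(d, ggplot2::aes(x = abs(.data$smd), y = .data$covariate,
                                  colour = .data$type)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL, colour = NULL,
                  title = "Covariate balance") +
    ggplot2::theme_minimal()
}

#' Model-ratio curves for a one-covariate design
#'
#' For designs with a single continuous covariate, draws the true and
#' limiting propensity scores, their ratio e(X)/e*(X), and the true and
#' limiting treated-arm conditional outcomes -- the ingredients of the bias
#' functionals.
#'
#' @param pair A [misspecified_pair()] over a one-dimensional design.
#' @param n_points Grid resolution.
#' @return A ggplot.
#' @export
plot_model_ratio <- function(pair, n_points = 301) {
  law <- pair$design$covariates
  cmp <- law$components[[1L]]
  if (length(law$components) != 1L || !cmp$type %in% c("uniform", "normal")) {
    abort("plot_model_ratio() needs a design with one continuous covariate.")
  }
  xs <- if (cmp$type == "uniform") {
    seq(cmp$min, cmp$max, length.out = n_points)
  } else {
    seq(cmp$mean - 4 * cmp$sd, cmp$mean + 4 * cmp$sd, length.out = n_points)
  }
  X <- as_tibble(setNames(list(xs), cmp$name))
  sf <- pair_surfaces(pair, X)
  d <- dplyr::bind_rows(
    tibble(x = xs, value = sf$e, curve = "e(X)", panel = "propensity"),
    tibble(x = xs, value = sf$es, curve = "e*(X)", panel = "propensity"),
    tibble(x = xs, value = sf$e / sf$es, curve = "e/e*", panel = "PS-model ratio"),
    tibble(x = xs, value = sf$mu1, curve = "mu1(X)", panel = "outcome"),
    if (!is.null(sf$mu1s))
      tibble(x = xs, value = sf$mu1s, curve = "mu1*(X)", panel = "outcome")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$value,
                                  colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = cmp$name, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
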