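# Applied-workflow diagnostics: positivity/overlap of the estimated
# propensity scores and weighted covariate balance.

#' Overlap report for estimated propensity scores
#'
#' Arm-wise summaries of the estimated propensity-score distribution and
#' counts of values outside the positivity band \[eta, 1 - eta\].
#'
#' @param data Data frame with the treatment column.
#' @param e_hat Estimated propensity scores, one per row.
#' @param threshold Positivity bound eta (default 0.1).
#' @param treatment Treatment column name.
#' @return A tibble of class `overlap_report` with one row per arm.
#' @export
overlap_report <- function(data, e_hat, threshold = 0.1, treatment = "T") {
  t <- data[[treatment]]
  stopifnot(length(e_hat) == nrow(data), threshold > 0, threshold < 0.5)
  one_arm <- function(arm) {
    e <- e_hat[t == arm]
    tibble(
      arm = if (arm == 1) "treated" else "control",
      n = length(e),
      min = min(e), p25 = unname(quantile(e, 0.25)),
      median = unname(quantile(e, 0.5)), p75 = unname(quantile(e, 0.75)),
      max = max(e),
      n_below = sum(e < threshold), n_above = sum(e > 1 - threshold)
    )
  }
  out <- dplyr::bind_rows(one_arm(1), one_arm(0))
  attr(out, "e_hat") <- e_hat
  attr(out, "treatment") <- t
  attr(out, "threshold") <- threshold
  class(out) <- c("overlap_report", class(out))
  out
}

#' Weighted covariate balance report
#'
#' Standardized mean differences (SMD) per covariate, unweighted and under
#' the IPW weights T/e and (1 - T)/(1 - e). The pooled standard deviation
#' comes from the unweighted sample; a constant covariate has SMD 0 by
#' convention.
#'
#' @inheritParams overlap_report
#' @param covariates Covariate column names; defaults to every numeric
#'   column except treatment/outcome bookkeeping columns.
#' @param threshold Balance flag threshold on |SMD| (default 0.10).
#' @param outcome Outcome column name (excluded from the default covariates).
#' @return A tibble of class `balance_report` with columns `covariate`,
#'   `smd_unweighted`, `smd_weighted`, `balanced`.
#' @export
balance_report <- function(data, e_hat, covariates = NULL, threshold = 0.10,
                           treatment = "T", outcome = "Y") {
  t <- data[[treatment]]
  stopifnot(length(e_hat) == nrow(data))
  if (is.null(covariates)) {
    drop <- c(treatment, outcome, "Y0", "Y1", "e_true")
    covariates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], drop)
  }
  w1 <- t / e_hat
  w0 <- (1 - t) / (1 - e_hat)
  smd_one <- function(x) {
    s_pool <- sqrt((var(x[t == 1]) + var(x[t == 0])) / 2)
    if (!is.finite(s_pool) || s_pool == 0) return(c(0, 0))
    raw <- (mean(x[t == 1]) - mean(x[t == 0])) / s_pool
    wtd <- (sum(w1 * x) / sum(w1) - sum(w0 * x) / sum(w0)) / s_pool
    c(raw, wtd)
  }
  vals <- vapply(covariates, function(nm) smd_one(data[[nm]]), numeric(2))
  out <- tibble(
    covariate = covariates,
    smd_unweighted = unname(vals[1, ]),
    smd_weighted = unname(vals[2, ]),
    balanced = abs(vals[2, ]) <= threshold
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("balance_report", class(out))
  out
}
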