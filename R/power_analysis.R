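# shared kernel: power of a two-sided level-alpha Wald test when the test
# statistic is N(ncp, 1), using the one-tailed approximation standard for
# summary-data MR power calculators (so power at ncp = 0 equals alpha/2)
.power_from_ncp <- function(ncp, alpha) {
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

.check_power_args <- function(n, r2_gx, alpha, case_fraction = NULL) {
  if (any(n <= 0) || any(n != floor(n))) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (r2_gx <= 0 || r2_gx >= 1) stop("r2_gx must lie in (0,1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)", call. = FALSE)
  if (!is.null(case_fraction) &&
      (case_fraction <= 0 || case_fraction >= 1)) {
    stop("case_fraction must lie in (0,1)", call. = FALSE)
  }
}

#' Power of a Mendelian randomization analysis with a binary outcome
#'
#' Normal-approximation power for detecting a causal log odds ratio `theta`
#' per standard-deviation change in the exposure, with instruments that
#' jointly explain `r2_gx` of the exposure variance, in an outcome sample of
#' size `n` of which a fraction `case_fraction` are cases. The
#' non-centrality is |theta| * sqrt(n * r2_gx * K(1-K)); power is
#' Phi(ncp - z_{1-alpha/2}), the standard approximation implemented by
#' summary-data MR power calculators (its value at theta = 0 is alpha/2).
#'
#' @param n outcome sample size.
#' @param case_fraction proportion of cases K, in (0,1).
#' @param r2_gx variance of the exposure explained by the instruments.
#' @param theta true causal effect (log odds ratio per SD of exposure).
#' @param alpha two-sided significance level (default 0.05).
#' @return power, a probability.
#' @export
power_binary <- function(n, case_fraction, r2_gx, theta, alpha = 0.05) {
  .check_power_args(n, r2_gx, alpha, case_fraction)
  ncp <- abs(theta) * sqrt(n * r2_gx * case_fraction * (1 - case_fraction))
  .power_from_ncp(ncp, alpha)
}

#' Power of a Mendelian randomization analysis with a continuous outcome
#'
#' As [power_binary()] but for an outcome in standard-deviation units; the
#' non-centrality is |theta| * sqrt(n * r2_gx).
#'
#' @param n outcome sample size.
#' @param r2_gx variance of the exposure explained by the instruments.
#' @param theta true causal effect (SD of outcome per SD of exposure).
#' @param alpha two-sided significance level (default 0.05).
#' @return power, a probability.
#' @export
power_continuous <- function(n, r2_gx, theta, alpha = 0.05) {
  .check_power_args(n, r2_gx, alpha)
  ncp <- abs(theta) * sqrt(n * r2_gx)
  .power_from_ncp(ncp, alpha)
}

#' Power across a grid of sample sizes
#'
#' @param n_grid vector of outcome sample sizes.
#' @param r2_gx,theta,alpha as in [power_binary()]/[power_continuous()].
#' @param case_fraction proportion of cases for a binary outcome, or `NULL`
#'   for a continuous outcome.
#' @return data frame with columns `n` and `power`, monotone
#'   non-decreasing in `n`.
#' @export
power_curve <- function(n_grid, r2_gx, theta, case_fraction = NULL,
                        alpha = 0.05) {
  if (length(n_grid) == 0) stop("empty sample-size grid", call. = FALSE)
  pw <- vapply(n_grid, function(n) {
    if (is.null(case_fraction)) power_continuous(n, r2_gx, theta, alpha)
    else power_binary(n, case_fraction, r2_gx, theta, alpha)
  }, numeric(1))
  data.frame(n = n_grid, power = pw)
}
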