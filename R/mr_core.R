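# fixed 95% normal quantile so printed confidence intervals round-trip
# bit-stably
Z95 <- 1.959964

mr_estimate <- function(theta, se_theta, n_variants, method, pc_k = NULL,
                        scale = NULL) {
  stopifnot(is.finite(theta), is.finite(se_theta), se_theta > 0)
  structure(list(
    theta = theta,
    se_theta = se_theta,
    pvalue = 2 * stats::pnorm(-abs(theta / se_theta)),
    n_variants = as.integer(n_variants),
    method = method,
    pc_k = if (is.null(pc_k)) NA_integer_ else as.integer(pc_k),
    scale = scale
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate (%s, %d variant%s):\n", x$method, x$n_variants,
              if (x$n_variants == 1) "" else "s"))
  cat(sprintf("  theta = %.6g (se %.6g), p = %.4g\n",
              x$theta, x$se_theta, x$pvalue))
  if (!is.na(x$pc_k)) cat(sprintf("  principal components used: %d\n", x$pc_k))
  invisible(x)
}

#' Single-variant Wald ratio estimate
#'
#' The causal effect from one instrument: theta = beta_y / beta_x with
#' first-order standard error se_y / |beta_x|. Uncertainty in the exposure
#' association is ignored (the fixed-denominator convention of summary-data
#' MR); with a strong instrument this term is negligible.
#'
#' @param beta_x,beta_y variant associations with exposure and outcome.
#' @param se_y standard error of `beta_y`.
#' @return an `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(beta_x, beta_y, se_y) {
  if (beta_x == 0) stop("weak/undefined instrument: beta_x is zero", call. = FALSE)
  stopifnot(se_y > 0)
  mr_estimate(beta_y / beta_x, se_y / abs(beta_x), 1L, "wald")
}

# Sigma = D rho D with D a diagonal of standard errors
outcome_covariance <- function(se, rho) {
  se * rho * rep(se, each = length(se))
}

# solve the zero-intercept GLS theta = (X' S^-1 X)^-1 X' S^-1 Y through a
# Cholesky factor, never an explicit inverse
.gls_fit <- function(x, y, sigma) {
  R <- chol(sigma)
  xt <- backsolve(R, x, transpose = TRUE)
  yt <- backsolve(R, y, transpose = TRUE)
  xtx <- sum(xt * xt)
  theta <- sum(xt * yt) / xtx
  list(theta = theta, se = sqrt(1 / xtx))
}

#' Generalized inverse-variance weighted estimate for correlated variants
#'
#' Regresses the outcome associations on the exposure associations with a
#' zero intercept by generalized weighted least squares, with error
#' covariance Sigma_{jk} = se_j se_k rho_{jk} built from the outcome
#' standard errors and the signed LD correlations. With uncorrelated
#' variants this reduces to the textbook inverse-variance weighted
#' estimator; with a single variant it reduces to the Wald ratio.
#'
#' When Sigma is numerically near-singular (condition number above 1e8, as
#' happens with variants in very strong LD) the fit is refused with an error
#' directing the caller to [pc_ivw()].
#'
#' @param h a `harmonized_set`.
#' @param weights which side's standard errors build Sigma. The default
#'   `"outcome_se"` is the generalized IVW estimator; `"exposure_se"` is
#'   provided only for sensitivity analysis.
#' @param max_condition condition-number gate for Sigma (default 1e8).
#' @return an `mr_estimate` with method `"ivw_correlated"`.
#' @export
ivw_correlated <- function(h, weights = c("outcome_se", "exposure_se"),
                           max_condition = 1e8) {
  stopifnot(inherits(h, "harmonized_set"))
  weights <- match.arg(weights)
  if (weights == "exposure_se") {
    message("ivw_correlated: using EXPOSURE standard errors in Sigma ",
            "(sensitivity mode; the primary analysis uses outcome_se)")
  }
  n <- length(h$variant_ids)
  if (n == 0) stop("empty harmonized set", call. = FALSE)
  se <- if (weights == "outcome_se") h$se_outcome else h$se_exposure
  sigma <- outcome_covariance(se, h$ld)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) {
    stop("weight covariance is not positive semidefinite", call. = FALSE)
  }
  if (min(ev) <= 0 || max(ev) / min(ev) > max_condition) {
    stop("weight covariance is near-singular (condition number > 1e8); ",
         "use pc_ivw() for a principal-components stabilized estimate",
         call. = FALSE)
  }
  fit <- .gls_fit(h$beta_exposure, h$beta_outcome, sigma)
  mr_estimate(fit$theta, fit$se, n, "ivw_correlated",
              scale = h$outcome_scale)
}

#' Principal-components stabilized IVW estimate
#'
#' For variant sets in strong LD the weight covariance of [ivw_correlated()]
#' is near-singular and the plain generalized IVW estimate is unstable. This
#' estimator forms the weighted correlation matrix
#' Psi_{jk} = beta_x_j beta_x_k rho_{jk} / (se_y_j se_y_k), keeps the
#' smallest number k of leading principal components whose eigenvalues sum
#' to at least `variance_kept` of the total (negative eigenvalues, which can
#' arise from noisy external LD estimates, are clamped to zero first), and
#' applies the generalized IVW formula after projecting the exposure and
#' outcome associations and the weight covariance onto those components.
#'
#' @param h a `harmonized_set` with at least 2 variants.
#' @param variance_kept fraction of Psi's variance the retained components
#'   must explain, in (0,1] (default 0.99).
#' @param weighted_psi if `FALSE`, decompose the unweighted LD correlation
#'   matrix instead of Psi (sensitivity mode).
#' @return an `mr_estimate` with method `"pc_ivw"`; `pc_k` records the
#'   number of components used.
#' @export
pc_ivw <- function(h, variance_kept = 0.99, weighted_psi = TRUE) {
  stopifnot(inherits(h, "harmonized_set"))
  n <- length(h$variant_ids)
  if (n < 2) stop("pc_ivw requires at least 2 variants", call. = FALSE)
  if (!(variance_kept > 0 && variance_kept <= 1)) {
    stop("variance_kept must lie in (0,1]", call. = FALSE)
  }
  psi <- if (weighted_psi) {
    w <- h$beta_exposure / h$se_outcome
    w * h$ld * rep(w, each = n)
  } else {
    h$ld
  }
  eig <- eigen(psi, symmetric = TRUE)
  lambda <- eig$values
  lambda[lambda < 1e-10 * max(abs(lambda))] <- 0
  total <- sum(lambda)
  if (total <= 0) stop("weighted correlation matrix has no positive eigenvalues",
                       call. = FALSE)
  k <- which(cumsum(lambda) >= variance_kept * total)[1]
  V <- eig$vectors[, seq_len(k), drop = FALSE]

  sigma <- outcome_covariance(h$se_outcome, h$ld)
  xt <- crossprod(V, h$beta_exposure)
  yt <- crossprod(V, h$beta_outcome)
  st <- crossprod(V, sigma %*% V)
  st <- (st + t(st)) / 2
  fit <- .gls_fit(xt, yt, st)
  mr_estimate(fit$theta, fit$se, n, "pc_ivw", pc_k = k,
              scale = h$outcome_scale)
}

#' Convert a log-odds MR estimate to an odds ratio with confidence interval
#'
#' @param est an `mr_estimate` whose outcome is on the log-odds scale; the
#'   result is the odds ratio per unit increase in the exposure.
#' @param level confidence level in (0,1); for 0.95 the normal quantile is
#'   fixed at 1.959964.
#' @return a list with `or_point`, `ci_low`, `ci_high`, `level`.
#' @export
to_odds_ratio <- function(est, level = 0.95) {
  stopifnot(inherits(est, "mr_estimate"))
  if (!(level > 0 && level < 1)) stop("level must lie in (0,1)", call. = FALSE)
  if (!is.null(est$scale) && !identical(est$scale, "log_odds")) {
    warning("outcome scale is '", est$scale,
            "'; odds-ratio conversion assumes log-odds", call. = FALSE)
  }
  z <- if (identical(level, 0.95)) Z95 else stats::qnorm((1 + level) / 2)
  list(or_point = exp(est$theta),
       ci_low = exp(est$theta - z * est$se_theta),
       ci_high = exp(est$theta + z * est$se_theta),
       level = level)
}

#' Fixed-effect inverse-variance pooling of MR estimates
#'
#' Combines independent cohort estimates of the same causal parameter with
#' weights 1/se^2. All estimates must be on the same outcome scale.
#'
#' @param estimates list of `mr_estimate` objects.
#' @return an `mr_estimate` with method `"fixed_effect"`.
#' @export
meta_fixed_effect <- function(estimates) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, logical(1), "mr_estimate")))
  scales <- unique(unlist(lapply(estimates, function(e) e$scale %||% NA_character_)))
  scales <- scales[!is.na(scales)]
  if (length(scales) > 1) {
    stop("cannot pool estimates on different scales: ",
         paste(scales, collapse = ", "), call. = FALSE)
  }
  if (length(estimates) == 1) return(estimates[[1]])
  theta <- vapply(estimates, `[[`, numeric(1), "theta")
  se <- vapply(estimates, `[[`, numeric(1), "se_theta")
  w <- 1 / se^2
  mr_estimate(sum(w * theta) / sum(w), sqrt(1 / sum(w)),
              sum(vapply(estimates, `[[`, integer(1), "n_variants")),
              "fixed_effect",
              scale = if (length(scales) == 1) scales else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
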