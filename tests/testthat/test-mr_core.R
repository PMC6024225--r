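test_that("Wald ratio arithmetic, sign and error handling", {
  e <- wald_ratio(0.2, 0.1, 0.05)
  expect_equal(e$theta, 0.5)
  expect_equal(e$se_theta, 0.25)
  en <- wald_ratio(-0.2, 0.1, 0.05)
  expect_equal(en$theta, -0.5)
  expect_equal(en$se_theta, 0.25)
  ei <- wald_ratio(1, 0.37, 0.11)
  expect_equal(c(ei$theta, ei$se_theta), c(0.37, 0.11))
  expect_error(wald_ratio(0, 0.1, 0.05), "weak")
})

test_that("generalized IVW matches closed forms on the worked examples", {
  mk <- function(rho12) {
    harmonized_set(c("a", "b"), c(0.5, 0.25), c(0.01, 0.01), c(1e-9, 1e-8),
                   c(0.2, 0.05), c(0.1, 0.1),
                   matrix(c(1, rho12, rho12, 1), 2))
  }
  e0 <- ivw_correlated(mk(0))
  expect_equal(e0$theta, 0.36, tolerance = 1e-12)
  expect_equal(e0$se_theta, 1 / sqrt(31.25), tolerance = 1e-12)
  e5 <- ivw_correlated(mk(0.5))     # hand GLS via the 2x2 inverse
  expect_equal(e5$theta, 0.4, tolerance = 1e-12)
  expect_equal(e5$se_theta, 0.2, tolerance = 1e-12)

  # single variant reduces to the Wald ratio
  h1 <- harmonized_set("a", 0.5, 0.01, 1e-9, 0.2, 0.1, matrix(1))
  e1 <- ivw_correlated(h1)
  w <- wald_ratio(0.5, 0.2, 0.1)
  expect_equal(e1$theta, w$theta)
  expect_equal(e1$se_theta, w$se_theta)
})

test_that("generalized IVW equals the explicit-inverse GLS oracle", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(2:30, 1)
    h <- random_harmonized(n)
    sigma <- h$se_outcome * h$ld * rep(h$se_outcome, each = n)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (max(ev) / min(ev) >= 1e6) next
    e <- ivw_correlated(h)
    o <- gls_oracle(h$beta_exposure, h$beta_outcome, sigma)
    expect_equal(e$theta, o$theta, tolerance = 1e-10)
    expect_equal(e$se_theta, o$se, tolerance = 1e-10)
  }
})

test_that("generalized IVW with identity LD equals the textbook IVW formula", {
  set.seed(202)
  for (rep in 1:50) {
    n <- sample(2:20, 1)
    h <- random_harmonized(n, rho = diag(n))
    e <- ivw_correlated(h)
    o <- ivw_uncorrelated_oracle(h$beta_exposure, h$beta_outcome, h$se_outcome)
    expect_equal(e$theta, o$theta, tolerance = 1e-10)
    expect_equal(e$se_theta, o$se, tolerance = 1e-10)
  }
})

test_that("estimates are invariant under simultaneous allele flips", {
  set.seed(303)
  for (rep in 1:20) {
    n <- 8
    h <- random_harmonized(n)
    flip <- sample(c(-1, 1), n, replace = TRUE)
    h2 <- h
    h2$beta_exposure <- flip * h$beta_exposure
    h2$beta_outcome <- flip * h$beta_outcome
    h2$ld <- h$ld * tcrossprod(flip)
    e1 <- ivw_correlated(h)
    e2 <- ivw_correlated(h2)
    expect_equal(e1$theta, e2$theta, tolerance = 1e-12)
    expect_equal(e1$se_theta, e2$se_theta, tolerance = 1e-12)
  }
})

test_that("p-values are consistent with theta and its standard error", {
  set.seed(404)
  for (rep in 1:20) {
    h <- random_harmonized(6)
    e <- ivw_correlated(h)
    expect_equal(e$pvalue, 2 * pnorm(-abs(e$theta / e$se_theta)),
                 tolerance = 1e-12)
  }
})

test_that("near-singular weight covariance is refused with a pointer to pc_ivw", {
  h <- harmonized_set(c("a", "b"), c(0.5, 0.5), c(0.01, 0.01), c(1e-9, 1e-9),
                      c(0.2, 0.2), c(0.1, 0.1), matrix(c(1, 1, 1, 1), 2))
  expect_error(ivw_correlated(h), "pc_ivw")
})

test_that("pc_ivw with all variance kept equals the unprojected estimator", {
  set.seed(505)
  for (rep in 1:20) {
    h <- random_harmonized(sample(3:10, 1))
    e_pc <- pc_ivw(h, variance_kept = 1.0)
    e_full <- ivw_correlated(h)
    expect_equal(e_pc$theta, e_full$theta, tolerance = 1e-8)
    expect_equal(e_pc$se_theta, e_full$se_theta, tolerance = 1e-8)
  }
})

test_that("pc_ivw resolves a perfectly duplicated variant to the duplicate-free answer", {
  # exact duplicate pair: rank-1 weighted matrix, k = 1, Wald answer
  h2 <- harmonized_set(c("a", "a2"), c(0.5, 0.5), c(0.01, 0.01),
                       c(1e-9, 1e-9), c(0.2, 0.2), c(0.1, 0.1),
                       matrix(1, 2, 2))
  e <- pc_ivw(h2)
  w <- wald_ratio(0.5, 0.2, 0.1)
  expect_equal(e$pc_k, 1L)
  expect_equal(e$theta, w$theta, tolerance = 1e-10)
  expect_equal(e$se_theta, w$se_theta, tolerance = 1e-10)

  # duplicate pair plus an independent variant: equals dropping the duplicate
  ld3 <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3)
  h3 <- harmonized_set(c("a", "a2", "c"), c(0.5, 0.5, 0.3), rep(0.01, 3),
                       rep(1e-9, 3), c(0.2, 0.2, 0.1), c(0.1, 0.1, 0.12), ld3)
  dedup <- ivw_correlated(subset_harmonized(h3, c("a", "c")))
  e3 <- pc_ivw(h3)
  expect_equal(e3$theta, dedup$theta, tolerance = 1e-10)
  expect_equal(e3$se_theta, dedup$se_theta, tolerance = 1e-10)
})

test_that("pc_ivw is stable on strong block LD, close to a pruned-subset estimate", {
  cfg <- sim_config(n_variants = 50, ld_structure = "blocks", ld_rho = 0.95,
                    block_size = 10, theta_true = 0.2, seed = 42)
  sim <- simulate_summary_pair(cfg)
  h <- suppressMessages(harmonize(sim$exposure, sim$outcome, sim$ld))
  e_pc <- pc_ivw(h, variance_kept = 0.99)
  pruned <- stepwise_select(h, r2_max = 0.4)
  e_pruned <- ivw_correlated(subset_harmonized(h, pruned))
  expect_lt(abs(e_pc$theta - e_pruned$theta), 2 * e_pruned$se_theta)
  expect_true(is.finite(e_pc$se_theta))
  expect_lt(e_pc$pc_k, 50)
})

test_that("pc_ivw validates its inputs", {
  h <- random_harmonized(4, seed = 1)
  expect_error(pc_ivw(h, variance_kept = 0), "variance_kept")
  expect_error(pc_ivw(h, variance_kept = 1.5), "variance_kept")
  h1 <- harmonized_set("a", 0.5, 0.01, 1e-9, 0.2, 0.1, matrix(1))
  expect_error(pc_ivw(h1), "at least 2")
})

test_that("odds-ratio conversion reproduces printed confidence intervals", {
  # null effect
  orr <- to_odds_ratio(wald_ratio(1, 0, 0.1))
  expect_equal(orr$or_point, 1.0)
  expect_equal(orr$ci_low, exp(-1.959964 * 0.1), tolerance = 1e-12)
  expect_equal(orr$ci_high, exp(1.959964 * 0.1), tolerance = 1e-12)
  expect_equal(c(orr$ci_low, orr$ci_high), c(0.8220, 1.2166),
               tolerance = 1e-4)

  # a published-style row "1.24 (1.01 to 1.51)": rebuilding theta and se from
  # the printed interval reproduces the printed bounds
  se <- (log(1.51) - log(1.01)) / (2 * 1.959964)
  theta_mid <- (log(1.51) + log(1.01)) / 2
  e_mid <- structure(list(theta = theta_mid, se_theta = se, pvalue = 0.038,
                          n_variants = 5L, method = "ivw_correlated",
                          pc_k = NA_integer_, scale = "log_odds"),
                     class = "mr_estimate")
  orr_mid <- to_odds_ratio(e_mid)
  expect_equal(orr_mid$ci_low, 1.01, tolerance = 1e-12)
  expect_equal(orr_mid$ci_high, 1.51, tolerance = 1e-12)
  # anchoring at the printed point 1.24 instead reproduces the printed
  # bounds to printed precision
  e_pt <- structure(list(theta = log(1.24), se_theta = se, pvalue = 0.038,
                         n_variants = 5L, method = "ivw_correlated",
                         pc_k = NA_integer_, scale = "log_odds"),
                    class = "mr_estimate")
  orr_pt <- to_odds_ratio(e_pt)
  expect_equal(orr_pt$ci_low, 1.01, tolerance = 0.01)
  expect_equal(orr_pt$ci_high, 1.51, tolerance = 0.01)

  # se -> 0: interval collapses onto the point
  tiny <- to_odds_ratio(wald_ratio(1, 0.2, 1e-12))
  expect_equal(tiny$ci_low, tiny$or_point, tolerance = 1e-9)
  expect_error(to_odds_ratio(wald_ratio(1, 0.2, 0.1), level = 1.2), "level")
})

test_that("fixed-effect pooling weights by inverse variance", {
  e1 <- structure(list(theta = 0.2, se_theta = 0.1, pvalue = 0.05,
                       n_variants = 3L, method = "ivw_correlated",
                       pc_k = NA_integer_, scale = "log_odds"),
                  class = "mr_estimate")
  e2 <- e1; e2$theta <- 0.4
  pooled <- meta_fixed_effect(list(e1, e2))
  expect_equal(pooled$theta, 0.3)
  expect_equal(pooled$se_theta, 0.1 / sqrt(2), tolerance = 1e-12)

  # single estimate: identity
  expect_identical(meta_fixed_effect(list(e1)), e1)

  # near-zero weight: result approaches the other estimate
  e3 <- e2; e3$se_theta <- 1e6
  pooled2 <- meta_fixed_effect(list(e1, e3))
  expect_equal(pooled2$theta, e1$theta, tolerance = 1e-6)

  # mixed scales refuse to pool
  e4 <- e2; e4$scale <- "continuous_sd"
  expect_error(meta_fixed_effect(list(e1, e4)), "different scales")
})
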