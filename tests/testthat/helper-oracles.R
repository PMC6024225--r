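# Independent oracles and fixture builders. These deliberately use the most
# direct (and least efficient) formulations -- explicit matrix inverses,
# double loops -- so they share no code path with the package.

# zero-intercept GLS via an explicit inverse
gls_oracle <- function(x, y, sigma) {
  si <- solve(sigma)
  theta <- as.numeric((t(x) %*% si %*% y) / (t(x) %*% si %*% x))
  se <- sqrt(1 / as.numeric(t(x) %*% si %*% x))
  list(theta = theta, se = se)
}

# textbook uncorrelated IVW closed form
ivw_uncorrelated_oracle <- function(bx, by, se_y) {
  w <- 1 / se_y^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  list(theta = theta, se = se)
}

# brute-force greedy selection: sort by (p, pos, id), then scan with a
# double loop over all kept pairs
greedy_oracle <- function(ids, p, pos, r2, r2_max) {
  ord <- order(p, ifelse(is.na(pos), .Machine$integer.max, pos), ids)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (r2[i, j] >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  ids[kept]
}

# random positive-definite correlation matrix
random_corr <- function(n) {
  a <- matrix(stats::rnorm(n * n), n)
  s <- crossprod(a) + n * diag(n)
  stats::cov2cor(s)
}

# random harmonized set for property tests
random_harmonized <- function(n, rho = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rho)) rho <- random_corr(n)
  bx <- stats::runif(n, 0.03, 0.3) * sample(c(-1, 1), n, replace = TRUE)
  se_y <- stats::runif(n, 0.05, 0.2)
  harmonized_set(
    variant_ids = sprintf("v%03d", seq_len(n)),
    beta_exposure = bx,
    se_exposure = stats::runif(n, 0.005, 0.02),
    p_exposure = stats::runif(n, 1e-10, 0.01),
    beta_outcome = 0.2 * bx + stats::rnorm(n, 0, 0.05),
    se_outcome = se_y,
    ld = rho,
    pos = seq_len(n) * 100L,
    outcome_scale = "log_odds")
}

# small in-memory summary dataset
toy_dataset <- function(df, ...) summary_dataset(df, ...)

toy_exposure <- function() {
  summary_dataset(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = "10", pos = c(100L, 200L, 300L),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.2, 0.4),
    beta = c(0.10, 0.08, 0.05),
    se = c(0.01, 0.01, 0.01),
    pvalue = NA, n = NA, info = 1,
    stringsAsFactors = FALSE),
    trait_name = "exposure", trait_scale = "log_transformed")
}
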