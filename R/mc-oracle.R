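# Independent Monte-Carlo validators for the analytic engines. Each one
# simulates raw data (or exact sufficient statistics) from the generative
# model, applies the standard test, and reports the empirical rejection rate.
# They deliberately share no code with the analytic formulas: agreement
# between the two routes is the package's correctness evidence.

new_oracle_result <- function(engine, rate, n_reps, seed, n_redrawn = 0L) {
  structure(
    list(engine = engine, rejection_rate = rate, n_reps = n_reps,
         se = sqrt(rate * (1 - rate) / n_reps), seed = seed,
         n_redrawn = n_redrawn),
    class = "eqtl_oracle"
  )
}

#' @export
print.eqtl_oracle <- function(x, ...) {
  cat("Monte-Carlo oracle (", x$engine, "): rejection rate ",
      format(x$rejection_rate, digits = 5), " (SE ",
      format(x$se, digits = 3), ", ", x$n_reps, " reps, seed ", x$seed,
      ")\n", sep = "")
  if (x$n_redrawn > 0)
    cat("  ", x$n_redrawn, "degenerate replicates redrawn\n")
  invisible(x)
}

# genotypes drawn from HWE as a reps x n matrix of additive codes
sim_genotypes <- function(n, reps, freqs) {
  matrix(sample.int(3L, n * reps, replace = TRUE, prob = freqs) - 1L,
         nrow = reps)
}

#' Monte-Carlo rejection rate for the bulk SLR engine
#'
#' Simulates `n_reps` bulk eQTL datasets (genotype from Hardy-Weinberg
#' proportions, expression from the linear model with residual SD
#' `sqrt(sigma_y^2 - slope^2 * 2 p (1-p))`), performs the ordinary
#' least-squares t-test of zero slope at the Bonferroni-adjusted level, and
#' reports the fraction of rejections. Replicates in which the sampled
#' genotypes are all identical (zero genotype variance) are redrawn and
#' counted.
#'
#' @inheritParams power_eqtl_slr
#' @param n_reps Number of simulated datasets.
#' @param seed Integer seed; fixed seed gives a fixed result.
#' @return An object of class `eqtl_oracle` with the rejection rate, its
#'   binomial standard error, and bookkeeping.
#' @export
oracle_slr <- function(n, maf, slope, sigma_y, fwer = 0.05, n_tests = 1e6,
                       n_reps = 1e5, seed = 1L) {
  check_count(n, "n", 3)
  check_count(n_reps, "n_reps", 1)
  geno <- hwe_genotype_model(maf)
  alpha <- per_test_alpha(fwer, n_tests)
  sigma_e <- residual_sd(slope, sigma_y, geno$var_additive)
  tc <- stats::qt(1 - alpha / 2, n - 2)

  set.seed(seed)
  rejected <- logical(0)
  redrawn <- 0L
  chunk <- max(1L, min(n_reps, floor(2e7 / n)))
  remaining <- n_reps
  while (remaining > 0L) {
    r <- min(chunk, remaining)
    x <- sim_genotypes(n, r, geno$freqs)
    sxx <- rowSums(x^2) - rowSums(x)^2 / n
    bad <- sxx <= 0
    while (any(bad)) { # zero genotype variance: t-test undefined, redraw
      redrawn <- redrawn + sum(bad)
      x[bad, ] <- sim_genotypes(n, sum(bad), geno$freqs)
      sxx <- rowSums(x^2) - rowSums(x)^2 / n
      bad <- sxx <= 0
    }
    e <- matrix(stats::rnorm(r * n, sd = sigma_e), nrow = r)
    y <- slope * x + e
    sxy <- rowSums(x * y) - rowSums(x) * rowSums(y) / n
    syy <- rowSums(y^2) - rowSums(y)^2 / n
    bhat <- sxy / sxx
    rss <- syy - bhat * sxy
    tstat <- bhat / sqrt(rss / (n - 2) / sxx)
    rejected <- c(rejected, abs(tstat) > tc)
    remaining <- remaining - r
  }
  new_oracle_result("bulk SLR", mean(rejected), n_reps, seed, redrawn)
}

#' Monte-Carlo rejection rate for the bulk ANOVA engine
#'
#' Simulates the one-way unbalanced ANOVA by drawing genotype group sizes
#' multinomially from the Hardy-Weinberg frequencies and then drawing the
#' exact sufficient statistics of each group (the group mean, normal with
#' variance `sigma^2 / n_k`, and the within-group sum of squares,
#' `sigma^2` times a chi-square with `n_k - 1` df). Replicates with any
#' group smaller than 2 are redrawn and counted.
#'
#' @inheritParams power_eqtl_anova
#' @inheritParams oracle_slr
#' @return An object of class `eqtl_oracle`.
#' @export
oracle_anova <- function(n, maf, delta, sigma, fwer = 0.05, n_tests = 1e6,
                         n_reps = 1e5, seed = 1L) {
  check_count(n, "n", 4)
  check_count(n_reps, "n_reps", 1)
  geno <- hwe_genotype_model(maf)
  alpha <- per_test_alpha(fwer, n_tests)
  mu <- c(0, delta[1], delta[1] + delta[2])
  fc <- stats::qf(1 - alpha, 2, n - 3)

  set.seed(seed)
  draw_sizes <- function(r) {
    nk <- stats::rmultinom(r, n, prob = geno$freqs)
    redraw <- colSums(nk < 2) > 0
    cnt <- 0L
    while (any(redraw)) {
      cnt <- cnt + sum(redraw)
      nk[, redraw] <- stats::rmultinom(sum(redraw), n, prob = geno$freqs)
      redraw <- colSums(nk < 2) > 0
    }
    list(nk = nk, redrawn = cnt)
  }
  ds <- draw_sizes(n_reps)
  nk <- ds$nk # 3 x n_reps
  ybar <- matrix(stats::rnorm(3L * n_reps, mean = mu,
                              sd = sigma / sqrt(nk)), nrow = 3L)
  ssw <- sigma^2 * matrix(stats::rchisq(3L * n_reps, df = nk - 1L),
                          nrow = 3L)
  grand <- colSums(nk * ybar) / n
  ssb <- colSums(nk * sweep(ybar, 2, grand)^2)
  fstat <- (ssb / 2) / (colSums(ssw) / (n - 3))
  new_oracle_result("bulk ANOVA", mean(fstat > fc), n_reps, seed,
                    ds$redrawn)
}

#' Monte-Carlo rejection rate for the single-cell LMM engine
#'
#' Simulates the random-intercept model (conditional intra-subject
#' correlation `rho` applied to the residual variance, so the marginal
#' outcome variance is `sigma_y^2`) and applies the exact generalized
#' least-squares test of the genotype slope with the covariance treated as
#' known. Because the genotype is constant within a subject, the GLS
#' estimator depends on the data only through the subject means, whose
#' variance is `sigma_e^2 (1 + (m-1) rho) / m`; the oracle simulates those
#' sufficient statistics directly and rejects on the exact normal test.
#'
#' @inheritParams power_eqtl_sclmm
#' @inheritParams oracle_slr
#' @return An object of class `eqtl_oracle`.
#' @export
oracle_sclmm <- function(n, m, rho, maf, slope, sigma_y, fwer = 0.05,
                         n_tests = 1e6, n_reps = 1e4, seed = 1L) {
  check_count(n, "n", 3)
  check_count(m, "m", 1)
  check_count(n_reps, "n_reps", 1)
  geno <- hwe_genotype_model(maf)
  alpha <- per_test_alpha(fwer, n_tests)
  sigma_e <- residual_sd(slope, sigma_y, geno$var_additive)
  v_mean <- sigma_e^2 * (1 + (m - 1) * rho) / m # Var(subject mean | x)
  zc <- stats::qnorm(1 - alpha / 2)

  set.seed(seed)
  x <- sim_genotypes(n, n_reps, geno$freqs)
  sxx <- rowSums(x^2) - rowSums(x)^2 / n
  bad <- sxx <= 0
  redrawn <- 0L
  while (any(bad)) {
    redrawn <- redrawn + sum(bad)
    x[bad, ] <- sim_genotypes(n, sum(bad), geno$freqs)
    sxx <- rowSums(x^2) - rowSums(x)^2 / n
    bad <- sxx <= 0
  }
  ybar <- slope * x + matrix(stats::rnorm(n_reps * n, sd = sqrt(v_mean)),
                             nrow = n_reps)
  sxy <- rowSums(x * ybar) - rowSums(x) * rowSums(ybar) / n
  z <- (sxy / sxx) / sqrt(v_mean / sxx)
  new_oracle_result("single-cell LMM", mean(abs(z) > zc), n_reps, seed,
                    redrawn)
}
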