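# Analytic power for bulk-tissue eQTL: one expression value per subject,
# tested against genotype either by simple linear regression on the additive
# code (t-test of the slope) or by one-way unbalanced ANOVA across the three
# genotype groups (overall F-test).

new_power_result <- function(engine, power, alpha_per_test, df, ncp, params) {
  structure(
    list(engine = engine, power = power, alpha_per_test = alpha_per_test,
         df = df, ncp = ncp, params = params),
    class = "eqtl_power"
  )
}

#' @export
print.eqtl_power <- function(x, ...) {
  cat("eQTL power calculation (", x$engine, ")\n", sep = "")
  p <- x$params
  cat("  ", paste(names(p), vapply(p, format, ""), sep = " = ",
                  collapse = ", "), "\n", sep = "")
  cat("  per-test alpha =", format(x$alpha_per_test),
      " df =", paste(format(x$df), collapse = ", "),
      " ncp =", format(x$ncp, digits = 6), "\n")
  cat("  power =", format(x$power, digits = 6), "\n")
  invisible(x)
}

# two-sided power of a noncentral-t Wald test at level alpha
power_t2 <- function(ncp, df, alpha) {
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp = ncp) + stats::pt(tc, df, ncp = ncp,
                                            lower.tail = FALSE)
}

# real-valued power kernels shared with the inversion module; n may be
# non-integer there (the root is taken before rounding up)
slr_power_value <- function(n, maf, slope, sigma_y, alpha) {
  va <- 2 * maf * (1 - maf)
  sigma_e <- residual_sd(slope, sigma_y, va)
  power_t2(slope * sqrt(va) * sqrt(n) / sigma_e, n - 2, alpha)
}

anova_power_value <- function(n, maf, delta, sigma, alpha) {
  mu <- c(0, delta[1], delta[1] + delta[2])
  p <- maf
  w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  mu_bar <- sum(w * mu)
  ncp <- n * sum(w * (mu - mu_bar)^2) / sigma^2
  stats::pf(stats::qf(1 - alpha, 2, n - 3), 2, n - 3, ncp = ncp,
            lower.tail = FALSE)
}

sclmm_power_value <- function(n, m, rho, maf, slope, sigma_y, alpha) {
  va <- 2 * maf * (1 - maf)
  sigma_e <- residual_sd(slope, sigma_y, va)
  ncp <- slope * sqrt(va) * sqrt(n * m) /
    (sigma_e * sqrt(1 + (m - 1) * rho))
  power_t2(ncp, n * m - 2, alpha)
}

#' Power of bulk-tissue eQTL by simple linear regression
#'
#' Two-sided power of the t-test of zero slope in the regression of a
#' subject-level expression value on the additively coded genotype, with the
#' genotype drawn from Hardy-Weinberg proportions at the given MAF.
#'
#' The outcome is parameterized by its marginal standard deviation
#' `sigma_y`, so the residual SD is
#' `sigma_e = sqrt(sigma_y^2 - slope^2 * 2 p (1-p))`. The test statistic has
#' a noncentral t distribution with `n - 2` degrees of freedom and
#' noncentrality `slope * sqrt(2 p (1-p)) * sqrt(n) / sigma_e`, and the test
#' is carried out at the Bonferroni-adjusted level `fwer / n_tests`.
#'
#' @param n Number of subjects (>= 3).
#' @param maf Minor allele frequency in (0, 0.5].
#' @param slope Change in expression per copy of the minor allele.
#' @param sigma_y Marginal SD of the expression value (> 0); must satisfy
#'   `slope^2 * 2 maf (1-maf) < sigma_y^2`.
#' @param fwer Family-wise error rate (default 0.05).
#' @param n_tests Number of SNP-gene pairs tested (default 1e6).
#'
#' @return An object of class `eqtl_power` with elements `power`,
#'   `alpha_per_test`, `df`, `ncp` and the resolved parameters.
#'
#' @examples
#' power_eqtl_slr(n = 100, maf = 0.2, slope = 0.13, sigma_y = 0.13,
#'                fwer = 0.05, n_tests = 200000)
#' @export
power_eqtl_slr <- function(n, maf, slope, sigma_y, fwer = 0.05,
                           n_tests = 1e6) {
  check_count(n, "n", 3)
  geno <- hwe_genotype_model(maf)
  check_positive(sigma_y, "sigma_y")
  alpha <- per_test_alpha(fwer, n_tests)
  sigma_e <- residual_sd(slope, sigma_y, geno$var_additive)
  ncp <- slope * sqrt(geno$var_additive) * sqrt(n) / sigma_e
  df <- n - 2
  new_power_result("bulk SLR", power_t2(ncp, df, alpha), alpha,
                   c(df = df), ncp,
                   list(n = n, maf = maf, slope = slope, sigma_y = sigma_y,
                        fwer = fwer, n_tests = n_tests))
}

#' Power of bulk-tissue eQTL by one-way unbalanced ANOVA
#'
#' Power of the overall F-test of equal mean expression across the three
#' genotype groups (the model used by the GTEx consortium), with group
#' weights taken as the Hardy-Weinberg genotype frequencies. Means are
#' anchored at the homozygous-major group, so the effect is given as the two
#' successive mean differences `delta = c(mu_het - mu_hom_major,
#' mu_hom_minor - mu_het)`.
#'
#' The noncentrality parameter is `n * sum_k w_k (mu_k - mu_bar)^2 / sigma^2`
#' with HWE weights `w`, and the reference distribution is noncentral F with
#' 2 and `n - 3` degrees of freedom. Group sizes in a real study are random;
#' the closed form uses their expectations.
#'
#' @param n Number of subjects (>= 4).
#' @param maf Minor allele frequency in (0, 0.5].
#' @param delta Length-2 numeric: genotype-group mean differences
#'   (heterozygous minus homozygous-major, homozygous-minor minus
#'   heterozygous), in expression units.
#' @param sigma Within-group SD of expression (> 0).
#' @inheritParams power_eqtl_slr
#'
#' @return An object of class `eqtl_power`.
#'
#' @examples
#' power_eqtl_anova(n = 200, maf = 0.3, delta = c(0.13, 0.13), sigma = 0.13,
#'                  fwer = 0.05, n_tests = 200000)
#' @export
power_eqtl_anova <- function(n, maf, delta, sigma, fwer = 0.05,
                             n_tests = 1e6) {
  check_count(n, "n", 4)
  geno <- hwe_genotype_model(maf)
  check_positive(sigma, "sigma")
  if (!is.numeric(delta) || length(delta) != 2L || any(!is.finite(delta)))
    stop("'delta' must be a numeric vector of two finite mean differences",
         call. = FALSE)
  alpha <- per_test_alpha(fwer, n_tests)
  mu <- c(0, delta[1], delta[1] + delta[2])
  w <- unname(geno$freqs)
  mu_bar <- sum(w * mu)
  ncp <- n * sum(w * (mu - mu_bar)^2) / sigma^2
  df1 <- 2
  df2 <- n - 3
  pw <- stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = ncp,
                  lower.tail = FALSE)
  new_power_result("bulk ANOVA", pw, alpha, c(df1 = df1, df2 = df2), ncp,
                   list(n = n, maf = maf, delta1 = delta[1],
                        delta2 = delta[2], sigma = sigma, fwer = fwer,
                        n_tests = n_tests))
}
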