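# Analytic power for single-cell eQTL under a random-intercept linear mixed
# model: y_ij = b0_i + b1 * x_i + e_ij for cell j of subject i, with x_i the
# additively coded genotype. Cells from one subject are exchangeable with
# intra-subject correlation rho, so m cells carry the information of
# m / (1 + (m - 1) rho) independent ones (the design effect).

#' Power of single-cell eQTL by a random-intercept linear mixed model
#'
#' Two-sided power to detect a nonzero genotype slope on (suitably
#' transformed, approximately Gaussian) single-cell expression, when each of
#' `n` subjects contributes `m` cells whose residuals share an intra-subject
#' correlation `rho`.
#'
#' With marginal outcome SD `sigma_y`, residual SD
#' `sigma_e = sqrt(sigma_y^2 - slope^2 * 2 p (1-p))` and design effect
#' `deff = 1 + (m - 1) * rho`, the noncentrality parameter is
#' `slope * sqrt(2 p (1-p)) * sqrt(n m) / (sigma_e * sqrt(deff))` and the
#' reference distribution is noncentral t with `n m - 2` degrees of freedom.
#' At `m = 1` or `rho = 0` this reduces exactly to the bulk
#' simple-linear-regression engine with `n m` subjects; as `rho` approaches 1
#' extra cells add no information and the noncentrality collapses to the
#' bulk value at `n` subjects.
#'
#' @param n Number of subjects (>= 3).
#' @param m Number of cells per subject (>= 1).
#' @param rho Intra-subject correlation of expression between two cells of
#'   the same subject, in [0, 1).
#' @inheritParams power_eqtl_slr
#'
#' @return An object of class `eqtl_power`.
#'
#' @examples
#' power_eqtl_sclmm(n = 50, m = 100, rho = 0.3, maf = 0.2,
#'                  slope = 0.1, sigma_y = 0.5, fwer = 0.05, n_tests = 1)
#' @export
power_eqtl_sclmm <- function(n, m, rho, maf, slope, sigma_y, fwer = 0.05,
                             n_tests = 1e6) {
  check_count(n, "n", 3)
  check_count(m, "m", 1)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < 0 || rho >= 1)
    stop("'rho' must be a single number in [0, 1)", call. = FALSE)
  geno <- hwe_genotype_model(maf)
  check_positive(sigma_y, "sigma_y")
  alpha <- per_test_alpha(fwer, n_tests)
  sigma_e <- residual_sd(slope, sigma_y, geno$var_additive)
  deff <- 1 + (m - 1) * rho
  ncp <- slope * sqrt(geno$var_additive) * sqrt(n * m) /
    (sigma_e * sqrt(deff))
  df <- n * m - 2
  new_power_result("single-cell LMM", power_t2(ncp, df, alpha), alpha,
                   c(df = df), ncp,
                   list(n = n, m = m, rho = rho, maf = maf, slope = slope,
                        sigma_y = sigma_y, fwer = fwer, n_tests = n_tests))
}

#' Effective sample size of a clustered single-cell design
#'
#' The number of independent observations that carries the same information
#' as `n` subjects with `m` correlated cells each:
#' `n * m / (1 + (m - 1) * rho)`.
#'
#' @inheritParams power_eqtl_sclmm
#' @return A single number between `n` and `n * m`.
#' @examples
#' effective_sample_size(50, 100, 0.3) # far fewer than 5000 cells
#' @export
effective_sample_size <- function(n, m, rho) {
  check_count(n, "n", 1)
  check_count(m, "m", 1)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < 0 || rho >= 1)
    stop("'rho' must be a single number in [0, 1)", call. = FALSE)
  n * m / (1 + (m - 1) * rho)
}
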