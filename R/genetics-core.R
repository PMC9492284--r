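#' Genotype model under Hardy-Weinberg equilibrium
#'
#' Builds the genotype frequency model implied by a minor allele frequency
#' (MAF) under Hardy-Weinberg equilibrium (HWE), together with the variance
#' of the additive genotype code (0 copies, 1 copy, 2 copies of the minor
#' allele). All analytic power engines in this package treat the genotype as
#' a random draw from this model.
#'
#' @param maf Minor allele frequency, a single number in (0, 0.5]. Values
#'   above 0.5 are rejected rather than folded: the minor allele is by
#'   definition the less common one, and silently folding hides input errors.
#'
#' @return An object of class `hwe_genotype_model`: a list with elements
#'   `maf`, `freqs` (named probabilities of the homozygous-major,
#'   heterozygous and homozygous-minor genotypes, `(1-p)^2`, `2p(1-p)`,
#'   `p^2`) and `var_additive` (`2p(1-p)`, the variance of the 0/1/2 code).
#'
#' @examples
#' hwe_genotype_model(0.2)
#' hwe_genotype_model(0.5)$var_additive # maximal, 0.5
#' @export
hwe_genotype_model <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || !is.finite(maf) ||
      maf <= 0 || maf > 0.5) {
    stop("'maf' must be a single number in (0, 0.5]; got ",
         deparse(substitute(maf)), " = ", format(maf), call. = FALSE)
  }
  p <- maf
  freqs <- c(hom_major = (1 - p)^2, het = 2 * p * (1 - p), hom_minor = p^2)
  structure(
    list(maf = p, freqs = freqs, var_additive = 2 * p * (1 - p)),
    class = "hwe_genotype_model"
  )
}

#' @export
print.hwe_genotype_model <- function(x, ...) {
  cat("HWE genotype model (MAF =", format(x$maf), ")\n")
  cat("  genotype frequencies:",
      paste(names(x$freqs), format(x$freqs, digits = 4), sep = "=",
            collapse = ", "), "\n")
  cat("  additive-code variance:", format(x$var_additive, digits = 6), "\n")
  invisible(x)
}

#' Per-test significance level under Bonferroni control
#'
#' eQTL scans test very many SNP-gene pairs; the package controls the
#' family-wise error rate (FWER) across all of them by Bonferroni, so each
#' single test is carried out at level `fwer / n_tests`.
#'
#' @param fwer Family-wise error rate in (0, 1).
#' @param n_tests Number of SNP-gene pairs tested (positive integer).
#'
#' @return The per-test significance level `fwer / n_tests`.
#' @examples
#' per_test_alpha(0.05, 1e6) # 5e-8, the usual genome-wide scale
#' @export
per_test_alpha <- function(fwer, n_tests) {
  if (!is.numeric(fwer) || length(fwer) != 1L || !is.finite(fwer) ||
      fwer <= 0 || fwer >= 1) {
    stop("'fwer' must be a single number in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(n_tests) || length(n_tests) != 1L || !is.finite(n_tests) ||
      n_tests < 1 || n_tests != trunc(n_tests)) {
    stop("'n_tests' must be a single integer >= 1", call. = FALSE)
  }
  fwer / n_tests
}

# shared parameter checks -----------------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("'", name, "' must be a single positive number", call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != trunc(x))
    stop("'", name, "' must be an integer >= ", min, call. = FALSE)
  invisible(x)
}

# residual SD of the outcome after removing the genotype effect; errors when
# the claimed slope is infeasible for the stated marginal SD
residual_sd <- function(slope, sigma_y, var_additive) {
  v <- sigma_y^2 - slope^2 * var_additive
  if (v <= 0) {
    stop("infeasible effect: slope^2 * var_additive = ",
         format(slope^2 * var_additive),
         " must be < sigma_y^2 = ", format(sigma_y^2),
         " (|slope| < ", format(sigma_y / sqrt(var_additive)), ")",
         call. = FALSE)
  }
  sqrt(v)
}
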