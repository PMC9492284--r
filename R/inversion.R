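# Solve for any one of {power, sample size, effect size, minimum allowable
# MAF} given the other three, for each analytic engine. Power is monotone in
# each unknown on its natural domain, so the solver is bracketed scalar
# root-finding; sample sizes are rounded up to the smallest integer that
# meets the target.

#' Solve an eQTL design for power, sample size, effect size or MAF
#'
#' Given three of the four interrelated design quantities -- power, number
#' of subjects, effect size, and minor allele frequency -- computes the
#' fourth. Pass exactly one of `power`, `n`, `effect`, `maf` as `NULL` to
#' mark it as the unknown.
#'
#' The effect size is the genotype slope for the `"slr"` and `"sc_lmm"`
#' engines. For `"anova"` the effect is a positive scale factor applied to
#' `delta_direction` (a two-dimensional group-mean-difference pattern cannot
#' be recovered from a single power value, so its direction must be
#' supplied; solving gives `delta = effect * delta_direction`).
#'
#' Solving for `n` returns the smallest integer sample size whose power
#' reaches the target, together with the power actually achieved there.
#' Solving for `effect` returns the minimum detectable (positive) effect;
#' solving for `maf` returns the minimum allowable minor allele frequency.
#' If the target power is unattainable anywhere on the search interval the
#' solver stops with an error reporting the attainable power range.
#'
#' @param engine One of `"slr"`, `"anova"`, `"sc_lmm"`.
#' @param power Target power in `(alpha_per_test, 1)`, or `NULL` to compute
#'   it from the other three.
#' @param n Number of subjects, or `NULL` to solve for it.
#' @param effect Genotype slope (`"slr"`, `"sc_lmm"`) or scale on
#'   `delta_direction` (`"anova"`), or `NULL` to solve for it.
#' @param maf Minor allele frequency in (0, 0.5], or `NULL` to solve for it.
#' @param sigma_y Marginal outcome SD (`"slr"`, `"sc_lmm"`).
#' @param sigma Within-genotype-group SD (`"anova"`).
#' @param delta_direction Length-2 pattern of genotype-group mean
#'   differences scaled by `effect` (`"anova"` only).
#' @param m,rho Cells per subject and intra-subject correlation
#'   (`"sc_lmm"` only).
#' @inheritParams power_eqtl_slr
#' @param n_bounds Search interval for `n`.
#' @param maf_bounds Search interval for `maf` (upper limit 0.5; tightened
#'   automatically when large MAF would make the stated slope infeasible).
#'
#' @return An object of class `eqtl_solve`: a list with `engine`, `unknown`,
#'   `value` (the solved parameter), `achieved_power`, `target_power` and
#'   the resolved known parameters.
#'
#' @examples
#' # minimum sample size for 80% power in a 200k-test bulk scan
#' solve_eqtl("slr", power = 0.8, n = NULL, effect = 0.13, maf = 0.2,
#'            sigma_y = 0.13, n_tests = 2e5)
#' # minimum detectable slope for a fixed single-cell design
#' solve_eqtl("sc_lmm", power = 0.8, n = 100, effect = NULL, maf = 0.2,
#'            m = 50, rho = 0.3, sigma_y = 0.5, n_tests = 1e4)
#' @export
solve_eqtl <- function(engine = c("slr", "anova", "sc_lmm"),
                       power = NULL, n = NULL, effect = NULL, maf = NULL,
                       sigma_y = 0.13, sigma = 0.13,
                       delta_direction = c(1, 1),
                       m = NULL, rho = NULL,
                       fwer = 0.05, n_tests = 1e6,
                       n_bounds = c(4, 1e7),
                       maf_bounds = c(1e-6, 0.5)) {
  engine <- match.arg(engine)
  unknowns <- c(power = is.null(power), n = is.null(n),
                effect = is.null(effect), maf = is.null(maf))
  if (sum(unknowns) != 1L)
    stop("exactly one of 'power', 'n', 'effect', 'maf' must be NULL; got ",
         sum(unknowns), " unknowns (",
         paste(names(unknowns)[unknowns], collapse = ", "), ")",
         call. = FALSE)
  unknown <- names(unknowns)[unknowns]
  alpha <- per_test_alpha(fwer, n_tests)
  if (engine == "sc_lmm") {
    if (is.null(m) || is.null(rho))
      stop("'m' and 'rho' are required for the sc_lmm engine",
           call. = FALSE)
    check_count(m, "m", 1)
  }
  if (!is.null(power)) {
    if (!is.numeric(power) || length(power) != 1L || power <= alpha ||
        power >= 1)
      stop("target 'power' must lie in (alpha_per_test, 1) = (",
           format(alpha), ", 1)", call. = FALSE)
  }

  n_min <- if (engine == "anova") 4 else 3
  n_lo <- max(n_min, n_bounds[1])

  # forward power at possibly non-integer n
  pw <- function(n., effect., maf.) {
    switch(engine,
      slr = slr_power_value(n., maf., effect., sigma_y, alpha),
      anova = anova_power_value(n., maf., effect. * delta_direction,
                                sigma, alpha),
      sc_lmm = sclmm_power_value(n., m, rho, maf., effect., sigma_y, alpha))
  }

  done <- function(value, achieved) {
    structure(
      list(engine = engine, unknown = unknown, value = value,
           achieved_power = achieved, target_power = power,
           alpha_per_test = alpha,
           params = list(n = n, effect = effect, maf = maf,
                         sigma_y = sigma_y, sigma = sigma, m = m, rho = rho,
                         fwer = fwer, n_tests = n_tests)),
      class = "eqtl_solve")
  }

  if (unknown == "power") {
    check_count(n, "n", n_min)
    val <- pw(n, effect, maf)
    return(done(val, val))
  }

  solve_root <- function(f, lower, upper, what) {
    plo <- f(lower)
    phi <- f(upper)
    lo_p <- min(plo, phi); hi_p <- max(plo, phi)
    if (power < lo_p || power > hi_p)
      stop("target power ", format(power), " is unattainable for '", what,
           "' on [", format(lower), ", ", format(upper),
           "]: attainable range is [", format(lo_p, digits = 6), ", ",
           format(hi_p, digits = 6), "]", call. = FALSE)
    if (hi_p - lo_p < 1e-10)
      stop("power is flat in '", what, "' across the search interval; ",
           "the design is degenerate and no meaningful root exists",
           call. = FALSE)
    stats::uniroot(function(u) f(u) - power, lower = lower, upper = upper,
                   f.lower = plo - power, f.upper = phi - power,
                   tol = .Machine$double.eps^0.75, maxiter = 2000L)$root
  }

  if (unknown == "n") {
    root <- solve_root(function(u) pw(u, effect, maf),
                       n_lo, n_bounds[2], "n")
    n_sol <- ceiling(root - 1e-9)
    while (n_sol > n_lo && pw(n_sol - 1, effect, maf) >= power)
      n_sol <- n_sol - 1
    while (pw(n_sol, effect, maf) < power) n_sol <- n_sol + 1
    return(done(as.integer(n_sol), pw(n_sol, effect, maf)))
  }

  if (unknown == "effect") {
    check_count(n, "n", n_min)
    if (engine == "anova") {
      upper <- 1
      while (pw(n, upper, maf) < power && upper < 1e8) upper <- upper * 2
      root <- solve_root(function(u) pw(n, u, maf), 1e-12, upper, "effect")
    } else {
      va <- 2 * maf * (1 - maf)
      upper <- sigma_y / sqrt(va) * (1 - 1e-9) # open feasibility boundary
      root <- solve_root(function(u) pw(n, u, maf), 1e-12, upper, "effect")
    }
    return(done(root, pw(n, root, maf)))
  }

  # unknown == "maf": tighten the upper bound if large MAF makes the slope
  # infeasible (slope^2 * 2p(1-p) must stay below sigma_y^2)
  check_count(n, "n", n_min)
  hi <- maf_bounds[2]
  if (engine != "anova") {
    vmax <- (sigma_y / effect)^2 * (1 - 1e-9)
    if (vmax < 0.5) hi <- min(hi, (1 - sqrt(1 - 2 * vmax)) / 2)
  }
  root <- solve_root(function(u) pw(n, effect, u), maf_bounds[1], hi, "maf")
  done(root, pw(n, effect, root))
}

#' @export
print.eqtl_solve <- function(x, ...) {
  cat("eQTL design solution (", x$engine, "): ", x$unknown, " = ",
      format(x$value, digits = 8), "\n", sep = "")
  if (!is.null(x$target_power))
    cat("  target power =", format(x$target_power), "\n")
  cat("  achieved power =", format(x$achieved_power, digits = 8),
      " (per-test alpha =", format(x$alpha_per_test), ")\n")
  invisible(x)
}
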