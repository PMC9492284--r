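engines <- list(
  slr = list(engine = "slr", n = 200, effect = 0.18, maf = 0.2,
             sigma_y = 0.5, fwer = 0.05, n_tests = 10),
  anova = list(engine = "anova", n = 300, effect = 0.1, maf = 0.3,
               sigma = 0.3, delta_direction = c(1, 1), fwer = 0.05,
               n_tests = 10),
  sc_lmm = list(engine = "sc_lmm", n = 60, effect = 0.2, maf = 0.2,
                m = 50, rho = 0.3, sigma_y = 0.5, fwer = 0.05,
                n_tests = 10))

test_that("solving for power is the forward evaluation", {
  forward <- list(
    slr = function(a) power_eqtl_slr(a$n, a$maf, a$effect, a$sigma_y,
                                     a$fwer, a$n_tests)$power,
    anova = function(a) power_eqtl_anova(a$n, a$maf,
                                         a$effect * a$delta_direction,
                                         a$sigma, a$fwer, a$n_tests)$power,
    sc_lmm = function(a) power_eqtl_sclmm(a$n, a$m, a$rho, a$maf, a$effect,
                                          a$sigma_y, a$fwer,
                                          a$n_tests)$power)
  for (nm in names(engines)) {
    a <- engines[[nm]]
    sol <- do.call(solve_eqtl, c(a, list(power = NULL)))
    expect_equal(sol$unknown, "power")
    expect_equal(sol$value, forward[[nm]](a))
    expect_gt(sol$value, 0)
    expect_lt(sol$value, 1)
  }
})

test_that("round-trip: solving each unknown at target 0.8 reproduces it", {
  for (a in engines) {
    # n: smallest integer reaching the target, bracketing at n-1
    sn <- do.call(solve_eqtl, modifyList(c(a, list(power = 0.8)),
                                         list(n = NULL)))
    expect_gte(sn$achieved_power, 0.8)
    below <- do.call(solve_eqtl,
                     modifyList(c(a, list(power = NULL)),
                                list(n = sn$value - 1L)))
    expect_lt(below$achieved_power, 0.8)

    # effect: continuous root, power within 1e-6
    se <- do.call(solve_eqtl, modifyList(c(a, list(power = 0.8)),
                                         list(effect = NULL)))
    expect_gt(se$value, 0)
    expect_equal(se$achieved_power, 0.8, tolerance = 1e-6)

    # maf: continuous root, power within 1e-6
    sm <- do.call(solve_eqtl, modifyList(c(a, list(power = 0.8)),
                                         list(maf = NULL)))
    expect_gt(sm$value, 0)
    expect_lte(sm$value, 0.5)
    expect_equal(sm$achieved_power, 0.8, tolerance = 1e-6)
  }
})

test_that("solved minimum sample size is confirmed by the Monte-Carlo
           oracle at the boundary", {
  sol <- solve_eqtl("slr", power = 0.8, n = NULL, effect = 0.13, maf = 0.2,
                    sigma_y = 0.13, fwer = 0.05, n_tests = 200000)
  expect_gte(sol$achieved_power, 0.8)
  o <- oracle_slr(sol$value, 0.2, 0.13, 0.13, fwer = 0.05,
                  n_tests = 200000, n_reps = 2e4, seed = 13)
  # independent comparator: exact power of the design averaged over the
  # random genotype draw (conditional noncentral-t power at each realized
  # genotype variance), which the oracle estimates
  set.seed(13)
  n <- sol$value
  alpha <- per_test_alpha(0.05, 200000)
  sigma_e <- sqrt(0.13^2 - 0.13^2 * 0.32)
  x <- matrix(sample(0:2, n * 2e4, TRUE, c(0.64, 0.32, 0.04)), 2e4)
  sxx <- rowSums(x^2) - rowSums(x)^2 / n
  sxx <- sxx[sxx > 0]
  tc <- qt(1 - alpha / 2, n - 2)
  ncp <- 0.13 * sqrt(sxx) / sigma_e
  exact <- mean(pt(-tc, n - 2, ncp) +
                  pt(tc, n - 2, ncp, lower.tail = FALSE))
  expect_lt(abs(o$rejection_rate - exact), 3 * o$se)
  # the closed form (expected genotype variance) sits close above it
  expect_lt(abs(sol$achieved_power - exact), 0.05)
})

test_that("minimum detectable slope shrinks to zero as the target
           approaches the per-test alpha", {
  alpha <- per_test_alpha(0.05, 100)
  slopes <- vapply(c(1e-2, 1e-4, 1e-6), function(eps) {
    solve_eqtl("slr", power = alpha + eps, n = 500, effect = NULL,
               maf = 0.2, sigma_y = 0.5, fwer = 0.05, n_tests = 100)$value
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
  expect_lt(slopes[3], 1e-3)
})

test_that("unattainable targets and ill-posed requests error informatively", {
  # power at maf = 0.5 is the ceiling; ask above it
  top <- solve_eqtl("slr", power = NULL, n = 50, effect = 0.05, maf = 0.5,
                    sigma_y = 0.5, fwer = 0.05, n_tests = 100)
  expect_error(
    solve_eqtl("slr", power = min(0.99, top$value + 0.5), n = 50,
               effect = 0.05, maf = NULL, sigma_y = 0.5, fwer = 0.05,
               n_tests = 100),
    "attainable")
  expect_error(solve_eqtl("slr", power = NULL, n = NULL, effect = 0.1,
                          maf = 0.2, sigma_y = 0.5),
               "exactly one")
  expect_error(solve_eqtl("sc_lmm", power = 0.8, n = NULL, effect = 0.1,
                          maf = 0.2, sigma_y = 0.5),
               "'m' and 'rho'")
})
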