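test_that("ZINB simulation is reproducible and respects structural zeros", {
  args <- list(n = 30, m = 40, maf = 0.3, slope = 0.5, mean_int = 1,
               sd_int = 0.5, zero_p = 0.2, theta = 2)
  d1 <- do.call(simulate_zinb_dataset, c(args, seed = 21))
  d2 <- do.call(simulate_zinb_dataset, c(args, seed = 21))
  expect_identical(d1, d2)
  expect_true(all(d1$counts >= 0))
  expect_identical(dim(d1$counts), c(30L, 40L))
  expect_true(all(d1$genotype %in% 0:2))

  # structural zeros lower-bound the observed zero fraction
  dz <- simulate_zinb_dataset(50, 100, 0.3, 0, mean_int = -5, sd_int = 0.2,
                              zero_p = 0.9, theta = 2, seed = 22)
  expect_gte(mean(dz$counts == 0), 0.9)
})

test_that("theta -> Inf with no zero inflation approaches the Poisson
           limit in mean and variance", {
  d <- simulate_zinb_dataset(1, 2e4, 0.5, 0, mean_int = 1, sd_int = 0,
                             zero_p = 0, theta = 1e8, seed = 23)
  y <- as.numeric(d$counts)
  mu <- exp(1)
  expect_lt(abs(mean(y) - mu), 3 * sqrt(mu / length(y)))
  # SE of the sample variance of a Poisson: sqrt((mu + 2 mu^2) / n)
  expect_lt(abs(var(y) - mu), 3 * sqrt((mu + 2 * mu^2) / length(y)))
})

test_that("marginal moments match the zero-inflated NB by direct
           computation", {
  zero_p <- 0.3; theta <- 2; mu <- exp(1.2)
  d <- simulate_zinb_dataset(1, 1e5, 0.5, 0, mean_int = 1.2, sd_int = 0,
                             zero_p = zero_p, theta = theta, seed = 24)
  y <- as.numeric(d$counts)
  m1 <- (1 - zero_p) * mu                 # E[Y] of the mixture
  v_nb <- mu + mu^2 / theta
  v <- (1 - zero_p) * (v_nb + mu^2) - m1^2 # Var[Y] of the mixture
  expect_lt(abs(mean(y) - m1), 3 * sqrt(v / length(y)))
})

test_that("the AGHQ fitter recovers generating parameters on one dataset", {
  d <- simulate_zinb_dataset(100, 50, 0.3, 0.8, mean_int = 1, sd_int = 0.5,
                             zero_p = 0.1, theta = 2, seed = 31)
  f <- fit_zinb_mixed(d$counts, d$genotype)
  expect_true(f$converged)
  expect_lt(abs(f$estimates[["slope"]] - 0.8), 4 * f$se_slope)
  expect_lt(abs(f$estimates[["zero_p"]] - 0.1), 0.05)
  expect_lt(abs(f$estimates[["theta"]] - 2), 0.5)
  expect_lt(abs(f$estimates[["sd_int"]] - 0.5), 0.25)
})

test_that("with no zero inflation and no random effect the fit matches a
           plain negative binomial regression", {
  skip_if_not_installed("MASS")
  d <- simulate_zinb_dataset(150, 30, 0.3, 0.6, mean_int = 1, sd_int = 0,
                             zero_p = 0, theta = 3, seed = 32)
  f <- fit_zinb_mixed(d$counts, d$genotype)
  expect_true(f$converged)
  dat <- data.frame(y = as.numeric(d$counts),
                    x = rep(d$genotype, ncol(d$counts)))
  nb <- MASS::glm.nb(y ~ x, data = dat)
  se_joint <- sqrt(f$se_slope^2 + summary(nb)$coefficients["x", 2]^2)
  expect_lt(abs(f$estimates[["slope"]] - coef(nb)[["x"]]), 2 * se_joint)
  expect_lt(abs(f$estimates[["theta"]] - nb$theta), 2 * nb$SE.theta +
              0.2 * nb$theta)
})

test_that("the fitter agrees with an independent ZINB mixed-model
           implementation on one dataset", {
  skip_if_not_installed("glmmTMB")
  d <- simulate_zinb_dataset(60, 40, 0.3, 0.7, mean_int = 1, sd_int = 0.5,
                             zero_p = 0.15, theta = 2, seed = 34)
  f <- fit_zinb_mixed(d$counts, d$genotype)
  expect_true(f$converged)
  dat <- data.frame(y = as.numeric(d$counts),
                    x = rep(d$genotype, ncol(d$counts)),
                    subj = factor(rep(seq_len(60), ncol(d$counts))))
  g <- glmmTMB::glmmTMB(y ~ x + (1 | subj), ziformula = ~1,
                        family = glmmTMB::nbinom2, data = dat)
  cf <- summary(g)$coefficients$cond
  se_joint <- sqrt(f$se_slope^2 + cf["x", 2]^2)
  expect_lt(abs(f$estimates[["slope"]] - cf["x", 1]), 2 * se_joint)
  expect_equal(f$estimates[["theta"]], glmmTMB::sigma(g), tolerance = 0.1)
})

test_that("degenerate inputs are flagged rather than fitted", {
  z <- matrix(0L, 20, 10)
  f <- fit_zinb_mixed(z, rep(c(0, 1), 10))
  expect_false(f$converged)
  expect_true(f$degenerate)

  d <- simulate_zinb_dataset(20, 10, 0.3, 0, 1, 0.3, 0.1, 2, seed = 33)
  f2 <- fit_zinb_mixed(d$counts, rep(0L, 20)) # constant genotype
  expect_true(f2$degenerate)
})

test_that("simulation-based power is bit-identical across runs and worker
           counts", {
  args <- list(n = 25, m = 15, maf = 0.3, slope = 0.6, mean_int = 1,
               sd_int = 0.5, zero_p = 0.1, theta = 2, fwer = 0.05,
               n_tests = 1, n_sim = 30, seed = 17)
  r1 <- do.call(power_zinb_sim, args)
  r2 <- do.call(power_zinb_sim, args)
  r4 <- do.call(power_zinb_sim, c(args, list(workers = 2)))
  expect_identical(r1$details, r2$details)
  expect_identical(r1$details, r4$details)
  expect_identical(r1$power, r4$power)
})

test_that("the simulation report accounts exactly for its replicates", {
  r <- power_zinb_sim(25, 15, 0.3, 0.6, 1, 0.5, 0.1, 2, fwer = 0.05,
                      n_tests = 1, n_sim = 40, seed = 19)
  expect_equal(r$n_converged + r$n_failed, r$n_sim)
  expect_equal(r$power, r$n_rejected / r$n_converged)
  expect_equal(r$mc_se, sqrt(r$power * (1 - r$power) / r$n_converged))
  expect_identical(nrow(r$details), 40L)
  expect_true(all(r$details$rejected %in% c(0, 1)))
  # conservative mode divides by all replicates instead
  rc <- power_zinb_sim(25, 15, 0.3, 0.6, 1, 0.5, 0.1, 2, fwer = 0.05,
                       n_tests = 1, n_sim = 40, seed = 19,
                       conservative = TRUE)
  expect_equal(rc$power, rc$n_rejected / rc$n_sim)
})

test_that("power does not decrease when the slope doubles (paired seeds)", {
  lo <- power_zinb_sim(30, 15, 0.3, 0.3, 1, 0.5, 0.1, 2, fwer = 0.05,
                       n_tests = 1, n_sim = 60, seed = 23)
  hi <- power_zinb_sim(30, 15, 0.3, 0.6, 1, 0.5, 0.1, 2, fwer = 0.05,
                       n_tests = 1, n_sim = 60, seed = 23)
  expect_gte(hi$power, lo$power)
})
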