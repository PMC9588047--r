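# Circular mixture models: densities, likelihoods, maximum-likelihood fits,
# the swap variant, and the generative simulator.  Numeric expectations were
# frozen from an independent implementation of the von Mises density and the
# concentration / circular-s.d. mapping.

test_that("kappa and circular sd round-trip to high precision", {
  expect_equal(kappa_from_sd(20), 8.736066643465632, tolerance = 1e-9)
  for (s in c(2, 5, 15, 40, 100))
    expect_lt(abs(sd_from_kappa(kappa_from_sd(s)) - s), 1e-6)
})

test_that("the von Mises density normalizes and peaks at mu", {
  x <- seq(-179.5, 180, by = 0.5)
  d <- dvonmises_deg(x, 37, kappa_from_sd(25))
  expect_equal(sum(d) * 0.5, 1, tolerance = 1e-6)
  expect_equal(x[which.max(d)], 37)
})

test_that("standard log-likelihood matches frozen oracle values", {
  # all-uniform mixture: each error contributes log(1/360)
  expect_equal(loglik_standard(c(-20, 4, 133), 0, 20, 1),
               3 * log(1 / 360), tolerance = 1e-12)
  # single error at the mean with no guessing: the log-density itself
  expect_equal(loglik_standard(0, 0, 20, 0), -3.898684102773045,
               tolerance = 1e-8)
  # general case, frozen from the independent implementation
  expect_equal(loglik_standard(c(0, 10, -10, 25), 2, 20, 0.1),
               -16.911959332170916, tolerance = 1e-8)
  # likelihood prefers the generating parameters over a reflected bias
  set.seed(21)
  e <- simulate_errors(1000, mu = 5, sd = 20, p_m = 0.9)
  expect_gt(loglik_standard(e, 5, 20, 0.1), loglik_standard(e, -5, 20, 0.1))
  expect_error(loglik_standard(10, 0, -1, 0.1), "sd")
  expect_error(loglik_standard(10, 0, 10, 1.4), "p_uniform")
})

test_that("the standard fit is deterministic and recovers its generator", {
  set.seed(31)
  e <- simulate_errors(320, mu = 4, sd = 18, p_m = 0.9)
  f1 <- fit_standard_mixture(e)
  f2 <- fit_standard_mixture(e)
  expect_identical(f1, f2)
  expect_true(f1$converged)
  expect_lt(abs(f1$mu - 4), 3)
  expect_lt(abs(f1$sd - 18), 3)
  expect_lt(abs(f1$p_m - 0.9), 0.08)
  # uniform data pins the memory component near zero
  set.seed(32)
  u <- runif(320, -180, 180)
  expect_lt(fit_standard_mixture(u)$p_m, 0.1)
  expect_error(fit_standard_mixture(runif(10)), "20")
})

test_that("the swap model nests the standard model and recovers swaps", {
  set.seed(41)
  e <- simulate_errors(320, mu = 0, sd = 15, p_m = 0.85)
  off <- matrix(rep(c(170, -20), each = 320), ncol = 2)
  fixed <- fit_swap_mixture(e, off, fix_p_nontarget = 0)
  std <- fit_standard_mixture(e)
  expect_lt(abs(fixed$loglik - std$loglik), 1e-4)
  # extra parameter can only improve the likelihood
  free <- fit_swap_mixture(e, off)
  expect_gte(free$loglik, std$loglik - 1e-6)
  expect_lt(free$p_nontarget, 0.05)   # no swaps in the generator
  # 15% of responses centered on a non-target at +170
  set.seed(42)
  es <- simulate_errors(320, mu = 0, sd = 15, p_m = 0.8, p_nontarget = 0.15,
                        offsets = 170)
  fs <- fit_swap_mixture(es, matrix(170, 320, 1))
  expect_lt(abs(fs$p_nontarget - 0.15), 0.08)
  expect_error(fit_swap_mixture(es, NULL), "offsets")
})

test_that("the generative simulator has the stated limiting behavior", {
  set.seed(51)
  # degenerate target component: every error collapses onto mu
  e0 <- simulate_errors(200, mu = 12, sd = 0.5, p_m = 1)
  expect_lt(max(abs(e0 - 12)), 3)
  # pure guessing is uniform: Rayleigh test does not reject at alpha = 0.01
  eu <- simulate_errors(10000, mu = 0, sd = 20, p_m = 0)
  r <- sqrt(mean(cos(eu * pi / 180))^2 + mean(sin(eu * pi / 180))^2)
  z <- length(eu) * r^2          # Rayleigh statistic, approx chi^2 / 2
  expect_lt(z, 4.6)              # 0.01 critical value
  # empirical circular s.d. of the target component approaches the generator
  et <- simulate_errors(1e5, mu = 0, sd = 20, p_m = 1)
  rbar <- sqrt(mean(cos(et * pi / 180))^2 + mean(sin(et * pi / 180))^2)
  expect_lt(abs(sqrt(-2 * log(rbar)) * 180 / pi - 20), 0.5)
})
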