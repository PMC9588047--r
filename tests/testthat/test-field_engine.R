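# Generic field-engine operations: sigmoid, kernels, convolution, Euler
# integration, peak detection, and scalar nodes.

test_that("sigmoid matches the closed form and saturates correctly", {
  expect_equal(df_sigmoid(0), 0.5)
  expect_equal(df_sigmoid(1, beta = 4), 1 / (1 + exp(-4)), tolerance = 1e-12)
  expect_equal(df_sigmoid(1, beta = 4), 0.98201379, tolerance = 1e-7)
  expect_equal(df_sigmoid(1e3), 1)
  expect_equal(df_sigmoid(-1e3), 0)
  expect_equal(df_sigmoid(2, beta = 3, theta = 2), 0.5)
  expect_error(df_sigmoid(c(0, NaN)), "non-finite")
})

test_that("kernel validation enforces surround structure", {
  expect_error(interaction_kernel(c_exc = 1, sigma_exc = 10, c_inh = 1,
                                  sigma_inh = 5), "surround")
  expect_error(interaction_kernel(g_inh = -1))
  k <- interaction_kernel(c_exc = 2, sigma_exc = 3, c_inh = 1, sigma_inh = 8)
  expect_s3_class(k, "interaction_kernel")
})

test_that("lateral input equals the brute-force convolution oracle", {
  set.seed(42)
  for (n in c(60, 120)) {
    k <- interaction_kernel(c_exc = 1.5, sigma_exc = 5, c_inh = 0.8,
                            sigma_inh = 12, g_inh = 0.05)
    f <- df_field("x", n_sites = n, kernel = k,
                  u = rnorm(n, mean = -2, sd = 3))
    got <- lateral_input(f)
    # O(n^2) direct evaluation of the convolution integral
    g <- df_sigmoid(f$u)
    dx <- 360 / n
    kv <- dfwm:::kernel_profile(k, n)
    brute <- vapply(seq_len(n), function(i) {
      sum(kv[((i - seq_len(n)) %% n) + 1] * g) * dx
    }, numeric(1)) - k$g_inh * sum(g) * dx
    expect_lt(max(abs(got - brute)), 1e-8)
  }
})

test_that("a unit output impulse reproduces the kernel profile", {
  n <- 90
  k <- interaction_kernel(c_exc = 2, sigma_exc = 6)
  # large activation at site 10 saturates the sigmoid to ~1; everything else
  # is pushed to output ~0
  u <- rep(-60, n); u[10] <- 60
  f <- df_field("x", n_sites = n, kernel = k, u = u, beta = 4)
  got <- lateral_input(f)
  kv <- dfwm:::kernel_profile(k, n) * 360 / n
  expected <- kv[((seq_len(n) - 10) %% n) + 1]
  expect_lt(max(abs(got - expected)), 1e-6)
})

test_that("noise-free relaxation follows the exponential closed form", {
  f <- df_field("x", n_sites = 30, h = -5, tau = 20, u = rep(3, 30))
  expect_error(euler_step(f, dt = 25), "dt < tau")
  # fixed point: u = h with no input
  g <- df_field("x", n_sites = 10, h = -5)
  expect_equal(run_field(g, 0, duration = 100, dt = 1)$u, rep(-5, 10))
  # constant input: u -> h + s, |error| < 1% of |s| after 5 tau
  s <- 4
  f2 <- run_field(df_field("x", n_sites = 10, h = -5, tau = 20), s,
                  duration = 100, dt = 0.5)
  expect_lt(max(abs(f2$u - (-5 + s))), 0.01 * s)
  # trajectory matches exp(-t / tau) relaxation at finite t
  f3 <- run_field(df_field("x", n_sites = 5, h = -5, tau = 20), s,
                  duration = 20, dt = 0.01)
  expect_equal(f3$u[1], -5 + s * (1 - exp(-1)), tolerance = 1e-3)
})

test_that("peak detection finds and refines circular local maxima", {
  f <- df_field("x", n_sites = 120, u = rep(-5, 120))
  expect_equal(nrow(detect_peaks(f, 0)), 0)
  x <- field_sites(f)
  f$u <- 5 * exp(-dfwm:::wrap180(x - 90)^2 / 50) - 3
  pk <- detect_peaks(f, 0)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$location - 90), 3)
  # two bumps: found in descending activation order, near the argmax scan
  f$u <- 6 * exp(-dfwm:::wrap180(x - 280)^2 / 50) +
    4 * exp(-dfwm:::wrap180(x - 80)^2 / 50) - 3
  pk <- detect_peaks(f, 0)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$location[1] - 280), 3)
  expect_lt(abs(pk$location[2] - 80), 3)
})

test_that("grid refinement leaves a noise-free peak position stable", {
  peak_pos <- function(n, dt) {
    k <- interaction_kernel(c_exc = 1.8, sigma_exc = 3, c_inh = 0,
                            sigma_inh = 10, g_inh = 0.02)
    f <- df_field("x", n_sites = n, h = -3.8, tau = 20, kernel = k)
    x <- field_sites(f)
    inp <- 8 * exp(-dfwm:::wrap180(x - 123.4)^2 / (2 * 25))
    f <- run_field(f, inp, duration = 300, dt = dt)
    f <- run_field(f, 0, duration = 300, dt = dt)
    detect_peaks(f, 0)$location[1]
  }
  base <- peak_pos(120, 2)
  expect_lt(abs(dfwm:::wrap180(base - peak_pos(120, 1))), 0.5)
  expect_lt(abs(dfwm:::wrap180(base - peak_pos(240, 2))), 0.5)
})

test_that("self-sustaining and input-driven kernel regimes both exist", {
  run_regime <- function(c_exc, h) {
    k <- interaction_kernel(c_exc = c_exc, sigma_exc = 3, g_inh = 0.02)
    f <- df_field("x", n_sites = 120, h = h, tau = 20, kernel = k)
    x <- field_sites(f)
    inp <- 8 * exp(-dfwm:::wrap180(x - 90)^2 / (2 * 25))
    f <- run_field(f, inp, duration = 400, dt = 2)
    stopifnot(max(f$u) > 0)          # peak formed under input
    f <- run_field(f, 0, duration = 1000, dt = 2)
    max(f$u)
  }
  # working-memory-like interactions sustain the peak for a second
  expect_gt(run_regime(13, -3.8), 0)
  # sensory-like weak interactions let it decay back to rest
  expect_lt(run_regime(0.25, -5), 0)
})

test_that("scalar nodes integrate, latch and release", {
  n0 <- df_node("pd", h = -3, tau = 15, self_exc = 0)
  expect_equal(node_step(n0, 0)$u, n0$u, tolerance = 1e-12)  # rest is a fixed point
  n <- df_node("pd", h = -3, tau = 15, self_exc = 1)
  # strong constant drive crosses the output midpoint within 10 tau
  for (i in seq_len(75)) n <- node_step(n, 6)
  expect_gt(node_output(n), 0.5)
  # drive removed with sub-sustaining self-excitation: output decays
  for (i in seq_len(75)) n <- node_step(n, 0)
  expect_lt(node_output(n), 0.1)
})

test_that("integration is reproducible: bit-identical with q = 0, seeded with q > 0", {
  k <- interaction_kernel(c_exc = 3, sigma_exc = 5)
  mk <- function(q) df_field("x", n_sites = 60, q = q, kernel = k)
  a <- run_field(mk(0), 2, duration = 100)
  b <- run_field(mk(0), 2, duration = 100)
  expect_identical(a$u, b$u)
  set.seed(7); c1 <- run_field(mk(0.2), 2, duration = 100)
  set.seed(7); c2 <- run_field(mk(0.2), 2, duration = 100)
  expect_identical(c1$u, c2$u)
  expect_false(identical(a$u, c1$u))
})
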