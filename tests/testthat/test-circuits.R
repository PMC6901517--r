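test_that("noise-free cubic circuit sits at its fixed points", {
  p <- cubic_params(T = 0)
  tr <- simulate_cubic(p, sim_config(dt = 0.01, duration = 20, seed = 1))
  expect_true(all(tr$a == 0) && all(tr$y == 0))
  # unit step: plateau solves the coupled fixed point
  # a(1+eps) + eps c3 a^3 = eps alpha2 -> a ~ 0.09084 for the defaults
  tr2 <- simulate_cubic(p, sim_config(dt = 0.005, duration = 80, seed = 1),
                        signal = list(kind = "step", size = 1))
  a_inf <- utils::tail(tr2$a[, 1], 1)
  root <- uniroot(function(a) a * 1.1 + 0.1 * a^3 - 0.1, c(0, 1),
                  tol = 1e-12)$root
  expect_equal(a_inf, root, tolerance = 1e-3)
})

test_that("stationary activity averages to zero under noise", {
  p <- unit_cubic(T = 0.01)
  tr <- simulate_cubic(p, sim_config(dt = 0.02, duration = 4000, seed = 2))
  a <- tr$a[tr$time > 100, 1]
  # 3 SE with an autocorrelation-aware effective sample size (tau ~ 1)
  se <- stats::sd(a) / sqrt(length(a) * 0.02 / (2 * 1))
  expect_lt(abs(mean(a)), 3 * se)
})

test_that("simulations are bit-reproducible under a fixed seed", {
  p <- unit_cubic(T = 0.05)
  s <- sim_config(dt = 0.01, duration = 10, seed = 99)
  tr1 <- simulate_cubic(p, s)
  tr2 <- simulate_cubic(p, s)
  expect_identical(tr1$a, tr2$a)
  f <- fhn_params()
  tf1 <- simulate_fhn(f, s); tf2 <- simulate_fhn(f, s)
  expect_identical(tf1$a, tf2$a)
})

test_that("dt bound is enforced", {
  expect_error(simulate_cubic(cubic_params(), sim_config(dt = 0.1, duration = 1)),
               class = "dqs_config_error")
})

test_that("FHN resting state matches the cubic-root oracle", {
  f <- fhn_params(T = 0)  # Methods set: eps = 0.1, a0 = 1.5
  rs <- fhn_resting_state(f)
  # oracle frozen from uniroot on eps(a - a^3/3) = a + a0
  expect_equal(unname(rs["a"]), -1.5331854143, tolerance = 1e-8)
  tr <- simulate_fhn(f, sim_config(dt = 0.01, duration = 100, seed = 1),
                     init = c(-1, 0))
  expect_equal(utils::tail(tr$a[, 1], 1), unname(rs["a"]), tolerance = 1e-4)
  # small eps: resting activity approaches -a0
  rs2 <- fhn_resting_state(fhn_params(epsilon = 0.01))
  expect_equal(unname(rs2["a"]), -1.5, tolerance = 0.01)
})

test_that("noisy FHN fires excursions while the mean stays near rest", {
  f <- fhn_params(T = 0.1)
  tr <- simulate_fhn(f, sim_config(dt = 0.02, duration = 2000, seed = 7))
  a <- tr$a[tr$time > 50, 1]
  a_rs <- fhn_resting_state(f)["a"]
  expect_gt(max(a), 1)               # large excursions happen
  expect_lt(abs(median(a) - a_rs), 0.4)  # but rest dominates
})

test_that("ensemble step response matches the noise-free solution", {
  p <- unit_cubic(T = 0.005)
  s <- sim_config(dt = 0.02, duration = 40, seed = 11, n_realizations = 40,
                  transient = 5)
  st <- estimate_step_response("cubic", p, s, step_size = 0.5)
  p0 <- unit_cubic(T = 0)
  tr0 <- simulate_cubic(p0, sim_config(dt = 0.02, duration = 35, seed = 1),
                        signal = list(kind = "step", size = 0.5))
  i <- seq(5, length(st$time), by = 20)
  expect_true(all(abs(st$activity[i] - tr0$a[i, 1]) <
                    3 * st$stderr[i] + 1e-3))
  # zero step size: paired common random numbers cancel exactly
  s0 <- sim_config(dt = 0.02, duration = 10, seed = 11, n_realizations = 3)
  z <- estimate_step_response("cubic", p, s0, step_size = 0)
  expect_true(all(z$activity == 0))
})

test_that("measured sine response matches the analytic spectrum within 5%", {
  p <- unit_cubic(T = 0)
  ws <- as.numeric(omega_star(p))
  om <- ws * c(0.1, 0.3, 0.6, 1, 1.8, 3)
  ms <- estimate_sine_response("cubic", p, sim_config(dt = 0.01, seed = 5,
                                                      n_realizations = 1),
                               omega = om, amplitude = 0.02)
  an <- cubic_response(p, om)
  expect_lt(max(Mod(ms$value - an$value) / Mod(an$value)), 0.05)
  # phase crosses zero at omega*
  expect_lt(abs(spectrum_phase(ms)[4]), 0.03)
})

test_that("linearity check flags a large-amplitude stimulus", {
  p <- unit_cubic(T = 0)
  expect_warning(
    estimate_sine_response("cubic", p, sim_config(dt = 0.01, seed = 5,
                                                  n_realizations = 1),
                           omega = 1, amplitude = 3, check_linearity = TRUE),
    "linearity")
})

test_that("correlation spectrum of an OU process matches the Lorentzian", {
  # signal-only population: gamma sdot = -K s + xi
  m <- signal_model(gamma = 1, K = 1, alpha1 = 0, T_s = 0.02)
  cfg <- population_config("cubic", cubic_params(alpha2 = 0, T = 0), m, N = 1,
                           sim_config(dt = 0.02, duration = 5000, seed = 13))
  tr <- simulate_population(cfg)
  cs <- correlation_spectrum(tr, "s", from = 50)
  lor <- 2 * m$T_s * m$gamma / (m$K^2 + m$gamma^2 * cs$omega^2)
  i <- cs$omega < 5
  # band-averaged agreement within 3 SE of the segment average
  rel <- mean(cs$value[i] / lor[i])
  expect_lt(abs(rel - 1), 3 / sqrt(cs$n_segments * sum(i)) + 0.05)
  # noise-free stationary state has zero spectrum
  tr0 <- simulate_cubic(cubic_params(T = 0), sim_config(dt = 0.02, duration = 200, seed = 1))
  cs0 <- correlation_spectrum(tr0, "a", from = 10)
  expect_true(all(cs0$value < 1e-20))
})

test_that("halving dt leaves endpoint statistics within tolerance", {
  p <- unit_cubic(T = 0.02)
  v <- vapply(c(0.02, 0.01), function(dt) {
    tr <- simulate_cubic(p, sim_config(dt = dt, duration = 3000, seed = 17))
    stats::var(tr$a[tr$time > 50, 1])
  }, numeric(1))
  expect_lt(abs(v[1] - v[2]) / v[2], 0.1)
})
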