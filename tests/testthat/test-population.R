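test_that("detector classifies constructed series correctly", {
  dt <- 0.05
  t <- seq(0, 500, by = dt)
  set.seed(2)
  pure <- 0.8 * cos(0.7 * t)
  d1 <- detect_oscillation(pure + rnorm(length(t), 0, 0.01), dt)
  expect_identical(d1$classification, "oscillatory")
  expect_rel(d1$amplitude, 0.8, 0.05)
  expect_rel(d1$frequency, 0.7, 0.05)
  d2 <- detect_oscillation(rnorm(length(t)), dt)
  expect_identical(d2$classification, "quiescent")
})

test_that("population with decoupled feedback reduces to the single circuit", {
  p <- unit_cubic(T = 0.05)
  p0 <- p; p0$alpha2 <- 0  # cell blind to s: coupled run must match exactly
  s <- sim_config(dt = 0.02, duration = 20, seed = 31)
  cfg <- population_config("cubic", p0, signal_model(alpha1 = 0), N = 1, s)
  tr_pop <- simulate_population(cfg, n_keep = 1L)
  tr_one <- simulate_cubic(p0, s)
  expect_identical(tr_pop$a, tr_one$a)
  expect_identical(tr_pop$y, tr_one$y)
})

test_that("classification is stable across seeds near threshold", {
  cfg <- population_config("cubic", fig_cubic(), fig_signal(), N = 16,
                           sim_config(dt = 0.02, duration = 900, seed = 1,
                                      transient = 300))
  for (nb in c(1.2, 2.2)) {
    cls <- vapply(c(5, 11, 23), function(sd) {
      cfg$sim$seed <- sd
      tr <- simulate_population(with_nbar(cfg, nb), n_keep = 1L)
      detect_oscillation(tr$s[tr$time >= 300], 0.02)$classification
    }, character(1))
    expect_length(unique(cls), 1)
    expect_identical(unique(cls),
                     if (nb > 1.76) "oscillatory" else "quiescent")
  }
})

test_that("results depend on (N, alpha1) only through Nbar in the linear regime", {
  base <- population_config("cubic", fig_cubic(), fig_signal(), N = 8,
                            sim_config(dt = 0.02, duration = 900, seed = 3,
                                       transient = 300))
  freqs <- vapply(c(8L, 24L), function(N) {
    cfg <- population_config("cubic", base$circuit, base$signal, N, base$sim)
    tr <- simulate_population(with_nbar(cfg, 2.2), n_keep = 1L)
    d <- detect_oscillation(tr$s[tr$time >= 300], 0.02)
    expect_identical(d$classification, "oscillatory")
    d$frequency
  }, numeric(1))
  expect_rel(freqs[1], freqs[2], 0.05)
})

test_that("hopf exponent fit is exact on constructed power laws", {
  nb <- seq(1.8, 2.3, by = 0.025)
  for (beta in c(0.5, 1)) {
    A <- 0.8 * pmax(nb - 1.76, 0)^beta
    sw <- data.frame(Nbar = nb, amplitude = A)
    f <- fit_hopf_exponent(sw, Nbar_o = 1.76, refine = 0)
    expect_equal(f$beta, beta, tolerance = 1e-8)
  }
  # refinement recovers a slightly misspecified bifurcation point
  A <- 0.8 * pmax(nb - 1.80, 0)^0.5
  f2 <- fit_hopf_exponent(data.frame(Nbar = nb, amplitude = A),
                          Nbar_o = 1.76, refine = 0.05)
  expect_equal(f2$beta, 0.5, tolerance = 0.05)
  expect_equal(f2$Nbar_o, 1.80, tolerance = 0.01)
  expect_error(fit_hopf_exponent(data.frame(Nbar = 1:3, amplitude = 1:3),
                                 Nbar_o = 0.9), class = "dqs_config_error")
})

test_that("sweep brackets the onset and death follows 1/epsilon", {
  cfg <- population_config("cubic", fig_cubic(), fig_signal(), N = 16,
                           sim_config(dt = 0.02, duration = 900, seed = 7,
                                      transient = 300))
  sw <- density_sweep(cfg, c(1.2, 1.6, 2.0, 2.4))
  on <- attr(sw, "onset")
  expect_true(on$bracketed)
  expect_gt(on$Nbar_o, 1.4)
  expect_lt(on$Nbar_o, 2.3)
  # all-quiescent grid flags no bracket
  sw0 <- density_sweep(cfg, c(0.4, 0.8))
  expect_false(attr(sw0, "onset")$bracketed)
})

test_that("oscillation death shows the infinite-period signature", {
  cfg <- population_config("cubic",
                           cubic_params(epsilon = 0.2, alpha2 = 0.5, T = 0.01),
                           fig_signal(), N = 8,
                           sim_config(dt = 0.02, duration = 900, seed = 21,
                                      transient = 300))
  r <- find_upper_bifurcation(cfg, c(3, 25), iter = 6)
  expect_true(r$found)
  expect_gt(r$period_095, r$period_07)  # period grows approaching death
  # a range that ends before death reports not-found
  r2 <- find_upper_bifurcation(cfg, c(3, 4), iter = 2)
  expect_false(r2$found)
})
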