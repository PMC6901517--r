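complex_interpolant <- dqskit:::complex_interpolant

test_that("energy flux vanishes at zero phase and at omega*", {
  p <- unit_cubic()
  ws <- as.numeric(omega_star(p))
  sp <- cubic_spectrum(p)
  # real positive response -> no energy flow
  flat <- response_spectrum(c(1, 2), c(2 + 0i, 3 + 0i))
  expect_equal(energy_flux(flat, 1), c(0, 0))
  # at omega* the imaginary part is zero by construction
  expect_lt(abs(energy_flux(sp, signal_power = 1, omega = ws)), 1e-6)
})

test_that("flux is positive in the phase-leading band, sign = sign(phase)", {
  p <- unit_cubic()
  ws <- as.numeric(omega_star(p))
  sp <- cubic_spectrum(p)
  w_lead <- seq(0.1, 0.9, by = 0.1) * ws
  w_lag <- seq(1.1, 3, by = 0.3) * ws
  expect_true(all(energy_flux(sp, 0.7, omega = w_lead) > 0))
  expect_true(all(energy_flux(sp, 0.7, omega = w_lag) < 0))
  # sign identity across random spectra and frequencies
  set.seed(3)
  for (k in 1:10) {
    pk <- cubic_params(tau_a = exp(rnorm(1, 0, 0.3)),
                       tau_y = exp(rnorm(1, 0.5, 0.3)),
                       epsilon = runif(1, 0.02, 0.3))
    spk <- cubic_spectrum(pk, n = 800, wmax = 8)
    w <- runif(8, 0.05, 5)
    f <- complex_interpolant(spk$omega, spk$value)
    phase <- -Arg(f(w))
    expect_equal(sign(energy_flux(spk, 1, omega = w)), sign(phase))
  }
})

test_that("FDT holds for the simulated passive signal", {
  # pure Ornstein-Uhlenbeck medium: a population whose single cell cannot
  # feel or force the signal (alpha1 = alpha2 = 0, T = 0), signal noise on
  cfg <- population_config(
    "cubic", cubic_params(alpha2 = 0, T = 0),
    signal_model(gamma = 1, K = 1, alpha1 = 0, T_s = 0.05), N = 1,
    sim_config(dt = 0.02, duration = 6000, seed = 4, transient = 100))
  tr <- simulate_population(cfg)
  cs <- correlation_spectrum(tr, "s", from = 100)
  m <- cfg$signal
  resp <- signal_response(m, cs$omega)
  ratio <- fdt_ratio(resp, cs, T = m$T_s)
  # band-average in three octaves; periodogram SE ~ value/sqrt(nseg * nbin)
  for (band in list(c(0.1, 0.4), c(0.4, 1.6), c(1.6, 6))) {
    i <- cs$omega > band[1] & cs$omega <= band[2]
    se <- 1 / sqrt(cs$n_segments * sum(i))
    expect_lt(abs(mean(ratio[i]) - 1), 3 * se + 0.05)  # +EM discretisation bias
  }
})

test_that("FDT is violated in the active band of the adaptive circuit", {
  p <- unit_cubic(T = 0.01)
  tr <- simulate_cubic(p, sim_config(dt = 0.02, duration = 6000, seed = 8,
                                     transient = 100))
  ca <- correlation_spectrum(tr, "a", from = 100)
  resp <- cubic_response(p, ca$omega)
  ratio <- fdt_ratio(resp, ca, T = p$T)
  ws <- as.numeric(omega_star(p))
  low <- ca$omega < 0.7 * ws & ca$omega > 0.1 * ws
  high <- ca$omega > 6 & ca$omega < 15
  # phase-leading band: R'' < 0 while C_a > 0 -> negative ratio
  expect_lt(mean(ratio[low]), 0)
  # equilibrium branch: the ratio (1 + x)/(1 - x) with
  # x = tau_y/(eps^2 + omega^2 tau_y^2) approaches 1 only at high omega
  expect_lt(abs(mean(ratio[high]) - 1), 0.1)
})
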