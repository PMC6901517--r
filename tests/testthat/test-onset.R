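test_that("phase matching recovers omega* in the fast-clearance limit", {
  p <- fig_cubic()
  sp <- cubic_spectrum(p)
  roots <- phase_matching(sp, signal_model(gamma = 1e-7, K = 1, alpha1 = 0.5))
  expect_length(roots, 1)
  expect_rel(roots, as.numeric(omega_star(p)), 1e-3)
})

test_that("onset for the coupled-circuit parameters matches the dense-scan oracle", {
  # frozen oracle: 1e5-point scan + bisection of arg D(w) = atan(w tau_s)
  # for tau_a = tau_y = gamma = K = 1, eps = 0.1 gives
  # omega_o = 0.6633249581 and Nbar_o = |D||K - i gamma w| = 1.7600
  p <- fig_cubic()
  o <- onset_point(cubic_spectrum(p), fig_signal(), alpha2 = p$alpha2)
  expect_identical(o$status, "ok")
  expect_rel(o$omega_o, 0.6633249581, 1e-5)
  expect_rel(o$Nbar_o, 1.76, 1e-5)
  expect_lt(o$omega_o, as.numeric(omega_star(p)))
  expect_lt(o$diagnostics$residual, 1e-6)
})

test_that("passive spectra yield a distinguishable no-onset result", {
  w <- seq(0.01, 10, length.out = 400)
  passive <- response_spectrum(w, 1 / (1 - 1i * w))
  o <- onset_point(passive, signal_model())
  expect_identical(o$status, "no-active-band")
  expect_identical(o$root_multiplicity, 0L)
})

test_that("onset density obeys the gain condition and its scalings", {
  p <- fig_cubic()
  sp <- cubic_spectrum(p)
  # |R_a R_s| = 1, alpha1 = 1 -> N_o = 1 (constructed point)
  flatw <- c(0.5, 1, 1.5)
  flat <- response_spectrum(flatw, rep(2 + 0i, 3))
  d <- onset_density(flat, signal_model(gamma = 1, K = 2, alpha1 = 1),
                     omega_o = 1e-9 + 1)  # |R_s(1)| = 1/|2-i| -> gain 2/sqrt5
  expect_equal(d$N_o, sqrt(5) / 2, tolerance = 1e-6)
  # doubling alpha1 halves N_o, Nbar_o unchanged
  s1 <- signal_model(gamma = 1, K = 1, alpha1 = 0.5)
  s2 <- signal_model(gamma = 1, K = 1, alpha1 = 1)
  o1 <- onset_point(sp, s1, alpha2 = p$alpha2)
  o2 <- onset_point(sp, s2, alpha2 = p$alpha2)
  expect_equal(o2$N_o, o1$N_o / 2, tolerance = 1e-9)
  expect_equal(o2$Nbar_o, o1$Nbar_o, tolerance = 1e-9)
})

test_that("onset frequency decreases with signal relaxation time", {
  p <- fig_cubic()
  sp <- cubic_spectrum(p)
  taus <- c(0.01, 0.1, 0.3, 1, 3)
  oo <- vapply(taus, function(ts)
    onset_point(sp, signal_model(gamma = ts, K = 1, alpha1 = 0.5),
                alpha2 = p$alpha2)$omega_o, numeric(1))
  expect_true(all(diff(oo) < 0))
  expect_rel(oo[1], as.numeric(omega_star(p)), 0.02)
})

test_that("onset_from_step composes the full pipeline", {
  st <- generate_step_fixture("adaptive_step", epsilon = 0.1, omega_star = 1,
                              dt = 0.05, duration = 60)
  o <- onset_from_step(st, signal_model(gamma = 1e-4, K = 1, alpha1 = 1))
  expect_identical(o$status, "ok")
  expect_rel(o$period, 2 * pi, 0.02)
  # slower clearance lengthens the period
  o2 <- onset_from_step(st, signal_model(gamma = 0.35, K = 1, alpha1 = 1))
  expect_gt(o2$period, o$period)
  # non-adaptive step: no onset
  st2 <- generate_step_fixture("nonadaptive_step", dt = 0.05, duration = 60)
  o3 <- suppressWarnings(
    onset_from_step(st2, signal_model(gamma = 1e-4, K = 1, alpha1 = 1)))
  expect_false(o3$status == "ok")
})

test_that("renormalised response reduces to linear at A = 0 and shifts down", {
  p <- fig_cubic()
  w <- seq(0.05, 3, length.out = 600)
  r0 <- renormalised_response(p, 0, w)
  expect_equal(r0$spectrum$value, cubic_response(p, w)$value, tolerance = 1e-12)
  curve <- renormalised_onset_curve(p, fig_signal(), A = c(0, 0.4, 0.8, 1.2))
  expect_true(all(diff(curve$omega) < 0))  # frequency shifts down with A
  expect_true(all(diff(curve$Nbar) > 0))   # at increasing coupling
})

test_that("maximum signal relaxation time scales as 1/epsilon", {
  expect_identical(max_signal_time(cubic_params(epsilon = 0)), Inf)
  ts <- vapply(c(0.05, 0.1, 0.2), function(e)
    max_signal_time(cubic_params(epsilon = e)), numeric(1))
  expect_rel(ts[1] / ts[2], 2, 0.25)
  expect_rel(ts[2] / ts[3], 2, 0.25)
  # bracket property: root exists just below tau_s*, none just above
  p <- cubic_params(epsilon = 0.1)
  sp <- cubic_response(p, exp(seq(log(1e-4), log(4), length.out = 1500)))
  expect_gt(length(phase_matching(sp, signal_model(gamma = 0.95 * ts[2], K = 1))), 0)
  expect_identical(length(phase_matching(sp, signal_model(gamma = 1.05 * ts[2], K = 1))), 0L)
})
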