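# The reduced glycolysis circuit is deterministic; its tests probe the
# qualitative phase structure the defaults were calibrated for once:
# a single oscillatory window in clamped intracellular ACE with adaptive
# response on both wings, and the density/permeability behaviour of the
# coupled suspension (dynamical quorum sensing and its inverse).

test_that("conserved pools stay constant along trajectories", {
  p <- glyco_params()
  s <- simulate_cell_clamped(p, 0.6, duration = 300)
  aden <- s$state[, "ATP"] + s$state[, "ADP"]
  pyr <- s$state[, "NAD"] + s$state[, "NADH"]
  expect_lt(max(abs(aden - p$atot)) / p$atot, 1e-6)
  expect_lt(max(abs(pyr - p$ntot)) / p$ntot, 1e-6)
  tr <- simulate_suspension(suspension_params(rho = 0.3), duration = 200)
  aden2 <- tr$cells[, 1] + tr$cells[, 2]
  expect_lt(max(abs(aden2 - p$atot)) / p$atot, 1e-6)
})

test_that("clamped ACE scan shows a single interior oscillatory window", {
  p <- glyco_params()
  aces <- c(0.15, 0.3, 0.55, 0.7, 0.9, 1.3, 2.5)
  att <- vapply(aces, function(a)
    simulate_cell_clamped(p, a)$attractor, character(1))
  expect_identical(att, c("fixed_point", "fixed_point", "limit_cycle",
                          "limit_cycle", "limit_cycle", "fixed_point",
                          "fixed_point"))
})

test_that("both wings of the window respond adaptively", {
  p <- glyco_params()
  lower <- classify_regime(p, 0.49)
  upper <- classify_regime(p, 1.05)
  expect_identical(lower$regime, "adaptive")
  expect_identical(upper$regime, "adaptive")
  expect_lt(abs(upper$adaptation_error), abs(lower$adaptation_error) + 0.5)
  # far below the window redox starvation disengages the feedback
  far <- classify_regime(p, 0.2)
  expect_identical(far$regime, "non-adaptive")
  inside <- classify_regime(p, 0.7)
  expect_identical(inside$regime, "oscillatory")
})

test_that("membrane permeability controls the ACE gradient", {
  # very large D equilibrates the two compartments
  fast <- simulate_suspension(suspension_params(D = 50, rho = 0.5),
                              duration = 400)
  n <- length(fast$time); ti <- seq(floor(0.8 * n), n)
  expect_lt(abs(mean(fast$ace_in_mean[ti]) - mean(fast$ace_ex[ti])) /
              mean(fast$ace_in_mean[ti]), 0.05)
  # decreasing D at fixed rho raises the intracellular level
  lv <- vapply(c(3, 0.4, 0.1), function(D) {
    tr <- simulate_suspension(suspension_params(D = D, rho = 0.3),
                              duration = 400)
    mean(tr$ace_in_mean[seq(floor(0.8 * n), n)])
  }, numeric(1))
  expect_true(all(diff(lv) > 0))
  # D = 0 decouples the cells from the medium entirely
  dec <- simulate_suspension(suspension_params(D = 0, rho = 0.5),
                             duration = 200, ace_ex0 = 0.7)
  expect_lt(utils::tail(dec$ace_ex, 1), 0.01)  # pure decay, no secretion
})

test_that("suspension phase behaviour across permeabilities", {
  rho <- c(0.1, 0.35, 0.6, 0.85)
  # D = 3: smooth crossover, oscillations at all densities
  s3 <- suspension_density_sweep(suspension_params(D = 3), rho)
  expect_true(all(s3$classification == "oscillatory"))
  # D = 0.4: band with an upper quenching density (inverse DQS)
  s04 <- suspension_density_sweep(suspension_params(D = 0.4), rho)
  expect_identical(s04$classification[1], "oscillatory")
  expect_identical(utils::tail(s04$classification, 1), "quiescent")
  expect_true(is.finite(attr(s04, "quench")))
  # D = 0.1: no oscillation at any density
  s01 <- suspension_density_sweep(suspension_params(D = 0.1), rho)
  expect_true(all(s01$classification == "quiescent"))
  # amplitude decreases towards the quench while ACE_in rises
  expect_true(all(diff(s3$ace_in) > 0))
})

test_that("inverse-DQS quench is predicted from measured response spectra", {
  sp <- suspension_params(D = 0.4)
  sw <- suspension_density_sweep(sp, seq(0.7, 0.9, by = 0.05))
  quench <- attr(sw, "quench")
  expect_true(is.finite(quench))
  pred <- suspension_predict_quench(sp, rho_probe = c(0.90, 0.95),
                                    omega = seq(3.9, 4.6, by = 0.05))
  expect_true(all(pred$gains < 1))       # quiescent side is subcritical
  expect_lt(abs(pred$rho_c2 - quench) / quench, 0.15)
})
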