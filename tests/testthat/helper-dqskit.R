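# Shared parameter sets and small utilities for the suite.

# coupled-simulation parameters of the weakly nonlinear adaptive circuit
# (tau_a = tau_y = gamma = K = c3 = 1, alpha1 = alpha2 = 0.5, eps = 0.1,
# T = 0.01)
fig_cubic <- function(T = 0.01) {
  cubic_params(tau_a = 1, tau_y = 1, epsilon = 0.1, c3 = 1, alpha2 = 0.5,
               T = T)
}
fig_signal <- function() signal_model(gamma = 1, K = 1, alpha1 = 0.5)

# single-cell response variant (alpha2 = 1, for FDT comparisons)
unit_cubic <- function(T = 0.01) {
  cubic_params(tau_a = 1, tau_y = 1, epsilon = 0.1, c3 = 1, alpha2 = 1,
               T = T)
}

# dense-grid spectrum of the cubic circuit covering its active band
cubic_spectrum <- function(params, n = 3000, wmax = 6) {
  cubic_response(params, seq(0.004, wmax, length.out = n))
}

expect_rel <- function(object, expected, tol, info = NULL) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
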