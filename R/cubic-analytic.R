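#' Parameters of the adaptive two-node circuit with cubic nonlinearity
#'
#' The circuit couples an activity \eqn{a} to a negative-feedback memory
#' node \eqn{y}:
#' \deqn{\tau_a \dot a = -a - c_3 a^3 + y + \alpha_2 s + \eta_a, \qquad
#'       \tau_y \dot y = -a - \epsilon y + \eta_y,}
#' with Gaussian white noise of strengths
#' \eqn{\langle\eta_x\eta_x\rangle = 2 T \tau_x \delta}.  \eqn{\epsilon}
#' sets the adaptation error (residual step response at long times is
#' \eqn{\alpha_2\epsilon/(1+\epsilon)} per unit step), \eqn{c_3} limits the
#' activity at large amplitude, \eqn{\alpha_2} is the signal sensitivity.
#'
#' @param tau_a,tau_y relaxation times (> 0).
#' @param epsilon adaptation error parameter (>= 0).
#' @param c3 cubic coefficient (>= 0).
#' @param alpha2 signal sensitivity.
#' @param T noise strength (>= 0).
#' @return object of class `dqs_cubic`.
#' @export
cubic_params <- function(tau_a = 1, tau_y = 1, epsilon = 0.1, c3 = 1,
                         alpha2 = 1, T = 0.01) {
  if (tau_a <= 0 || tau_y <= 0) stop_config("tau_a and tau_y must be positive")
  if (epsilon < 0 || c3 < 0 || T < 0)
    stop_config("epsilon, c3 and T must be non-negative")
  structure(list(tau_a = tau_a, tau_y = tau_y, epsilon = epsilon, c3 = c3,
                 alpha2 = alpha2, T = T), class = "dqs_cubic")
}

# linearised denominator of the cubic circuit's response:
# R_a(w) = alpha2 / D(w),  D(w) = 1 - i w tau_a + 1/(eps - i w tau_y).
cubic_denominator <- function(params, omega, stiffening = 0) {
  (1 + stiffening) - 1i * omega * params$tau_a +
    1 / complex(real = params$epsilon, imaginary = -omega * params$tau_y)
}

#' Analytic response spectrum of the cubic adaptive circuit
#'
#' Linear (weak-noise, weak-stimulus) response of the circuit in
#' [cubic_params()]:
#' \deqn{\tilde R_a(\omega) = \alpha_2 \left[1 - i\omega\tau_a +
#'   \frac{1}{\epsilon - i\omega\tau_y}\right]^{-1}.}
#' Its imaginary part is negative (phase lead) for
#' \eqn{0 < \omega < \omega^*} and changes sign at the characteristic
#' frequency [omega_star()].  Requires
#' \eqn{\epsilon^2 \tau_a/\tau_y < 1} for the phase-leading band to exist.
#'
#' @param params a [cubic_params()].
#' @param omega positive increasing frequency grid.
#' @return a [response_spectrum()].
#' @export
cubic_response <- function(params, omega) {
  omega_star(params)  # validates the active-band condition
  response_spectrum(omega, params$alpha2 / cubic_denominator(params, omega))
}

#' Sign-change frequency of the cubic circuit
#'
#' \deqn{\omega^* = (\tau_a\tau_y)^{-1/2}\,(1 - \epsilon^2\tau_a/\tau_y)^{1/2}}
#' is the frequency where the imaginary part of the response (and hence the
#' phase shift) changes sign; the response amplitude peaks close to it.  The
#' quality factor \eqn{Q = \tau_a\omega^*} is attached as attribute `"Q"`.
#'
#' @param params a [cubic_params()].
#' @return the frequency, with attribute `Q`.
#' @export
omega_star <- function(params) {
  disc <- 1 - params$epsilon^2 * params$tau_a / params$tau_y
  if (disc <= 0)
    stop_numerical(
      "no active band: epsilon^2 * tau_a / tau_y = %.3g >= 1",
      params$epsilon^2 * params$tau_a / params$tau_y)
  ws <- sqrt(disc / (params$tau_a * params$tau_y))
  structure(ws, Q = params$tau_a * ws)
}
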