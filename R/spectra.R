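#' Frequency-resolved response spectrum
#'
#' The central container of the toolkit: a complex linear response
#' \eqn{\tilde R(\omega)} on a strictly increasing, positive angular
#' frequency grid.  The Fourier convention is fixed once for the whole
#' package: time series behave as \eqn{e^{-i\omega t}} and
#' \eqn{\tilde R(\omega) = \int_0^\infty R(t) e^{i\omega t} dt}, so the
#' over-damped signal response reads \eqn{1/(K - i\gamma\omega)} literally.
#' The phase is \eqn{\phi(\omega) \equiv -\arg \tilde R(\omega)}; the
#' response to \eqn{\cos(\omega t)} is \eqn{|\tilde R|\cos(\omega t+\phi)},
#' so \eqn{\phi > 0} means the response *leads* the stimulus.
#'
#' @param omega strictly increasing positive angular frequency grid
#'   (rad per unit time).
#' @param value complex response values on `omega`.
#' @return An object of class `dqs_spectrum` with fields `omega`, `value`
#'   and `convention`.
#' @export
response_spectrum <- function(omega, value) {
  if (length(omega) != length(value))
    stop_config("omega and value must have equal length")
  if (any(!is.finite(omega)) || any(omega <= 0) || any(diff(omega) <= 0))
    stop_config("omega must be strictly increasing and positive")
  structure(list(omega = as.numeric(omega), value = as.complex(value),
                 convention = "exp(-i*omega*t); R(w)=int_0^Inf R(t)exp(i w t)dt"),
            class = "dqs_spectrum")
}

#' @export
print.dqs_spectrum <- function(x, ...) {
  cat(sprintf("<dqs_spectrum> %d frequencies on [%.4g, %.4g]\n",
              length(x$omega), min(x$omega), max(x$omega)))
  bands <- active_band(x)
  if (nrow(bands)) {
    cat(sprintf("  active (phase-leading) band(s): %s\n",
                paste(sprintf("[%.4g, %.4g]", bands$lower, bands$upper),
                      collapse = ", ")))
  } else cat("  no phase-leading band on this grid\n")
  invisible(x)
}

#' Phase shift of a response spectrum
#'
#' Returns \eqn{\phi(\omega) = -\arg \tilde R(\omega)} in \eqn{(-\pi,\pi]}.
#' Positive values are a phase lead over a sinusoidal stimulus, negative
#' values a lag.
#'
#' @param spectrum a [response_spectrum()].
#' @return numeric vector of phases.
#' @export
spectrum_phase <- function(spectrum) {
  -Arg(spectrum$value)
}

#' Amplitude of a response spectrum
#' @param spectrum a [response_spectrum()].
#' @export
spectrum_amplitude <- function(spectrum) {
  Mod(spectrum$value)
}

#' Signal (medium) model
#'
#' Over-damped dynamics of the shared extracellular signal:
#' \eqn{\gamma \dot s = -K s + \sum_j \alpha_1 a_j + \xi}.  For chemical
#' signals \eqn{\gamma = 1} and \eqn{K} is the degradation/dilution rate;
#' the relaxation time is \eqn{\tau_s = \gamma / K}.
#'
#' @param gamma friction (or unit conversion) coefficient, > 0.
#' @param K restoring stiffness / degradation rate, > 0.
#' @param alpha1 per-cell forcing strength, > 0.
#' @param T_s signal noise strength (0 allowed).
#' @return object of class `dqs_signal` with derived `tau_s = gamma/K`.
#' @export
signal_model <- function(gamma = 1, K = 1, alpha1 = 1, T_s = 0) {
  if (!is.finite(gamma) || gamma <= 0 || !is.finite(K) || K <= 0)
    stop_config("invalid signal model: gamma and K must be positive")
  if (alpha1 < 0) stop_config("invalid signal model: negative alpha1")
  if (T_s < 0) stop_config("invalid signal model: negative noise strength")
  structure(list(gamma = gamma, K = K, alpha1 = alpha1, T_s = T_s,
                 tau_s = gamma / K), class = "dqs_signal")
}

#' @export
print.dqs_signal <- function(x, ...) {
  cat(sprintf("<dqs_signal> gamma=%g K=%g alpha1=%g T_s=%g (tau_s=%g)\n",
              x$gamma, x$K, x$alpha1, x$T_s, x$tau_s))
  invisible(x)
}

#' Signal response spectrum
#'
#' \eqn{\tilde R_s(\omega) = 1 / (K - i\gamma\omega)}.  Its phase
#' \eqn{\phi_s = -\arctan(\omega\tau_s)} lies in \eqn{(-\pi/2, 0)} for all
#' \eqn{\omega > 0}: a dissipative medium always lags.
#'
#' @param model a [signal_model()].
#' @param omega positive increasing frequency grid.
#' @return a [response_spectrum()].
#' @export
signal_response <- function(model, omega) {
  if (!inherits(model, "dqs_signal")) stop_config("model must be a dqs_signal")
  response_spectrum(omega, 1 / complex(real = model$K,
                                       imaginary = -model$gamma * omega))
}

#' Correlation (fluctuation) spectrum
#'
#' One-sided grid of the two-sided power spectral density
#' \eqn{\tilde C(\omega) = \langle|\tilde x(\omega)|^2\rangle} per unit
#' observation time of a stationary series.
#'
#' @param omega positive increasing frequency grid.
#' @param value non-negative spectral density values.
#' @param n_segments number of averaged segments (for standard errors).
#' @export
corr_spectrum <- function(omega, value, n_segments = 1L) {
  if (any(value < 0)) stop_config("spectral density must be non-negative")
  structure(list(omega = as.numeric(omega), value = as.numeric(value),
                 n_segments = as.integer(n_segments)),
            class = "dqs_corr")
}

#' Phase-leading (active) frequency bands
#'
#' Maximal sub-intervals of the grid where \eqn{\mathrm{Im}\,\tilde
#' R(\omega) < 0}, i.e. where the response leads the stimulus and the cell
#' can pump energy into the signal.  A passive (equilibrium) response has
#' none.  Band edges interior to the grid are refined by linear
#' interpolation of the imaginary part.
#'
#' @param spectrum a [response_spectrum()].
#' @return data.frame with columns `lower`, `upper` (possibly 0 rows).
#' @export
active_band <- function(spectrum) {
  w <- spectrum$omega; im <- Im(spectrum$value)
  neg <- im < 0
  out <- data.frame(lower = numeric(0), upper = numeric(0))
  if (!any(neg)) return(out)
  r <- rle(neg)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  cross <- function(i1, i2) {  # zero crossing between grid nodes
    w[i1] + (w[i2] - w[i1]) * im[i1] / (im[i1] - im[i2])
  }
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i1 <- starts[k]; i2 <- ends[k]
    lo <- if (i1 == 1) w[1] else cross(i1 - 1, i1)
    hi <- if (i2 == length(w)) w[i2] else cross(i2, i2 + 1)
    out <- rbind(out, data.frame(lower = lo, upper = hi))
  }
  out
}

#' Cell-to-signal energy flux
#'
#' Average power delivered by one cell to a signal oscillating at
#' \eqn{\omega} with spectral power \eqn{\langle|\tilde s(\omega)|^2\rangle}:
#' \deqn{\dot W = -\alpha_1 \omega \tilde R''_a(\omega)
#'   \langle|\tilde s(\omega)|^2\rangle
#'   = \alpha_1 \omega |\tilde R_a| \sin\phi_a \langle|\tilde s|^2\rangle.}
#' Positive exactly when the activity leads the signal.
#'
#' @param spectrum activity [response_spectrum()].
#' @param signal_power \eqn{\langle|\tilde s(\omega)|^2\rangle} on the
#'   spectrum grid (scalar or vector), must be non-negative.
#' @param alpha1 per-cell forcing strength.
#' @param omega optional subset of frequencies (defaults to the full grid;
#'   values are interpolated if not grid nodes).
#' @return numeric vector of powers.
#' @export
energy_flux <- function(spectrum, signal_power, alpha1 = 1,
                        omega = spectrum$omega) {
  if (any(signal_power < 0)) stop_config("signal power must be non-negative")
  if (any(omega <= 0)) stop_config("energy flux defined for omega > 0")
  f <- complex_interpolant(spectrum$omega, spectrum$value)
  -alpha1 * omega * Im(f(omega)) * signal_power
}

#' Fluctuation-dissipation ratio
#'
#' \eqn{\mathrm{ratio}(\omega) = \omega \tilde C(\omega) /
#' (2 T \tilde R''(\omega))}.  Equals 1 at every frequency for equilibrium
#' dynamics; an adaptive circuit gives a negative ratio in its
#' phase-leading band (where \eqn{\tilde R'' < 0} while \eqn{\tilde C > 0}).
#' Grid points with \eqn{\tilde R'' = 0} are returned as `NA`.
#'
#' @param response a [response_spectrum()].
#' @param correlation a [corr_spectrum()] on the same grid.
#' @param T noise strength ("temperature") of the dynamics.
#' @return numeric vector of ratios with `NA` at masked points.
#' @export
fdt_ratio <- function(response, correlation, T) {
  if (length(response$omega) != length(correlation$omega) ||
      max(abs(response$omega - correlation$omega)) > 1e-9 * max(response$omega))
    stop_config("response and correlation grids do not match")
  rpp <- Im(response$value)
  out <- response$omega * correlation$value / (2 * T * rpp)
  out[rpp == 0] <- NA_real_
  out
}
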