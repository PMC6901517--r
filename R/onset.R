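#' Phase-matching roots
#'
#' Solves the first onset condition \eqn{\phi_a(\omega) = -\phi_s(\omega)}
#' for \eqn{\omega > 0}: the cell's phase lead must exactly cancel the
#' medium's phase lag at the selected frequency.  Candidate brackets are
#' sign changes of \eqn{\phi_a(\omega) - \arctan(\omega\tau_s)} on the
#' spectrum grid, refined by root bisection on a spline interpolant of the
#' complex response.  \eqn{\omega = 0} is never a valid onset.
#'
#' @param activity activity [response_spectrum()] covering its active band.
#' @param signal a [signal_model()].
#' @param tol relative frequency tolerance of the refinement (default 1e-8).
#' @return increasing numeric vector of roots (length 0 = no onset; the
#'   attribute `reason` then distinguishes `"no-active-band"` from
#'   `"no-crossing"`).
#' @export
phase_matching <- function(activity, signal, tol = 1e-8) {
  f <- complex_interpolant(activity$omega, activity$value)
  h <- function(w) -Arg(f(w)) - atan(w * signal$tau_s)
  w <- activity$omega
  hv <- h(w)
  if (nrow(active_band(activity)) == 0)
    return(structure(numeric(0), reason = "no-active-band"))
  br <- which(hv[-length(hv)] * hv[-1] <= 0 & is.finite(hv[-1]))
  roots <- numeric(0)
  for (k in br) {
    if (hv[k] == 0 && w[k] == w[1]) next
    r <- tryCatch(
      stats::uniroot(h, c(w[k], w[k + 1]), tol = tol * w[k + 1])$root,
      error = function(e) NA_real_)
    if (is.finite(r) && r > 0 && -Arg(f(r)) > -1e-9) roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  if (!length(roots)) return(structure(numeric(0), reason = "no-crossing"))
  roots
}

#' Critical density from the gain condition
#'
#' Given an onset frequency from [phase_matching()], the second condition
#' \eqn{|\tilde R_a(\omega_o)\tilde R_s(\omega_o)| = (\alpha_1 N_o)^{-1}}
#' yields the critical cell count and the dimensionless coupling
#' \eqn{\bar N_o = N_o\alpha_1\alpha_2} at which collective oscillations
#' first appear.
#'
#' @param activity activity [response_spectrum()].
#' @param signal a [signal_model()].
#' @param omega_o onset frequency (scalar or vector of roots).
#' @param alpha2 cell sensitivity entering \eqn{\bar N}.
#' @return data.frame with `omega`, `N_o`, `Nbar_o`, `residual`.
#' @export
onset_density <- function(activity, signal, omega_o, alpha2 = 1) {
  fa <- complex_interpolant(activity$omega, activity$value)
  Rs <- function(w) 1 / complex(real = signal$K, imaginary = -signal$gamma * w)
  gain <- Mod(fa(omega_o) * Rs(omega_o))
  if (any(gain == 0)) stop_numerical("divergent density: |R_a R_s| = 0")
  N_o <- 1 / (signal$alpha1 * gain)
  res <- Mod(N_o * signal$alpha1 * fa(omega_o) * Rs(omega_o) - 1)
  data.frame(omega = omega_o, N_o = N_o, Nbar_o = N_o * signal$alpha1 * alpha2,
             residual = res)
}

#' Full onset solution from an activity spectrum
#'
#' Combines [phase_matching()] and [onset_density()].  When several
#' phase-matched roots exist, the one with the smallest critical density is
#' the physical onset (the first linear instability met on raising the
#' density).
#'
#' @inheritParams onset_density
#' @return object of class `dqs_onset`: a list with `omega_o`, `N_o`,
#'   `Nbar_o`, `period`, `root_multiplicity`, `roots` (all candidates with
#'   densities) and `diagnostics`.  `NULL` fields and `status =
#'   "no-onset"` when phase matching has no solution.
#' @export
onset_point <- function(activity, signal, alpha2 = 1) {
  roots <- phase_matching(activity, signal)
  if (!length(roots)) {
    return(structure(list(status = attr(roots, "reason") %||% "no-onset",
                          omega_o = NA_real_, N_o = NA_real_,
                          Nbar_o = NA_real_, period = NA_real_,
                          root_multiplicity = 0L, roots = NULL),
                     class = "dqs_onset"))
  }
  cand <- onset_density(activity, signal, roots, alpha2 = alpha2)
  i <- which.min(cand$N_o)
  structure(list(status = "ok", omega_o = cand$omega[i], N_o = cand$N_o[i],
                 Nbar_o = cand$Nbar_o[i], period = 2 * pi / cand$omega[i],
                 root_multiplicity = nrow(cand), roots = cand,
                 diagnostics = list(residual = cand$residual[i])),
            class = "dqs_onset")
}

#' @export
print.dqs_onset <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<dqs_onset> no onset (%s)\n", x$status))
  } else {
    cat(sprintf(
      "<dqs_onset> omega_o=%.6g (period %.6g), N_o=%.6g, Nbar_o=%.6g, %d root(s)\n",
      x$omega_o, x$period, x$N_o, x$Nbar_o, x$root_multiplicity))
  }
  invisible(x)
}

#' Onset prediction straight from a measured step response
#'
#' The full data-analysis pipeline: smooth and differentiate the step
#' response into a kernel, Fourier transform it into a spectrum, then solve
#' the phase-matching and gain conditions against the given signal model.
#' Fast signal clearance (\eqn{\tau_s \to 0}) returns the theoretical
#' lower bound on the period, \eqn{2\pi/\omega^*}.
#'
#' @param step a [step_response()].
#' @param signal a [signal_model()]; its `tau_s` sets the medium lag.
#' @param alpha2 sensitivity entering \eqn{\bar N}.
#' @param omega optional frequency grid for the reconstructed spectrum; the
#'   default spans `[2*pi/T_record, pi/(5*dt)]` logarithmically.
#' @param window,order smoothing passed to [step_to_kernel()].
#' @return a `dqs_onset` (see [onset_point()]) with the reconstructed
#'   `spectrum` and `kernel` attached.
#' @export
onset_from_step <- function(step, signal, alpha2 = 1, omega = NULL,
                            window = 5, order = 2) {
  kern <- step_to_kernel(step, window = window, order = order)
  dt <- step$time[2] - step$time[1]
  Trec <- max(step$time)
  if (is.null(omega))
    omega <- exp(seq(log(2 * pi / Trec), log(pi / (5 * dt)), length.out = 400))
  spec <- kernel_to_spectrum(kern, omega)
  eps_hat <- tryCatch(as.numeric(adaptation_error(step)),
                      error = function(e) NA_real_)
  if (is.finite(eps_hat) && abs(eps_hat) > 0.2 * max(spectrum_amplitude(spec)))
    warning("large adaptation error relative to peak response; onset may not exist")
  res <- onset_point(spec, signal, alpha2 = alpha2)
  res$adaptation_error <- eps_hat
  res$spectrum <- spec
  res$kernel <- kern
  res
}

#' Renormalised (finite-amplitude) response of the cubic circuit
#'
#' First-harmonic (describing-function) approximation: when the activity
#' oscillates with amplitude \eqn{A}, the cubic term acts on the
#' fundamental as an extra linear stiffness \eqn{(3/4) c_3 A^2}, so
#' \deqn{\tilde R_a^+(\omega, A) = \alpha_2\left[1 + \tfrac{3}{4}c_3A^2
#'   - i\omega\tau_a + \frac{1}{\epsilon - i\omega\tau_y}\right]^{-1}.}
#' \eqn{A = 0} recovers the linear spectrum; the phase-matching crossing
#' moves to lower frequency as \eqn{A} grows, producing the downward
#' frequency shift seen above onset.  This is an approximation to the full
#' amplitude renormalisation (flagged in the `method` field).
#'
#' @param params a [cubic_params()].
#' @param A oscillation amplitude of the activity (>= 0).
#' @param omega positive increasing frequency grid.
#' @return list of class `dqs_renorm` with `A`, `spectrum`, `method`.
#' @export
renormalised_response <- function(params, A, omega) {
  if (A < 0) stop_config("amplitude must be non-negative")
  val <- params$alpha2 /
    cubic_denominator(params, omega, stiffening = 0.75 * params$c3 * A^2)
  structure(list(A = A, spectrum = response_spectrum(omega, val),
                 method = "first-harmonic balance (approximation)"),
            class = "dqs_renorm")
}

#' Finite-amplitude onset curve of the coupled cubic model
#'
#' Applies the phase-matching and gain conditions to the renormalised
#' spectrum at each amplitude, giving the predicted oscillation frequency
#' and the coupling strength \eqn{\bar N(A)} that sustains amplitude
#' \eqn{A}.  Inverting the curve predicts the frequency at a given
#' \eqn{\bar N} above onset.
#'
#' @param params a [cubic_params()].
#' @param signal a [signal_model()].
#' @param A amplitudes (vector).
#' @param omega frequency grid for the renormalised spectra.
#' @return data.frame with `A`, `omega`, `Nbar`.
#' @export
renormalised_onset_curve <- function(params, signal, A,
                                     omega = NULL) {
  if (is.null(omega)) {
    ws <- as.numeric(omega_star(params))
    omega <- seq(ws / 50, 3 * ws, length.out = 1200)
  }
  rows <- lapply(A, function(a) {
    sp <- renormalised_response(params, a, omega)$spectrum
    o <- onset_point(sp, signal, alpha2 = params$alpha2)
    data.frame(A = a, omega = o$omega_o, Nbar = o$Nbar_o)
  })
  do.call(rbind, rows)
}

#' Maximum signal relaxation time for oscillation onset
#'
#' With a finite adaptation error the cell's phase lead is bounded, so the
#' medium cannot lag arbitrarily: there is a largest
#' \eqn{\tau_s^* \sim \epsilon^{-1}} beyond which phase matching fails.
#' Located by bisection on \eqn{\tau_s} over the existence of a
#' [phase_matching()] root for the analytic cubic spectrum; for
#' \eqn{\epsilon = 0} the phase lead survives to zero frequency and
#' `Inf` is returned.
#'
#' @param params a [cubic_params()] with `epsilon > 0` (else `Inf`).
#' @param omega_min lowest frequency probed, relative to
#'   \eqn{\omega^*} (default 1e-4; the limiting root sits at
#'   \eqn{\omega \to 0^+}).
#' @param tol relative bisection tolerance (default 1e-4).
#' @return \eqn{\tau_s^*} (possibly `Inf`).
#' @export
max_signal_time <- function(params, omega_min = 1e-4, tol = 1e-4) {
  if (params$epsilon == 0) return(Inf)
  ws <- as.numeric(omega_star(params))
  omega <- exp(seq(log(omega_min * ws), log(4 * ws), length.out = 1500))
  sp <- cubic_response(params, omega)
  has_root <- function(tau_s) {
    length(phase_matching(sp, signal_model(gamma = tau_s, K = 1))) > 0
  }
  lo <- params$tau_y / 100
  if (!has_root(lo)) stop_numerical("no onset even at fast signal clearance")
  hi <- 2 * params$tau_y / params$epsilon
  it <- 0
  while (has_root(hi) && it < 60) { hi <- hi * 2; it <- it + 1 }
  if (it >= 60) return(Inf)
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (has_root(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
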