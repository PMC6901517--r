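#' FitzHugh-Nagumo circuit parameters
#'
#' Excitable two-node circuit:
#' \deqn{\tau_a \dot a = a - a^3/3 - y + \alpha_2 s + \eta_a, \qquad
#'       \tau_y \dot y = a - \epsilon y + a_0 + \eta_y,}
#' same noise contract as [cubic_params()].  The positive linear term in
#' the activity equation gives excitability; the excitable regime used
#' throughout requires \eqn{\tau_y > \tau_a}.  For small \eqn{\epsilon}
#' the resting activity sits near \eqn{-a_0}.
#'
#' @param tau_a,tau_y relaxation times with `tau_y > tau_a > 0`.
#' @param epsilon feedback leak (adaptation error parameter).
#' @param a0 resting-state offset.
#' @param alpha2 signal sensitivity.
#' @param T noise strength.
#' @export
fhn_params <- function(tau_a = 1, tau_y = 5, epsilon = 0.1, a0 = 1.5,
                       alpha2 = 1, T = 0.1) {
  if (!(tau_y > tau_a && tau_a > 0))
    stop_config("excitable regime requires tau_y > tau_a > 0")
  if (T < 0) stop_config("negative noise strength")
  structure(list(tau_a = tau_a, tau_y = tau_y, epsilon = epsilon, a0 = a0,
                 alpha2 = alpha2, T = T), class = "dqs_fhn")
}

#' Noise-free resting state of the FHN circuit
#'
#' Solves \eqn{\epsilon(a - a^3/3) = a + a_0} for the stable fixed point
#' (real cubic root) and returns `c(a, y)`.
#'
#' @param params an [fhn_params()].
#' @export
fhn_resting_state <- function(params) {
  eps <- params$epsilon; a0 <- params$a0
  # eps*(a - a^3/3) - a - a0 = 0  ->  -(eps/3) a^3 + (eps - 1) a - a0 = 0
  r <- polyroot(c(-a0, eps - 1, 0, -eps / 3))
  a <- Re(r[abs(Im(r)) < 1e-8])
  if (!length(a)) stop_numerical("no real resting state found")
  a <- a[which.min(abs(a + a0))]  # the branch continuous with a = -a0
  c(a = a, y = (a + a0) / eps)
}

#' Simulation configuration
#'
#' @param dt integration step; must satisfy `dt <= min(timescales)/50`,
#'   checked against the model at simulation time.
#' @param duration total simulated time (after which recording stops).
#' @param seed integer RNG seed (expanded by a documented splitting rule
#'   for ensembles).
#' @param n_realizations ensemble size for response estimators.
#' @param transient initial interval discarded by analyses.
#' @param stride record every `stride`-th step (thinning).
#' @export
sim_config <- function(dt = 0.01, duration = 100, seed = 1L,
                       n_realizations = 1L, transient = 0, stride = 1L) {
  if (duration <= transient) stop_config("duration must exceed transient")
  if (dt <= 0) stop_config("dt must be positive")
  structure(list(dt = dt, duration = duration, seed = as.integer(seed),
                 n_realizations = as.integer(n_realizations),
                 transient = transient, stride = as.integer(stride)),
            class = "dqs_simconfig")
}

check_dt <- function(sim, ...) {
  taus <- c(...)
  if (sim$dt > min(taus) / 50 + 1e-12)
    stop_config("dt = %g violates stability bound min(tau)/50 = %g",
                sim$dt, min(taus) / 50)
}

# Build the external-signal series for a protocol on the step grid.
signal_series <- function(protocol, n_steps, dt) {
  if (is.null(protocol)) return(numeric(0))
  if (is.numeric(protocol)) {
    if (length(protocol) < n_steps) stop_config("external series too short")
    return(protocol[seq_len(n_steps)])
  }
  t <- (seq_len(n_steps) - 1) * dt
  switch(protocol$kind,
    none = numeric(0),
    step = (t >= (protocol$t_on %||% 0)) * protocol$size,
    sinusoid = protocol$amplitude * cos(protocol$omega *
                                          (t - (protocol$t_on %||% 0))) *
               (t >= (protocol$t_on %||% 0)),
    stop_config("unknown signal protocol '%s'", protocol$kind))
}

make_traj <- function(raw, dt, stride, params, seed, n_keep) {
  time <- seq(0, by = dt * stride, length.out = length(raw$s))
  structure(list(time = time, s = raw$s, a_mean = raw$a_mean,
                 a = raw$a, y = raw$y, params = params, seed = seed),
            class = "dqs_traj")
}

#' @export
print.dqs_traj <- function(x, ...) {
  cat(sprintf("<dqs_traj> %d samples, t in [0, %.4g], %d recorded cell(s)\n",
              length(x$time), max(x$time), ncol(x$a)))
  invisible(x)
}

#' Simulate the cubic adaptive circuit (single cell or driven ensemble)
#'
#' Euler-Maruyama integration of the circuit in [cubic_params()], driven by
#' an optional signal protocol: `NULL` (unstimulated),
#' `list(kind = "step", size =, t_on =)`,
#' `list(kind = "sinusoid", amplitude =, omega =, t_on =)`, or a numeric
#' series sampled at `dt`.  Reproducible under a fixed seed.
#'
#' @param params a [cubic_params()].
#' @param sim a [sim_config()].
#' @param signal signal protocol (see above).
#' @param n_cells number of independent replicate cells integrated jointly.
#' @param n_keep number of per-cell trajectories recorded.
#' @param init optional `c(a, y)` initial condition (defaults to 0).
#' @return a `dqs_traj` with fields `time`, `s` (external signal is NOT
#'   echoed: 0), `a_mean`, `a`, `y`.
#' @export
simulate_cubic <- function(params, sim, signal = NULL, n_cells = 1L,
                           n_keep = min(n_cells, 2L), init = c(0, 0)) {
  check_dt(sim, params$tau_a, params$tau_y)
  n_steps <- ceiling(sim$duration / sim$dt)
  s_ext <- signal_series(signal, n_steps, sim$dt)
  set.seed(sim$seed)
  raw <- cpp_sim_cubic(n_cells, n_steps, sim$dt, params$tau_a, params$tau_y,
                       params$epsilon, params$c3, params$alpha2, params$T,
                       s_ext, FALSE, 1, 1, 0, 0, sim$stride, n_keep,
                       rep(init[1], n_cells), rep(init[2], n_cells), 0)
  make_traj(raw, sim$dt, sim$stride, params, sim$seed, n_keep)
}

#' Simulate the FitzHugh-Nagumo circuit
#'
#' Same contract as [simulate_cubic()] for the excitable circuit of
#' [fhn_params()].  Cells start in the noise-free resting state unless
#' `init` is given.
#'
#' @inheritParams simulate_cubic
#' @param params an [fhn_params()].
#' @export
simulate_fhn <- function(params, sim, signal = NULL, n_cells = 1L,
                         n_keep = min(n_cells, 2L), init = NULL) {
  check_dt(sim, params$tau_a, params$tau_y)
  if (is.null(init)) init <- fhn_resting_state(params)
  n_steps <- ceiling(sim$duration / sim$dt)
  s_ext <- signal_series(signal, n_steps, sim$dt)
  set.seed(sim$seed)
  raw <- cpp_sim_fhn(n_cells, n_steps, sim$dt, params$tau_a, params$tau_y,
                     params$epsilon, params$a0, params$alpha2, params$T,
                     s_ext, FALSE, 1, 0, 0, sim$stride, n_keep,
                     rep(init[1], n_cells), rep(init[2], n_cells), 0)
  make_traj(raw, sim$dt, sim$stride, params, sim$seed, n_keep)
}

sim_one <- function(model, params, sim, signal, n_cells, seed) {
  s2 <- sim; s2$seed <- seed
  if (model == "cubic")
    simulate_cubic(params, s2, signal, n_cells = n_cells, n_keep = 1L)
  else
    simulate_fhn(params, s2, signal, n_cells = n_cells, n_keep = 1L)
}

#' Noise-averaged step response of a circuit
#'
#' Ensemble estimate of \eqn{\langle a(t)\rangle - \langle a\rangle_u}
#' after a step stimulus.  Variance is reduced with common random numbers:
#' each stimulated realization is paired with an unstimulated one driven by
#' the identical noise sequence (same split seed), and the paired
#' differences are averaged.  A transient of `sim$transient` is simulated
#' before the step lands at relative time 0.
#'
#' @param model `"cubic"` or `"fhn"`.
#' @param params matching parameter object.
#' @param sim a [sim_config()]; `n_realizations >= 100` recommended for
#'   noisy circuits.
#' @param step_size amplitude of the step.
#' @return a [step_response()] with standard errors attached.
#' @export
estimate_step_response <- function(model = c("cubic", "fhn"), params, sim,
                                   step_size = 0.1) {
  model <- match.arg(model)
  n_steps <- ceiling(sim$duration / sim$dt)
  on_idx <- ceiling(sim$transient / sim$dt)
  prot <- list(kind = "step", size = step_size, t_on = sim$transient)
  acc <- NULL
  for (k in seq_len(sim$n_realizations)) {
    sk <- split_seed(sim$seed, k)
    tr1 <- sim_one(model, params, sim, prot, 1L, sk)
    tr0 <- sim_one(model, params, sim, NULL, 1L, sk)
    d <- tr1$a[, 1] - tr0$a[, 1]
    acc <- if (is.null(acc)) cbind(d) else cbind(acc, d)
  }
  keep <- which(tr1$time >= sim$transient)
  m <- rowMeans(acc)[keep]
  se <- if (ncol(acc) > 1) apply(acc[keep, , drop = FALSE], 1, stats::sd) /
    sqrt(ncol(acc)) else rep(0, length(keep))
  step_response(tr1$time[keep] - sim$transient, m, step_size = step_size,
                stderr = se)
}

#' Measured response spectrum from sinusoidal stimulation
#'
#' For each frequency, the ensemble-averaged activity under a weak
#' sinusoidal signal is fitted by least squares to
#' \eqn{A_r\cos(\omega t + \phi)} over an integer number of periods after a
#' discarded transient; the response value is
#' \eqn{(A_r/\mathrm{amplitude})\,e^{-i\phi}} under the package phase
#' convention.  Optionally the stimulus amplitude is halved and the
#' amplitude compared to check linearity (> 5% change attaches a
#' `nonlinearity` warning attribute).
#'
#' @param model `"cubic"` or `"fhn"`.
#' @param params matching parameter object.
#' @param sim a [sim_config()]; `duration`/`transient` are ignored in
#'   favour of `periods`/`discard`.
#' @param omega frequencies to probe (increasing).
#' @param amplitude stimulus amplitude.
#' @param periods measured periods per frequency (default 20).
#' @param discard discarded initial periods (default 5).
#' @param check_linearity rerun at half amplitude and compare (default
#'   FALSE; costs a second ensemble).
#' @return a [response_spectrum()] (attribute `nonlinearity` if checked).
#' @export
estimate_sine_response <- function(model = c("cubic", "fhn"), params, sim,
                                   omega, amplitude = 0.05, periods = 20,
                                   discard = 5, check_linearity = FALSE) {
  model <- match.arg(model)
  measure <- function(amp, seed0) {
    vapply(seq_along(omega), function(i) {
      w <- omega[i]
      Tper <- 2 * pi / w
      dur <- (periods + discard) * Tper
      s2 <- sim_config(dt = sim$dt, duration = dur, seed = 1L,
                       transient = discard * Tper, stride = sim$stride)
      prot <- list(kind = "sinusoid", amplitude = amp, omega = w, t_on = 0)
      acc <- 0
      for (k in seq_len(sim$n_realizations)) {
        tr <- sim_one(model, params, s2, prot,
                      1L, split_seed(seed0, 10000 * i + k))
        acc <- acc + tr$a[, 1]
      }
      am <- acc / sim$n_realizations
      tt <- tr$time
      keep <- tt >= discard * Tper & tt < (discard + periods) * Tper
      X <- cbind(cos(w * tt[keep]), sin(w * tt[keep]))
      cf <- qr.coef(qr(X), am[keep] - mean(am[keep]))
      complex(real = cf[1], imaginary = cf[2])  # c1 + i c2
    }, complex(1))
  }
  cf <- measure(amplitude, sim$seed)
  # a(t) = c1 cos + c2 sin = A cos(wt + phi), phi = atan2(-c2, c1)
  val <- (complex(real = Re(cf), imaginary = Im(cf)))
  A <- Mod(val); phi <- atan2(-Im(cf), Re(cf))
  spec <- response_spectrum(omega, (A / amplitude) * exp(-1i * phi))
  if (check_linearity) {
    cf2 <- measure(amplitude / 2, split_seed(sim$seed, 777))
    rel <- abs(Mod(cf2) / (amplitude / 2) - A / amplitude) /
      pmax(A / amplitude, 1e-300)
    attr(spec, "nonlinearity") <- max(rel)
    if (max(rel) > 0.05)
      warning(sprintf("linearity check failed: %.1f%% amplitude dependence",
                      100 * max(rel)))
  }
  spec
}

#' Correlation spectrum of a stationary trajectory
#'
#' Segment-averaged periodogram (Hann window, 50% overlap) of a recorded
#' variable, normalised as a two-sided spectral density so that the
#' equilibrium fluctuation-dissipation ratio \eqn{\omega C/(2TR'')} reads
#' 1.  The transient declared in the trajectory's config should already be
#' excluded by the caller (pass `from`).
#'
#' @param traj a `dqs_traj` (or a plain numeric series with `dt` given).
#' @param variable which series: `"a"` (first recorded cell), `"a_mean"`,
#'   or `"s"`.
#' @param segments number of averaging segments (default 8; fewer than 8
#'   available segments raises a variance warning).
#' @param from drop times before this value.
#' @param dt sampling interval when `traj` is a plain vector.
#' @return a [corr_spectrum()].
#' @export
correlation_spectrum <- function(traj, variable = c("a", "a_mean", "s"),
                                 segments = 8, from = 0, dt = NULL) {
  if (inherits(traj, "dqs_traj")) {
    variable <- match.arg(variable)
    x <- switch(variable, a = traj$a[, 1], a_mean = traj$a_mean, s = traj$s)
    keep <- traj$time >= from
    x <- x[keep]
    dt <- traj$time[2] - traj$time[1]
  } else x <- as.numeric(traj)
  if (is.null(dt)) stop_config("dt required for plain series")
  if (length(x) < 8 * segments)
    warning("record shorter than 8 segments: high periodogram variance")
  p <- welch_psd(x, dt, segments = segments)
  corr_spectrum(p$omega, p$psd, n_segments = p$n_segments)
}
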