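#' Reduced glycolysis circuit parameters
#'
#' A minimal condensed model of yeast glycolysis built around ATP
#' homeostasis and redox coupling to acetaldehyde (ACE):
#' \itemize{
#'   \item v1, upper glycolysis (HK+PFK condensed): `ATP -> ADP + G`,
#'     Michaelis in ATP (`KA`) with Hill inhibition by ATP (`KI`, `hill`)
#'     — the PFK negative feedback that drives the oscillator;
#'   \item v2, lower glycolysis (GAPDH+PYK condensed):
#'     `G + 2 ADP + NAD -> 2 ATP + PYR + NADH`, Michaelis in the lumped
#'     triose pool G (`KG`);
#'   \item v3 = `k3*ATP`, cellular ATP consumption;
#'   \item v4 = `k4*PYR` (PDC), pyruvate decarboxylation to ACE;
#'   \item v5 = `k5*NADH*ACE` (ADH), ACE reduction regenerating NAD;
#'   \item v6 = `k6*NADH`, glycerol-shunt reoxidation of NADH.  Without
#'     this ACE-independent redox sink, NAD conservation would force ADH
#'     to consume the entire PDC flux at steady state and the free
#'     intracellular ACE level would vanish.
#' }
#' Adenine (`ATP+ADP`) and pyridine (`NAD+NADH`) pools are conserved.
#' The NAD/NADH ratio is the instantaneous receiver of the ACE signal and
#' PYR is the sender.  Default constants were tuned once so that a cell
#' with clamped intracellular ACE has a single oscillatory window at
#' intermediate ACE with adaptive response on both wings, and so that the
#' suspension model below reproduces the qualitative density/permeability
#' phase behaviour; ACE is in arbitrary units throughout.
#'
#' @param k1,KA,KI,hill upper-glycolysis rate, ATP Michaelis constant,
#'   ATP inhibition threshold and Hill order.
#' @param k2,KG lower-glycolysis rate and G Michaelis constant.
#' @param k3 ATP consumption rate.
#' @param k4 PDC rate. @param k5 ADH rate. @param k6 glycerol-shunt rate.
#' @param atot,ntot conserved adenine and pyridine pool totals.
#' @export
glyco_params <- function(k1 = 8.30, KA = 0.052, KI = 0.588, hill = 4,
                         k2 = 4.61, KG = 1.56, k3 = 6.81, k4 = 7.24,
                         k5 = 4.29, k6 = 1.00, atot = 2, ntot = 2) {
  v <- c(k1, KA, KI, hill, k2, KG, k3, k4, k5, k6)
  if (any(v < 0)) stop_config("glycolysis rates must be non-negative")
  if (atot <= 0 || ntot <= 0) stop_config("conserved pools must be positive")
  structure(list(k1 = k1, KA = KA, KI = KI, hill = hill, k2 = k2, KG = KG,
                 k3 = k3, k4 = k4, k5 = k5, k6 = k6,
                 atot = atot, ntot = ntot), class = "dqs_glyco")
}

glyco_par_vec <- function(p)
  c(p$k1, p$KA, p$KI, p$hill, p$k2, p$KG, p$k3, p$k4, p$k5, p$k6)

glyco_init <- function(p, ace_in = 0.2)
  c(ATP = p$atot / 2, ADP = p$atot / 2, G = 0.5, PYR = 0.5,
    NAD = p$ntot / 2, NADH = p$ntot / 2, ACE_in = ace_in)

#' Suspension (cell population) parameters
#'
#' Identical cells exchanging ACE with a shared extracellular pool:
#' per cell, `dACE_in = v4 - k_in*ACE_in - v5 + D*(ACE_ex - ACE_in)`;
#' for the medium, `dACE_ex = -rho*mean(D*(ACE_ex - ACE_in)) -
#' k_ex*ACE_ex`.  `rho` is the dimensionless cell density (volume
#' fraction), `D` the membrane permeability, `k_in`/`k_ex` the intra- and
#' extracellular ACE degradation rates.
#'
#' @param cell a [glyco_params()].
#' @param rho cell density in `[0, 1]`.
#' @param D membrane permeability (>= 0).
#' @param k_in,k_ex ACE degradation rates (defaults 0.5 / 0.3).
#' @export
suspension_params <- function(cell = glyco_params(), rho = 0.1, D = 0.4,
                              k_in = 0.5, k_ex = 0.3) {
  if (rho < 0 || rho > 1) stop_config("rho must lie in [0, 1]")
  if (D < 0 || k_in < 0 || k_ex < 0)
    stop_config("D, k_in, k_ex must be non-negative")
  structure(list(cell = cell, rho = rho, D = D, k_in = k_in, k_ex = k_ex),
            class = "dqs_susp")
}

glyco_limit_cycle <- function(x, tol_amp = 5e-3) {
  n <- length(x)
  q1 <- x[seq(floor(0.5 * n), floor(0.75 * n))]
  q2 <- x[seq(floor(0.75 * n) + 1, n)]
  a2 <- diff(range(q2))
  a2 > tol_amp * max(mean(x), 0.05) && a2 > 0.6 * diff(range(q1))
}

#' Single cell with clamped intracellular ACE
#'
#' Integrates the 6-species reduced circuit (RK4) with `ACE_in` held
#' fixed, and classifies the attractor reached after the transient.
#'
#' @param params a [glyco_params()].
#' @param ace_in clamped intracellular ACE concentration.
#' @param duration,dt integration window and step.
#' @param init optional initial state (6 named concentrations).
#' @param stride recording stride.
#' @return list with `time`, `state` (matrix ATP, ADP, G, PYR, NAD, NADH),
#'   `attractor` (`"limit_cycle"` or `"fixed_point"`), `ace_in`.
#' @export
simulate_cell_clamped <- function(params, ace_in, duration = 600, dt = 0.005,
                                  init = NULL, stride = 20L) {
  if (is.null(init)) init <- glyco_init(params)[1:6]
  m <- cpp_sim_glyco_clamped(as.integer(ceiling(duration / dt)), dt,
                             glyco_par_vec(params), ace_in, init, stride)
  colnames(m) <- c("ATP", "ADP", "G", "PYR", "NAD", "NADH")
  atp <- m[, "ATP"]
  list(time = seq(0, by = dt * stride, length.out = nrow(m)), state = m,
       attractor = if (glyco_limit_cycle(atp)) "limit_cycle" else "fixed_point",
       ace_in = ace_in)
}

#' Dynamical regime of the clamped cell
#'
#' Inside the oscillatory ACE window the cell is classified
#' `"oscillatory"`.  Otherwise a small relative step (`step_frac`) in the
#' clamped ACE is applied at the fixed point and the pyruvate (sender)
#' response is scored: `"adaptive"` when the long-time plateau stays below
#' half the peak deviation (ATP homeostasis relays the signal
#' transiently), `"non-adaptive"` when the plateau persists.
#'
#' @param params a [glyco_params()].
#' @param ace_in clamped ACE level.
#' @param step_frac relative ACE step for the adaptation probe.
#' @param duration settling time per stage.
#' @return list with `regime`, `adaptation_error` (plateau/peak ratio of
#'   the PYR response; `NA` when oscillatory) and `peak` (peak deviation).
#' @export
classify_regime <- function(params, ace_in, step_frac = 0.03,
                            duration = 2500) {
  s1 <- simulate_cell_clamped(params, ace_in, duration = duration)
  if (s1$attractor == "limit_cycle")
    return(list(regime = "oscillatory", adaptation_error = NA_real_,
                peak = NA_real_))
  x0 <- s1$state[nrow(s1$state), ]
  s2 <- simulate_cell_clamped(params, ace_in * (1 + step_frac),
                              duration = duration, init = x0)
  dev <- s2$state[, "PYR"] - x0["PYR"]
  peak <- max(abs(dev))
  plateau <- mean(utils::tail(dev, max(50, floor(0.05 * length(dev)))))
  ratio <- if (peak > 0) plateau / peak else 0
  regime <- if (peak > 1e-12 && abs(ratio) < 0.5) "adaptive" else "non-adaptive"
  list(regime = regime, adaptation_error = ratio, peak = peak)
}

#' Simulate the coupled cell suspension
#'
#' RK4 integration of `n_cells` reduced-model cells exchanging ACE with
#' the shared extracellular pool.  With `n_cells = 1` (default) the
#' homogeneous population collapses to the exact two-compartment system of
#' the synchronised manifold, which is the object the density sweeps
#' analyse; `n_cells > 1` with `init_jitter` probes the stability of that
#' manifold.
#'
#' @param sp a [suspension_params()].
#' @param duration,dt integration window and step.
#' @param n_cells number of explicitly represented cells.
#' @param init_jitter relative lognormal-ish jitter on initial states.
#' @param ace_ex0 initial extracellular ACE.
#' @param seed RNG seed for the jitter.
#' @param stride recording stride.
#' @return list with `time`, `ace_ex`, `ace_in_mean`, `cells` (state of
#'   the first two cells, 7 columns each), `params`.
#' @export
simulate_suspension <- function(sp, duration = 800, dt = 0.0075,
                                n_cells = 1L, init_jitter = 0,
                                ace_ex0 = 0.1, seed = 1L, stride = 10L) {
  p <- sp$cell
  x0 <- matrix(rep(glyco_init(p), each = n_cells), nrow = n_cells)
  if (init_jitter > 0) {
    set.seed(seed)
    x0 <- x0 * (1 + init_jitter * matrix(rnorm(length(x0)), nrow = n_cells))
    x0[x0 < 0] <- 0
  }
  n_keep <- min(n_cells, 2L)
  raw <- cpp_sim_glyco_susp(as.integer(n_cells),
                            as.integer(ceiling(duration / dt)), dt,
                            glyco_par_vec(p), sp$k_in, sp$k_ex, sp$D, sp$rho,
                            x0, ace_ex0, numeric(0), FALSE, stride, n_keep)
  list(time = seq(0, by = dt * stride, length.out = length(raw$ace_ex)),
       ace_ex = raw$ace_ex, ace_in_mean = raw$ace_in_mean,
       cells = raw$cells, params = sp)
}

#' Density sweep of the suspension
#'
#' Simulates the (two-compartment) suspension across a density grid and
#' records the oscillation amplitude of ATP and of extracellular ACE
#' together with time-averaged intra/extracellular ACE levels.  Reports
#' the lower onset and, when oscillation dies within the grid, the upper
#' quenching density (inverse dynamical quorum sensing) as bracketing
#' midpoints.
#'
#' @param sp a [suspension_params()] template (its `rho` is ignored).
#' @param rho increasing density grid.
#' @param ... passed to [simulate_suspension()].
#' @return data.frame with per-density records; attributes `onset` and
#'   `quench` (each `NA` when not bracketed).
#' @export
suspension_density_sweep <- function(sp, rho, ...) {
  rows <- lapply(rho, function(r) {
    spr <- sp; spr$rho <- r
    tr <- simulate_suspension(spr, ...)
    n <- length(tr$time); ti <- seq(floor(0.8 * n), n)
    atp <- tr$cells[ti, 1]
    osc <- glyco_limit_cycle(tr$cells[, 1])
    data.frame(rho = r,
               classification = if (osc) "oscillatory" else "quiescent",
               amplitude = diff(range(atp)) / 2,
               ace_ex_amplitude = diff(range(tr$ace_ex[ti])) / 2,
               ace_in = mean(tr$ace_in_mean[ti]),
               ace_ex = mean(tr$ace_ex[ti]))
  })
  out <- do.call(rbind, rows)
  osc <- out$classification == "oscillatory"
  onset <- NA_real_; quench <- NA_real_
  if (any(osc)) {
    i1 <- which(osc)[1]; i2 <- utils::tail(which(osc), 1)
    if (i1 > 1) onset <- (rho[i1 - 1] + rho[i1]) / 2
    if (i2 < length(rho)) quench <- (rho[i2] + rho[i2 + 1]) / 2
  }
  structure(out, onset = onset, quench = quench,
            class = c("dqs_glyco_sweep", "data.frame"))
}

#' Density-dependent cell response spectrum in the suspension
#'
#' Measures, at the quiescent operating point of density `rho`, the linear
#' response of a cell's intracellular ACE (its effective activity, which
#' forces the medium through membrane export) to a weak sinusoidal
#' perturbation of extracellular ACE.  The suspension is first relaxed
#' unforced; the forcing is then applied with the extracellular pool
#' clamped at its steady level, and amplitude/phase are fitted over an
#' integer number of periods.
#'
#' @param sp a [suspension_params()] (quiescent at this density).
#' @param omega frequencies to probe.
#' @param amplitude forcing amplitude on extracellular ACE; the linear
#'   window shrinks near a resonance, so keep it small (default 0.002).
#' @param periods,discard measured/discarded periods per frequency.
#' @param settle minimum discarded time (time units): near a resonance the
#'   forced response builds up over the inverse damping rate, so the
#'   discard window is `max(discard * period, settle)`.
#' @param dt integration step.
#' @return a [response_spectrum()] of `ACE_in` per unit `ACE_ex`.
#' @export
suspension_response <- function(sp, omega, amplitude = 0.002, periods = 40,
                                discard = 20, settle = 500, dt = 0.0075) {
  relax <- simulate_suspension(sp, duration = 1500, dt = dt, stride = 500L)
  n <- length(relax$time)
  x0 <- matrix(relax$cells[n, 1:7], nrow = 1)
  ex0 <- relax$ace_ex[n]
  val <- vapply(omega, function(w) {
    Tper <- 2 * pi / w
    discard <- max(discard, ceiling(settle / Tper))
    dur <- (periods + discard) * Tper
    nst <- as.integer(ceiling(dur / dt))
    s_ext <- amplitude * cos(w * (seq_len(nst) - 1) * dt)
    raw <- cpp_sim_glyco_susp(1L, nst, dt, glyco_par_vec(sp$cell),
                              sp$k_in, sp$k_ex, sp$D, sp$rho,
                              x0, ex0, s_ext, TRUE, 1L, 1L)
    tt <- seq(0, by = dt, length.out = length(raw$ace_in_mean))
    keep <- tt >= discard * Tper
    yy <- raw$ace_in_mean[keep] - mean(raw$ace_in_mean[keep])
    X <- cbind(cos(w * tt[keep]), sin(w * tt[keep]))
    cf <- qr.coef(qr(X), yy)
    complex(real = cf[1], imaginary = cf[2])
  }, complex(1))
  A <- Mod(val) / amplitude
  phi <- atan2(-Im(val), Re(val))
  response_spectrum(omega, A * exp(-1i * phi))
}

#' Self-consistency (onset/quench) check for the suspension
#'
#' Applies the phase-matching and gain conditions with the
#' density-dependent responses: the medium balance
#' \eqn{\dot c_{ex} = -(k_{ex} + \rho D) c_{ex} + \rho D \bar c_{in}}
#' gives the signal response \eqn{R_s = 1/((k_{ex}+\rho D) - i\omega)}
#' with per-cell coupling \eqn{\rho D}, so the loop gain is
#' \eqn{G(\omega) = \rho D\, R_a(\omega) R_s(\omega)} with \eqn{R_a} from
#' [suspension_response()].  Collective oscillations require a
#' phase-matched frequency with \eqn{|G| \ge 1}.
#'
#' @param sp a [suspension_params()] at the density to probe.
#' @param omega frequency grid for the measured response.
#' @param ... passed to [suspension_response()].
#' @param refine rounds of adaptive frequency refinement around the gain
#'   peak (the near-critical resonance is narrow; default 3).
#' @return list with `gain` (peak |G| after refinement), `omega_peak`,
#'   `omega_o` (phase-matched root, NA if none — generically none strictly
#'   above the quench), `unstable` (gain >= 1).
#' @export
suspension_onset_check <- function(sp, omega, refine = 3, ...) {
  rhoD <- sp$rho * sp$D
  sig <- signal_model(gamma = 1, K = sp$k_ex + rhoD, alpha1 = rhoD)
  loop_gain <- function(spec) {
    rhoD * Mod(spec$value) / Mod(complex(real = sig$K,
                                         imaginary = -spec$omega))
  }
  ra <- suspension_response(sp, omega, ...)
  g <- loop_gain(ra)
  for (r in seq_len(refine)) {
    i <- which.max(g)
    lo <- ra$omega[max(1, i - 1)]; hi <- ra$omega[min(length(g), i + 1)]
    om2 <- seq(lo, hi, length.out = 9)[2:8]
    ra2 <- suspension_response(sp, om2, ...)
    keep <- !(ra2$omega %in% ra$omega)
    allom <- c(ra$omega, ra2$omega[keep])
    o <- order(allom)
    ra <- response_spectrum(allom[o], c(ra$value, ra2$value[keep])[o])
    g <- loop_gain(ra)
  }
  roots <- phase_matching(ra, sig)
  omega_o <- if (length(roots)) {
    fa <- complex_interpolant(ra$omega, ra$value)
    gg <- rhoD * Mod(fa(roots)) / Mod(complex(real = sig$K,
                                              imaginary = -roots))
    roots[which.max(gg)]
  } else NA_real_
  i <- which.max(g)
  list(gain = g[i], omega_peak = ra$omega[i], omega_o = omega_o,
       unstable = g[i] >= 1, spectrum = ra)
}

#' Predict the inverse-DQS quenching density from measured spectra
#'
#' The upper quench of the suspension is a Hopf bifurcation whose loop
#' gain \eqn{\max_\omega |G(\omega;\rho)|} diverges as the resonance pole
#' reaches the real axis, so \eqn{1/\mathrm{gain}} is asymptotically
#' linear in \eqn{\rho - \rho_{c2}}.  Measuring the gain at two (or more)
#' quiescent densities above the quench and extrapolating
#' \eqn{1/\mathrm{gain}} to 1 predicts \eqn{\rho_{c2}} from response
#' functions alone.
#'
#' @param sp a [suspension_params()] template.
#' @param rho_probe quiescent densities (>= 2) above the quench.
#' @param omega initial frequency grid covering the resonance.
#' @param ... passed to [suspension_onset_check()].
#' @return list with `rho_c2` (predicted), `gains` (per probe).
#' @export
suspension_predict_quench <- function(sp, rho_probe, omega, ...) {
  gains <- vapply(rho_probe, function(r) {
    spr <- sp; spr$rho <- r
    suspension_onset_check(spr, omega, ...)$gain
  }, numeric(1))
  fit <- stats::lm(I(1 / gains) ~ rho_probe)
  rho_c2 <- (1 - coef(fit)[1]) / coef(fit)[2]
  list(rho_c2 = unname(rho_c2), gains = gains)
}
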