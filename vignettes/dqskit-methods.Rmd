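---
title: "Methods: response spectra, onset conditions, and the simulated worlds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response spectra, onset conditions, and the simulated worlds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dqskit)
```

This vignette records the model assumptions, conventions, numerical
choices and calibration decisions behind `dqskit`, and what the test suite
does and does not establish.

## 1. Model and conventions

The package analyses a population of `N` cells whose scalar activities
`a_j` force a shared over-damped signal,
`γ ṡ = −K s + Σ_j α₁ a_j + ξ`, and respond to it linearly through a causal
kernel, `⟨a_j(t)⟩ = ∫ R_a(t−τ) ⟨s(τ)⟩ dτ`.  Everything downstream hangs on
two conventions, fixed once:

* **Fourier convention.** Time series go as `e^{−iωt}` and
  `R̃(ω) = ∫₀^∞ R(t) e^{iωt} dt`.  This makes the signal response read
  literally `R̃_s = 1/(K − iγω)` and gives the Kramers–Krönig relation its
  usual sign.
* **Phase convention.** `φ ≡ −arg(R̃)`; the response to `cos(ωt)` is
  `|R̃| cos(ωt + φ)`, so `φ > 0` is a *lead* and `φ < 0` a *lag*.  The
  signal always lags: `φ_s = −arctan(ωτ_s) ∈ (−π/2, 0)` with
  `τ_s = γ/K`.  (Under-damped media, where `φ_s` can pass −π/2, are out
  of scope.)

Onset of collective oscillation is the first linear instability of the
quiescent state on raising density: `φ_a(ω₀) = −φ_s(ω₀)` (phase matching)
and `|R̃_a R̃_s| = (α₁N₀)⁻¹` (gain).  `ω = 0` is never accepted as an
onset; when several phase-matched roots exist, the one with the smallest
critical density is reported, because it is reached first.  Roots are
bracketed on the spectrum grid and refined by bisection on a spline
interpolant of the complex response (relative tolerance 1e-8); the
residual `|N₀α₁R̃_aR̃_s − 1|` is reported and kept below 1e-6.

## 2. Adaptation, the active band, and energetics

A cell is *adaptive* when its step response returns to baseline up to a
small residual — the adaptation error `ε`, estimated here as the plateau
of the trailing 20% of the record (stationarity is checked by comparing
the two halves of that window at two standard errors; noise-free records
use a small deterministic tolerance instead).  By causality
`ε = lim_{ω→0} R̃′(ω)`, so a small `ε` together with the Kramers–Krönig
relation forces `R̃″` to change sign: there is an *active band* where
`R̃″ < 0`, the response leads, the cell-to-signal energy flux
`Ẇ = −α₁ ω R̃″ ⟨|s̃|²⟩` is positive, and the equilibrium
fluctuation–dissipation identity `2T R̃″ = ω C̃` fails (the FDT ratio
`ωC̃/(2TR̃″)` turns negative).  For the two-node circuit with cubic
saturation the band edge is
`ω* = (τ_aτ_y)^{−1/2}(1 − ε²τ_a/τ_y)^{1/2}`, which is also the onset
frequency in the fast-clearance limit and sets the minimum period 2π/ω*.
Because the attainable phase lead shrinks with `ε`, the medium cannot be
arbitrarily slow: the largest workable `τ_s*` scales as `1/ε`
(`max_signal_time()` locates it by bisection; the limiting root sits at
`ω → 0⁺`, so the reported value depends weakly on the lowest probed
frequency, default `1e-4·ω*`).

**Kramers–Krönig quadrature.** The principal value is handled by
singularity subtraction: with `g = ω₁R̃″(ω₁)`, the regular part
`(g(ω₁)−g(ω))/(ω₁²−ω²)` is integrated by trapezoid (the removable point
filled with `g′/2ω`) and the singular part integrates in closed form.  A
node at `ω₁ = 0` (where `R̃″` vanishes by oddness) is prepended, and the
tail beyond the grid is extrapolated as a fitted power law.  Accuracy is
grid-limited: spectra of adaptive circuits decay like `1/ω`, so the grid
must extend well past the last frequency of interest (a log grid spanning
`ω ∈ [0.005, 50]` reconstructs the cubic circuit's real part to 0.03%; a
narrow linear grid degrades to ~2%).  The error estimate returned is a
half-resolution refinement difference.

## 3. Stochastic circuits and estimators

The two single-cell models — the adaptive two-node circuit with cubic
saturation and the excitable FitzHugh–Nagumo (FHN) circuit — are
integrated by Euler–Maruyama in C++ with additive Gaussian noise obeying
`⟨η_x η_x⟩ = 2Tτ_x δ` (so `T` is a dimensionless temperature), default
step `min(τ)/100` and a hard bound `min(τ)/50`; halving `dt` moves
stationary statistics by well under the stated tolerances.  All draws
come from R's RNG, so a `set.seed()` gives bit-identical trajectories;
one user seed expands to per-realization seeds through the documented
rule in `split_seed()`.

* *Step responses* are ensemble means with common random numbers: each
  stimulated realization is paired with an unstimulated run driven by the
  identical noise stream, and the paired difference is averaged.  This
  cancels the noise exactly at zero step and cuts variance dramatically
  otherwise.
* *Sine responses* fit the ensemble-averaged activity to
  `A cos(ωt + φ)` by least squares over an integer number of periods
  (default 20 measured after 5 discarded); an optional half-amplitude
  rerun flags nonlinearity above 5%.
* *Correlation spectra* are segment-averaged periodograms (Hann window,
  50% overlap, 8 segments) normalised as two-sided spectral densities, so
  the FDT ratio of an equilibrium Ornstein–Uhlenbeck signal is 1 with no
  extra factors.

## 4. Populations, onset detection, and bifurcation fits

Populations are integrated jointly with the signal.  Sweeps vary the
coupling `N̄ = Nα₁α₂` at fixed `N` by adjusting `α₁ = N̄/(Nα₂)`; in the
linearised regime results depend on `(N, α₁, α₂)` only through `N̄`
(verified by a test).  FHN populations subtract the *noise-free* resting
state `a_rs` (cubic-root solve) in the signal equation, for
reproducibility.

**Oscillation detector.**  The dominant frequency is the Welch-periodogram
peak (parabolically refined).  A series is called oscillatory iff (i) the
peak exceeds the local spectral floor by a factor (default 10) and (ii)
the mean of the band-passed analytic envelope exceeds 3× the *quiescent
noise scale*.  The noise scale is the envelope's own standard deviation:
below onset the signal is narrowband Gaussian noise filtered through the
population susceptibility, whose envelope is Rayleigh with mean/sd ≈ 1.9
regardless of overall amplitude, while a limit cycle has a nearly
constant envelope.  This scale-free statistic was chosen after the naive
out-of-band residual misclassified near-onset noise precursors ~25% below
the true onset; with it, detected onsets land within ~5% of the
linear-theory prediction at `T = 0.01`.  Near a noisy supercritical Hopf
the transition is smeared over a window of width ~√T in `N̄`; that, not
the detector, limits onset accuracy.

The sweep onset is the midpoint of the last-quiescent/first-oscillatory
bracket.  Hopf exponents are least-squares slopes of `log A` vs
`log(N̄−N̄₀)` over relative excess 0.02–0.3, with `N̄₀` refined over a
small grid to maximise linearity (this absorbs the detection bias of the
bracket midpoint).  The refinement is only for *unknown* onsets: near a
noisy bifurcation the in-band noise floor makes R² nearly degenerate
along a trade-off between `N̄₀` and the exponent, so when `N̄₀` is known
from the gain condition the fit should use it directly (`refine = 0`).  The upper bifurcation (oscillation death at high
coupling, `N̄_b ∝ 1/ε`) is located by bisection; because death is an
infinite-period transition the amplitude stays finite up to it, so the
bisection adds an amplitude-continuity guard (oscillatory requires ≥ 25%
of the low-end reference amplitude) against narrowband noise around the
newly stabilised high-density fixed point.  The period is recorded at
0.70 and 0.95 of `N̄_b`; its growth is the infinite-period signature.

**Finite amplitude.**  Above onset the cubic term stiffens the effective
linear response; the package uses the first-harmonic (describing-function)
replacement `1 → 1 + (3/4)c₃A²` in the response denominator.  This is an
approximation (flagged in the result's `method` field): the exact
amplitude renormalisation is not reproduced here, but the approximation
captures the downward frequency shift and tracks simulated frequencies to
within the stated 10% near onset.

## 5. The reduced glycolysis world

The yeast module is a *minimal* condensed model honouring the known
topology: ATP-inhibited upper glycolysis (Hill order 4), a condensed
lower-glycolysis step producing ATP, pyruvate and NADH, ATP consumption,
pyruvate decarboxylation to acetaldehyde (ACE), ADH reoxidation
(ACE + NADH → NAD), and a glycerol-shunt NADH sink.  The shunt is
structurally necessary: without an ACE-independent redox sink, NAD
conservation forces ADH to consume the entire ACE production at steady
state and the free intracellular ACE level is identically zero, leaving
nothing to signal with.  Adenine and pyridine pools are conserved exactly
(a bookkeeping test).

Rate constants were calibrated **once** (random search plus a single
overall rate scale, which is an exact time rescale of the clamped cell and
therefore leaves its phase diagram invariant) so that, with the stated
extracellular constants `k_in = 0.5`, `k_ex = 0.3`:

* a cell with clamped intracellular ACE shows one oscillatory window at
  intermediate ACE (≈ [0.50, 0.99] in the model's arbitrary units) with
  adaptive response on both wings;
* the suspension shows a smooth crossover from synchronised self-
  oscillation to collective (DQS) oscillation at permeability `D = 3`, a
  DQS band with an upper quenching density (*inverse DQS*, ≈ 0.82) at
  `D = 0.4`, and no oscillation at `D = 0.1`.

Numeric thresholds reported elsewhere for related models (window edge
0.72, quench 0.73) are treated as qualitative templates, not targets.
Known limitations: the lower adaptive wing is narrow (a few per cent in
ACE; further below, redox starvation disengages ATP homeostasis and the
response is non-adaptive rather than increasingly inaccurate), and the
lower window edge is subcritical, so near-edge classification depends on
initial conditions.  Density sweeps analyse the identical-cells
two-compartment collapse (the synchronised manifold); `n_cells > 1` with
initial jitter exposes the multistability of the full population, which
is deliberately not the object of the sweeps.

**Inverse-DQS closure.**  The quench is a Hopf bifurcation whose loop
gain `G(ω;ρ) = ρD R̃_a R̃_s` (with `R̃_s = 1/((k_ex+ρD) − iω)` from the
medium balance and `R̃_a` the *measured* response of intracellular ACE to
extracellular forcing at the quiescent operating point) has a resonance
pole approaching the real axis.  Strict phase-matched roots appear only
at criticality, but `1/max_ω|G|` is asymptotically linear in
`ρ − ρ_{c2}`; extrapolating it to 1 from two quiescent densities predicts
the quench within ~10%.  Practicalities that matter: the resonance is
narrow (adaptive grid refinement is built in), the linear window shrinks
near criticality (forcing amplitude 0.002 by default), and the forced
response builds up over the inverse damping time (minimum settling time
500 time units).

## 6. Fixtures and what the tests establish

The fixture generator produces the *exact* (matrix-exponential) step
response of the linear two-node circuit, optionally noisy, with ground
truth (`ε`, plateau, `ω*`) in a JSON sidecar; `omega_star = 1` solves
`τ_a = τ_y = √(1−ε²)/ω*` so the phase sign change lands exactly at the
requested frequency.  Step differentiation uses Savitzky–Golay smoothing
(window 5, order 2 by default — the choice is a package default, exposed
as configuration, since differentiating measured data admits many
schemes) followed by the analytic derivative of the local fit.

Green tests establish: internal consistency of the conventions
(causality/Kramers–Krönig closure, FDT for equilibrium controls),
agreement of simulation with linear theory in the weak-noise/weak-stimulus
regime, the onset closure between the solver and the simulated sweeps at
the stated 10%, and the qualitative phase structure of the glycolysis
world.  They do not establish behaviour for heterogeneous populations,
under-damped media, strongly nonlinear stimulation, or quantitative
correspondence with any specific experimental dataset — the synthetic
worlds are idealised (white noise, identical cells, exactly linear
medium).
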