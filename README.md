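# dqskit

Tools for analysing **dynamical quorum sensing (DQS)** — the emergence of
collective oscillations in a population of cells that communicate through a
shared extracellular signal, where isolated cells are quiescent.  Examples
range from pulsatile cAMP signalling in social amoebae to glycolytic
oscillations in dense yeast suspensions and spontaneous otoacoustic
emissions.

## The theory in brief

Each cell's activity `a` responds linearly to a weak signal `s` through a
causal response function with spectrum R̃ₐ(ω); the over-damped medium obeys
γṡ = −Ks + Σⱼ α₁aⱼ + ξ, so its own response is R̃ₛ(ω) = 1/(K − iγω).
Writing R̃ = |R̃|e^{−iφ}, collective oscillations of N identical cells start
when the closed signal loop first becomes self-sustaining:

* **phase matching** — φₐ(ω₀) = −φₛ(ω₀): the cells' phase *lead* cancels
  the medium's phase *lag* at the selected frequency, and
* **gain** — |R̃ₐ(ω₀)R̃ₛ(ω₀)| = (α₁N₀)⁻¹, defining the critical density N₀
  and the dimensionless coupling N̄₀ = N₀α₁α₂.

A dissipative medium always lags (φₛ ∈ (−π/2, 0)), so cells must *lead*.
Cells that **adapt** — whose activity returns, up to a small adaptation
error ε, to baseline after a step stimulus — necessarily lead at low
frequency: by the Kramers–Krönig relation a small zero-frequency response
forces the imaginary part R̃ₐ″ to change sign at a frequency ω\*, creating
an *active band* (R̃ₐ″ < 0) in which the cell pumps energy into the signal
at rate Ẇ = −α₁ω R̃ₐ″(ω)⟨|s̃(ω)|²⟩ and the equilibrium
fluctuation–dissipation relation 2T R̃″ = ωC̃ is violated.

The package implements this machinery end to end: response-spectrum
containers with fixed conventions, Kramers–Krönig reconstruction, energy
flux and FDT diagnostics, the onset solver, Rcpp-backed stochastic
simulators for an adaptive two-node circuit with cubic nonlinearity and for
coupled FitzHugh–Nagumo populations, density sweeps with onset/death
detection and Hopf-exponent fits, a reduced model of yeast glycolysis
coupled through acetaldehyde (including *inverse* DQS, oscillation
quenching at high density), and a fixture generator for the
step-response → kernel → spectrum → onset data pipeline.

## Worked example: from a step response to an onset prediction

```r
library(dqskit)

# synthetic single-cell step response: adaptive, with the response-phase
# sign change engineered at omega* = 1 min^-1 (adaptation error 0.1)
st <- generate_step_fixture("adaptive_step", epsilon = 0.1, omega_star = 1,
                            dt = 0.05, duration = 60)

# full pipeline at fast signal clearance (tau_s -> 0)
onset_from_step(st, signal_model(gamma = 1e-4, K = 1, alpha1 = 1))
#> <dqs_onset> omega_o=0.999198 (period 6.28823), N_o=1.09975, Nbar_o=1.09975, 1 root(s)

# slower signal clearance lengthens the period
onset_from_step(st, signal_model(gamma = 0.35, K = 1, alpha1 = 1))$period
#> [1] 7.459349
```

The onset period at fast clearance, ~6.29 min, is the theoretical lower
bound 2π/ω\*; at τₛ = 0.35 min the phase-matching point slides down the
active band and the period lengthens.

Analytic-versus-simulation closure for the coupled cubic circuit
(τₐ = τ_y = γ = K = c₃ = 1, ε = 0.1, α₁ = α₂ = 0.5, T = 0.01):

```r
p   <- cubic_params(epsilon = 0.1, alpha2 = 0.5, T = 0.01)
sig <- signal_model(gamma = 1, K = 1, alpha1 = 0.5)
onset_point(cubic_response(p, seq(0.004, 6, length.out = 3000)), sig,
            alpha2 = p$alpha2)
#> <dqs_onset> omega_o=0.663325 (period 9.47226), N_o=7.04, Nbar_o=1.76, 1 root(s)
```

A density sweep of the simulated population (`density_sweep()`) detects
onset at N̄ ≈ 1.85 with frequency ≈ 0.65 — within 10% of the prediction —
and the oscillation amplitude above onset grows as (N̄ − N̄₀)^β with
β = 0.5 ± 0.1 (`fit_hopf_exponent()`), the supercritical Hopf signature.

## Command line

A thin CLI wraps the pipeline (`inst/cli/dqs`):

```sh
Rscript inst/cli/dqs fixtures --kind adaptive_step --omega-star 1 --seed 7 --out fx/
Rscript inst/cli/dqs analyze-step --step fx/step.csv --tau-s 1e-4 --out onset.json
```

All runs write JSON provenance records; exit codes distinguish
configuration (2) from numerical (3) failures.
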