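# stochimm

Deterministic and stochastic models of autoimmune T-cell dynamics.

## The scientific problem

Autoimmune disease can flare, regress and relapse even in genetically
identical organisms under identical immunisation protocols — as seen in
experimental autoimmune uveoretinitis (EAU), a murine model of inflammatory
eye disease in which per-eye CD4⁺ T-cell counts show a quiet prodromal
phase, a peak of retinal infiltration between two and three weeks
post-immunisation, and decaying oscillations thereafter.  Averages across
eyes decay smoothly, but *individual* eyes keep oscillating.  That contrast
is the signature of demographic stochasticity: each eye is one realisation
of a stochastic process whose mean behaves like the deterministic model.

`stochimm` implements a five-compartment model of this process for
modellers and quantitative immunologists, at every level of description:

- **ODE (mean field).**  Healthy host cells `S` grow logistically (rate
  `r`, capacity `N`) and are killed by autoreactive T cells `Taut` at rate
  `μa`.  Naive T cells `Tin` arrive at rate `λin` and are activated by
  antigen from `S` at rate `α`; a fraction `p` becomes regulatory (`Treg`,
  also produced at `λr`), the rest autoreactive.  Tregs suppress `Taut` at
  rate `δ`; autoreactive cells secrete a cytokine `I` (rate `σ`, cleared at
  `di`) that feeds back on proliferation of `Treg` and `Taut` at rates `ρ1`
  and `ρ2`:

  ```
  dS/dt    = r S (1 − S/N) − μa Taut S
  dTin/dt  = λin − din Tin − α Tin S
  dTreg/dt = λr − dr Treg + α p Tin S + ρ1 Treg I
  dTaut/dt = α (1−p) Tin S − da Taut − δ Treg Taut + ρ2 Taut I
  dI/dt    = σ Taut − di I
  ```

  The package finds and classifies all steady states: the cell-free state
  `E1 = (0, λin/din, λr/dr, 0, 0)` (always unstable — eigenvalue `r`), the
  cell-free autoimmune states `E2` (closed-form quadratic in `Treg*`, always
  carrying the eigenvalue `−din`), and the positive interior state `E*`
  (controlled low-level autoreactivity), with stability maps over
  `(ρ1, ρ2)`.

- **CTMC (exact).**  The equivalent continuous-time Markov chain with 12
  transition channels, sampled exactly by the Gillespie direct method.

- **Itô SDE (efficient).**  `dY = μ(Y) dt + H(Y) dW` with a 5×7
  block-diagonal diffusion factor over seven independent Wiener processes,
  satisfying `H Hᵀ = Σ ν νᵀ q` (the transition covariance), integrated by
  Euler–Maruyama, with seeded ensembles.

- **LNA (analytic fluctuations).**  The linear-noise approximation around a
  stable `E*`: the stationary covariance `C` solves the Lyapunov equation
  `A C + C Aᵀ + B = 0` with `A` the Jacobian and `B = Σ ν νᵀ q` at `E*`.
  `Var(Taut) = C[Taut, Taut]` quantifies the stochastic oscillations and is
  mapped over `(ρ1, ρ2, δ)`.

- **Synthetic EAU data.**  A seeded generator of per-eye CD4⁺ count tables
  (prodrome, peak, damped post-peak oscillation, multiplicative log-normal
  inter-eye noise; 10 replicate eyes for B10.RIII, 8 for C57BL/6) so the
  model-to-data comparison runs with no external data, plus a
  scale-and-offset fit exploiting the model's exact population-scaling
  invariance (`Tin, Treg, Taut → k·`, `μa, σ, δ → /k`, `λin, λr → k·`).

The headline stochastic phenomenon is **coherence resonance (stochastic
amplification)**: in parameter regions where `E*` is stable, the ODE damps
onto `E*` while single SDE/CTMC realisations sustain quasi-regular
oscillations indefinitely — a single course of disease can oscillate
forever even though the "average patient" settles down.

## Worked example

```r
library(stochimm)
p <- model_params()                 # reference rates; rho1 = 0.0022, rho2 = 4.4e-4

ss <- find_interior_steady_state(p)
ss
#> <steady state E_star: stable>
#>           S         Tin        Treg        Taut           I
#>    8334.650    7714.110 2466560.000     265.122     353.495
#> eigenvalues:
#> [1] -0.4107+0.2831i -0.4107-0.2831i -1.4760+0.0000i -3.6560+1.0260i
#> [5] -3.6560-1.0260i

stationary_covariance(p)
#> <linear-noise stationary covariance at E*>
#>   E*: 8334.6, 7714.1, 2466600, 265.12, 353.5
#>   Var(Taut) = 374.23  (sd = 19.345 cells)

tr_ode <- simulate_ode(p, default_init(), seq(0, 100, by = 0.02))
oscillation_metrics(tr_ode, "Taut", window = c(10, 100))
#> <oscillation metrics: f = 0.01097 /day, decay = NA /day, 0 peaks, amplitude ratio 1.1e-08>

tr_sde <- em_simulate(p, default_init(), seq(0, 100, by = 1e-3), seed = 1)
oscillation_metrics(tr_sde, "Taut", window = c(10, 100))
#> <oscillation metrics: f = 0.01372 /day, decay = -0.007253 /day, 123 peaks, amplitude ratio 1.02>
```

Reading: `E*` is stable (all eigenvalues have negative real part) with a
damped oscillatory pair `−0.41 ± 0.28i`, so the deterministic trajectory's
oscillation amplitude collapses (ratio ~1e-8 between the second and first
half of the window).  The single stochastic path keeps oscillating around
`Taut* ≈ 265` with amplitude ratio ≈ 1 — sustained stochastic oscillations
whose size (sd ≈ 19 cells) is predicted analytically by the linear-noise
variance.

Scenario-level runs (each writes CSV/JSON artifacts plus a reproducibility
manifest):

```r
run_scenario("variance-map", "out", seed = 1)   # Var(Taut) over (rho1, rho2)
run_scenario("compare", "out2", seed = 1)       # synthetic EAU counts + scale fit
```

or from a shell via the thin wrapper
`inst/scripts/run_scenario.R --scenario variance-map --out out --seed 1`.

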