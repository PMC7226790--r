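---
title: "Methods: deterministic and stochastic autoimmune T-cell dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deterministic and stochastic autoimmune T-cell dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters and how their defaults were fixed, the
numerical schemes and their tolerances, the design choices that were
genuinely open, and what the test suite does and does not establish.  All
numbers quoted here are computed by the test suite or by the code shown.

## The model

Five compartments interact in one organ: healthy somatic cells $S$, naive
T cells $T_{in}$, regulatory T cells $T_{reg}$, autoreactive T cells
$T_{aut}$, and a cytokine growth factor $I$ (an IL-2-like signal):

$$
\begin{aligned}
\dot S &= r S\left(1 - S/N\right) - \mu_a T_{aut} S\\
\dot T_{in} &= \lambda_{in} - d_{in} T_{in} - \alpha T_{in} S\\
\dot T_{reg} &= \lambda_r - d_r T_{reg} + \alpha p T_{in} S + \rho_1 T_{reg} I\\
\dot T_{aut} &= \alpha (1-p) T_{in} S - d_a T_{aut} - \delta T_{reg} T_{aut} + \rho_2 T_{aut} I\\
\dot I &= \sigma T_{aut} - d_i I
\end{aligned}
$$

Assumptions worth making explicit:

- Healthy cells grow logistically rather than by constant influx; the
  functional form of host-cell growth is known to matter for autoimmune
  dynamics, and the logistic choice makes homeostasis an emergent carrying
  capacity.
- Antibody responses are ignored; only T cells reactive to a single
  self-antigen are modelled.  Naive cells activated by antigen presented
  from healthy cells split `p : (1-p)` into regulatory and autoreactive
  fates.
- The cytokine is produced only by autoreactive cells but boosts
  proliferation of both regulatory ($\rho_1$) and autoreactive ($\rho_2$)
  cells — the tension that generates oscillatory feedback.
- All state variables are absolute counts (cells; cytokine in abundance
  units).  The system-size setting `Omega` is carried as metadata only; no
  per-volume rescaling is applied anywhere.

## Parameters

Defaults of `model_params()` (units per day unless noted):

| parameter | default | meaning |
|---|---|---|
| `r` | 2 | host-cell growth rate |
| `N` | 20000 | carrying capacity (cells) |
| `mu_a` | 4.4e-3 | killing of host cells per autoreactive cell |
| `alpha` | 4e-5 | naive activation per host cell |
| `lambda_in`, `lambda_r` | 18000, 54000 | thymic production (cells/day) |
| `d_in`, `d_r`, `d_i` | 2, 0.8, 0.6 | death/clearance rates |
| `p` | 0.4 | regulatory fraction of activated cells |
| `delta` | 2.22e-6 | Treg suppression of autoreactive cells (1/(cell day)) |
| `sigma` | 0.8 | cytokine secretion |
| `rho1`, `rho2` | 2.2e-3, 4.4e-4 | cytokine-driven proliferation (1/(unit day)) |
| `d_a` | 0.5 | autoreactive death rate (package calibration, below) |
| `d1` | `r` | linear death part of the host birth/death split |
| `Omega` | 1000 | system-size metadata |

The homeostatic levels implied by the first block are
$T_{in}^0 = \lambda_{in}/d_{in} = 9000$ and
$T_{reg}^0 = \lambda_r/d_r = 67500$.

### The open parameter `d_a` and the regime operating point

The reference rate table does not fix `d_a`, and the simulation figures
it accompanies do not state it either, so it is an exposed configuration
parameter.  The package default was fixed by a one-dimensional calibration
scan with everything else at its default.  Two findings shaped the choice:

1. At the default `(rho1, rho2) = (2.2e-3, 4.4e-4)` the interior state E*
   is **stable for every** `d_a` scanned (0.01–120; the least-damped point
   of the scan, near `d_a ≈ 6`, still has max Re eigenvalue ≈ −0.08/day at
   `delta = 4.44e-7`).  No value of `d_a` alone can produce a
   stable/unstable switch between `delta = 2.22e-6` and `4.44e-7` there.
2. That switch does exist nearby in the cytokine-proliferation plane: at
   `(rho1, rho2) = (5e-4, 8e-4)` with `d_a = 0.5`, E* is stable at
   `delta = 2.22e-6` (max Re ≈ −0.045, eigenvalues −0.045 ± 0.63i) and
   unstable at `delta = 4.44e-7` (max Re ≈ +0.10).

The default is therefore `d_a = 0.5`: it lies in the scanned interior, it
is the value used by the documented feasible example for the cell-free
autoimmune state E2, and at the package defaults it gives a damped
oscillation pair `−0.41 ± 0.28i`, i.e. a period of ≈ 22 days — the
two-to-three-week timescale on which EAU counts oscillate.  The
delta-driven regime dichotomy is exercised at the *regime operating point*
`regime_point()` (`rho1 = 5e-4`, `rho2 = 8e-4`), not at the defaults.

### Subcritical flares

Above the stability threshold the Hopf bifurcation at the operating point
is subcritical: a perturbation of E* grows into a giant flare
($T_{aut}$ transiently 100–1000× its steady level), collapses to
near-extinction and recurs — there is no small limit cycle.  Long
integrations in the unstable regime therefore overflow; the package
demonstrates "sustained" deterministic behaviour by the growth of a 0.1%
perturbation of E* over a bounded 40-day window (`run_scenario("ode-regimes")`),
where the damped regime has amplitude ratio < 0.5 and the growing regime
> 1.

## Stochastic layers

### Markov chain

The CTMC has 12 channels: host birth `q1 = b1 n1 + b2 n1²` and death
`q2 = d1 n1 + d2 n1² + mu_a n1 n4`; naive production `q3 = lambda_in` and
death `q4 = d_in n2`; activation to regulatory `q5 = alpha p n1 n2` and to
autoreactive `q6 = alpha (1-p) n1 n2`; regulatory production
`q7 = lambda_r + rho1 n3 n5` and death `q8 = d_r n3`; autoreactive
proliferation `q9 = rho2 n4 n5` and removal `q10 = (d_a + delta n3) n4`;
cytokine secretion `q11 = sigma n4` and clearance `q12 = d_i n5`.  Summing
stoichiometries against rates returns the ODE right-hand side exactly —
the consistency contract the tests enforce at random states.

Two conventions need stating:

- **Birth/death split.** Only `b1 − d1 = r` and `d2 − b2 = r/N` are fixed
  deterministically; different splits give the same mean field but
  different variances.  The package takes a logistic *birth* term and a
  linear *death* term (`b2 < 0`, `d2 = 0`) with default `d1 = r`
  (so `b1 = 2r`), and exposes `d1`.  The birth rate `b1 n + b2 n²` turns
  negative for `n1 > b1 N / r`; it is clamped at zero there to remain a
  valid rate.
- The cytokine clearance channel acts on the fifth (and only fifth)
  variable.

Sampling uses the Gillespie direct method — exponential waiting times at
the total rate, channel chosen proportionally — which is exact for the
chain.  At the full reference scale total rates are ~1e5/day, so exact
paths over long horizons are expensive; the suite exercises the sampler at
a 100×-reduced scale (`lambda_in`, `lambda_r`, `N` all divided by 100).
One statistical subtlety is documented rather than hidden: the CTMC mean
differs from the ODE by a finite-size (van Kampen) correction — for the
host compartment it is dominated by $-(r/N)\,\mathrm{Var}(n_1)$, about
−0.7 cells at the reduced scale — which is comparable to the 3-standard-
error resolution of a 500-path ensemble, so that comparison sits close to
its detection limit by construction.

### Itô SDE

The SDE `dY = μ dt + H dW` uses the channel drift and a 5×7 diffusion
factor over seven independent Wiener processes, one per birth/death pair
of a compartment plus one per conversion channel (naive→regulatory,
naive→autoreactive).  Entries are square roots of summed rates, signed so
that the conversion columns couple the source (−) and target (+) rows.
The defining contract — enforced to machine precision in the tests — is
$H H^\top = B = \sum_k \nu_k \nu_k^\top q_k$.  (A common shorthand writes
the `H` blocks as plain rate sums; the square-root form is what makes the
Itô construction reproduce the transition covariance.)

Integration is explicit Euler–Maruyama with default step `dt = 1e-3` days.
Components stepping below zero are clamped to zero — appropriate because
all rates vanish at empty populations — and the clamping frequency is
tracked, with a warning above 5% of component-steps (a symptom of too
large a step).  With the noise factor set to zero the scheme degenerates
to the explicit Euler method, which the tests verify exactly.  Ensembles
run per-path derived seeds (`seed + i − 1`, all recorded), so any single
realisation can be regenerated independently of the ensemble size.

### Linear-noise approximation

Around a stable E*, fluctuations are Gaussian with stationary covariance
$C$ solving $A C + C A^\top + B = 0$, where $A$ is the analytic Jacobian
and $B$ the transition covariance at E*.  The equation is solved by
Kronecker vectorisation.  One numerical point matters: near the
feasibility boundary $T_{reg}^*$ reaches 1e7 while suppression rates sit
at 1e-6, so the raw Kronecker matrix can be numerically singular even
though $A$ is comfortably Hurwitz.  The solver therefore balances $A$ by a
diagonal similarity first — Osborne equilibration by default, the
steady-state component magnitudes when the caller knows them — which keeps
relative residuals at ~1e-12 across the variance maps.  Variances are
reported in absolute counts; no `1/Omega` rescaling is applied, and the
monotonicity statements the tests assert (variance nondecreasing in
`rho2`, nonincreasing in `rho1`, decreasing in `delta`) are invariant to
that choice of units.

The headline cross-check ties the layers together: at the package
defaults, 500 Euler–Maruyama paths started at E* and run to 20 days (an
order of magnitude longer than the 1/0.41 ≈ 2.4-day relaxation time) give
a $T_{aut}$ variance within 3 Monte-Carlo standard errors of
$C[T_{aut}, T_{aut}] \approx 374$.

## Interior steady state and stability machinery

Every interior fixed point satisfies a closed-form reduction: given
$S \in (0, N)$, the $S$-balance fixes $T_{aut}$, then $I$, $T_{in}$ and
$T_{reg}$ follow in closed form (the $T_{reg}$ balance requires
$d_r > \rho_1 I$; beyond that boundary no interior state exists).  The
remaining scalar equation in $S$ is scanned on 2000 points for sign
changes, each bracket solved by `uniroot` (tol 1e-13) and polished by
Newton iteration on the full system to component-relative residuals below
1e-12.  Because the reduction is exhaustive, the scan enumerates *all*
interior fixed points up to its resolution; a multistart Newton fallback
from perturbed E1 states covers near-tangent root pairs, and accepts a
root as interior only if every component exceeds 1e-3 cells (plain
positivity lets Newton sneak in boundary states with $S \sim 10^{-20}$).

Stability is always decided from the numerical eigenvalues of the analytic
Jacobian with a margin of 1e-8/day; `|max Re| <` margin is labelled
`marginal`.  A printed closed-form cubic for the E2 spectrum is
dimensionally inconsistent and is not used; the two closed-form E2
eigenvalues that *are* structural — $-d_{in}$ from the naive row and
$r - \mu_a T_{aut}^*$ from the decoupled $S$ row — are asserted
numerically instead.

Map grids default to `rho1` ∈ [1e-4, 5e-3], `rho2` ∈ [1e-5, 1e-3]
(41×41 for production maps, 9×9 in the tests); the published maps do not
print their axis ranges, so these are package conventions chosen to
straddle the feasibility and stability boundaries.

## Oscillation metrics

- **Dominant frequency**: periodogram of the mean-removed, linearly
  detrended series, zero-padded 8× for resolution.  A stable-regime SDE
  path at the regime operating point peaks within 10% of the linear
  resonance frequency $|\mathrm{Im}\,\lambda|/2\pi \approx 0.1$/day; at
  the heavily damped default point the fluctuation spectrum is
  quasi-Lorentzian and the peak sits below the resonance, which is why the
  resonance-location test runs at the operating point.
- **Decay rate**: local maxima with prominence ≥ 5% of the series range;
  exponential fit of peak height above the asymptotic baseline (mean of
  the final quarter).  Validated on `exp(-0.1 t) cos(2π 0.5 t)` to 5%.
- **Amplitude ratio**: half the value range in the second half of the
  window divided by the same in the first half.  **Sustained oscillation
  is operationalised as ratio ≥ 0.5** — no published threshold exists for
  the "above-threshold oscillations = autoimmunity" notion, so this is a
  documented package convention; the regimes it separates sit far apart
  (damped ODE ≈ 1e-8, stochastic paths ≈ 1).

## Scaling invariance and data fitting

The map $T \mapsto k T$ on the three T-cell compartments with
`mu_a, sigma, delta → /k` and `lambda_in, lambda_r → k·` leaves the
dynamics exactly invariant (`S`, `I`, `rho1`, `rho2` and all death rates
unchanged); the tests verify equivariance of the vector field
algebraically at random points and of full trajectories to integrator
tolerance for k ∈ {1, 2, 10}.  Because of this invariance the absolute
T-cell scale is not identifiable from count data, which is a feature:
`fit_scale_to_counts()` least-squares fits the scale `k` and a day offset
(experimental time is measured from immunisation; model time from response
onset) of a model curve to per-day mean counts — closed-form `k` per
offset, grid scan plus Nelder–Mead polish.  On noiseless counts
manufactured from the model's own curve it recovers `k = 3` to 0.005% and
a 5-day offset to 0.0003 days; the acceptance threshold (1%, 0.25 days)
leaves room for integer rounding of counts.

## Synthetic EAU counts

The generator emulates the statistical structure of per-eye CD4⁺ counts:

- **Mean curve**: logistic rise (centred between prodrome end, day 10, and
  peak day 17; slope 1.2 days) times a post-peak damped cosine relaxing to
  a 35% plateau (frequency 0.07/day, decay 0.08/day), clamped at zero.
  This is the simplest family with the right phenomenology — prodrome,
  peak in days 14–21, regulated decaying oscillation — and it can be
  swapped for a model-driven $T_{aut}$ curve.
- **Noise**: per-eye, per-day multiplicative log-normal (sdlog 0.3),
  rounded to integers.  Counts are positive and right-skewed, and the
  across-eye spread grows with the mean, matching the fan-shaped
  uncertainty bands of such experiments; the spread scales linearly with
  the noise parameter to within the log-normal's 2–5% convexity.
- **Design**: 10 eyes for B10.RIII (peak mean 20000), 8 for C57BL/6 (peak
  mean 12000 — the milder of the two models); sampling days
  0, 7, 10, 12, 14, 17, 21, 28, 35, 49.  The source experiments print
  neither their exact schedule nor absolute scales; these are documented
  conventions.

What passing tests show: the pipeline — generation, CSV round-trip,
per-day aggregation, scale-and-offset fitting, band statistics — is
correct on data with the right shape, skew and replication.  What they do
not show: anything about flow-cytometry measurement error, gating,
inter-batch effects, or the biological mechanism of the prodrome (the
dynamic model itself starts at response onset and has no delayed phase —
a known limitation of this model family).

## Problem sizes and tolerances used by the suite

Chosen as the package's own desk-scale conventions: ODE tolerances
rtol = atol = 1e-8 (1e-10 for invariance checks); EM step 1e-3 days;
LNA-vs-ensemble at 500 paths × 20 days; coherence-resonance and band
checks on single 100–200-day paths; SSA mean-field at 100× reduced scale,
500 paths to t = 1; variance maps at 9×9.  The full suite runs in about a
minute on one core.

## Known limitations

- No prodromal phase in the dynamic model (see above); the generator
  imposes it phenomenologically.
- The unstable regime's flares make long deterministic integrations there
  diverge; regime classification relies on eigenvalues and short-window
  growth, not long unstable trajectories.
- Euler–Maruyama is weak order 1 with zero-clamping at the boundary; at
  the default step the clamp rate is far below the warning threshold, but
  very small compartments (e.g. early $T_{aut}$) are better served by the
  exact sampler at reduced scale.
- Tau-leaping, master-equation solvers, Hopf normal-form analysis and
  time-delay variants are out of scope.
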