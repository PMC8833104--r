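---
title: "Information in TCR-pMHC binding fluctuations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information in TCR-pMHC binding fluctuations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrfluct)
```

## The reversible binding model

Within the 2D contact area `ν` (μm²) between a T cell and an antigen
presenting cell, pMHC ligands `L` and TCRs `R` bind reversibly,

$$ L + R \;\underset{k_{off}}{\overset{k_{on}/\nu}{\rightleftharpoons}}\; B, $$

with `k_on/ν` the binding propensity per reactant pair (s⁻¹) and
`k_off` the unbinding rate (s⁻¹). With totals `L_max` and `R_max` the
complex number `B` lives on `0 … B_max`, `B_max = min(L_max, R_max)`,
and detailed balance gives the exact stationary law

$$ p(B) \propto \binom{B_{max}}{B}\binom{U_{max}}{B} K_d^{-B}\, B!,
   \qquad K_d = \frac{\nu k_{off}}{k_{on}}, $$

with `U_max = max(L_max, R_max)`. `K_d` is kept in dimensionless
copy-number form, `k_off / (k_on/ν)`, because that is the form that
multiplies integer copy numbers in the stationary weights; the physical
μm-based quantity appears only in the unit conversions
(`counts_from_density()`, `kd_from_effective_affinity()`).

Key assumption: the T cell responds on a slower time scale than the
binding dynamics, so all information measures are properties of the
*stationary* distribution.

### Information measures

* Shannon entropy `H(B) = −Σ p(i) log₂ p(i)` (bits): information per
  binding/unbinding event. Depends on `(L_max, R_max, K_d)` only.
* Entropy rate `H′(B) = 2 k_off ⟨B⟩ H(B)` (bits/s): at stationarity
  binding and unbinding events each occur at rate `k_off ⟨B⟩`, so
  `2 k_off ⟨B⟩` is the mean event rate, and `H′` is information per
  second. This is a deliberate, model-specific definition (mean event
  rate × stationary entropy), not the generic entropy rate of a
  continuous-time Markov chain. It distinguishes fast from slow
  kinetics at equal affinity: `H′` is exactly linear in `k_off` at
  fixed `K_d`.
* Variance rate `Var′(B) = 2 k_off ⟨B⟩ Var(B)`: same premultiplier,
  with the variance in place of the entropy. No information-theoretic
  meaning, but analytically convenient and empirically parallel to
  `H′`.
* Adhesion probability `P_a = 1 − 1/Z = 1 − p(0)`: the quantity fitted
  by adhesion frequency assays, and the bridge between the model and
  measured 2D affinities.

Both entropy and entropy rate are *biphasic* in the binding rate:
fluctuations vanish when binding is very weak (nothing associates) or
very strong (nothing dissociates) and peak at intermediate affinity.

## The five-reaction activation model

Signal generation couples three mechanisms — serial engagement,
reversible TCR conformational change, and TCR aggregation — in the
minimal reaction set

| reaction | propensity | meaning |
|---|---|---|
| `L + R_I → B` | `(k_on/ν) L R_I` | inactive TCR binds ligand |
| `B → L + R_A` | `k_off B` | unbinding leaves the TCR active |
| `L + R_A → B` | `(k_on/ν) L R_A` | active TCR rebinds at the same rate |
| `R_A → R_I` | `k_off R_A` | active TCR reverts |
| `R_A + B → R_A + B + S` | `k_off R_A B` | aggregation: signal emission |

Initial condition `R_I(0) = R_max`, everything else zero. Three
modelling conventions deserve note, since the reaction set alone does
not fix them:

* The signal propensity acts on raw copy numbers, `k_off R_A B`, with
  no `ν` division. This is the convention under which the stationary
  signalling rate `⟨Ṡ⟩ = k_off ⟨R_A B⟩` factorizes (approximately) to
  `k_off ⟨R_A⟩⟨B⟩ ≈ k_off Var(B) ⟨B⟩ = ½ Var′(B)`; a density
  formulation would only rescale the y-axis of dose–response curves.
* Unbinding always releases the TCR in the active state, whether the
  complex formed from `R_I` or `R_A`: both binding channels map to the
  same species `B`, so bound-TCR provenance is not tracked.
* Reversion uses the same constant `k_off` as unbinding (an active TCR
  rebinds at the same rate as an inactive one). A separate `k_revert`
  can be supplied through `signalling_config()` for sensitivity
  analyses, but the default model has a single deactivation constant,
  and reversion only applies to *free* active TCRs — `R_A` is a free
  species here.

The marginal dynamics of `B` (and of `R = R_I + R_A`) are identical in
law to the plain reversible-binding system, so all the analytic
stationary machinery above applies unchanged to this model; the test
suite verifies this by comparing holding-time-weighted occupancy
distributions from the two simulators.

The factorization `⟨R_A B⟩ ≈ ⟨R_A⟩⟨B⟩` and the identity
`⟨R_A⟩ ≈ Var(B)` are *never assumed* by the simulator — they are tested
approximations. The suite solves the stationary chemical master
equation exactly (a dense linear solve over the `(B, R_A)` state
space) as an independent oracle. That solve shows the identity is
excellent in ligand excess (`L_max ≫ R_max`: agreement to within 1%)
but genuinely breaks when both copy numbers are small and binding is
strong — at `L_max = R_max = 10`, `K_d = 10` the exact ratio
`⟨R_A⟩/Var(B)` is 1.35. The simulator reproduces the exact value there;
it is the approximation, not the code, that fails, and tests at that
corner therefore compare the simulator to the exact master-equation
solution rather than to the approximation.

## Parametrization

Defaults come from adhesion-frequency-assay measurements at 37 °C:

| quantity | value | unit |
|---|---|---|
| contact area `ν` | 10⁻¹ | μm² |
| TCR density `R_max/ν` | 10² | μm⁻² → `R_max ≈ 10` |
| pMHC density `L_max/ν` | 10¹–10³ | μm⁻² → `L_max ∈ [1, 100]` |
| effective 2D affinity `ν²/K_d` | 10⁻⁶–10⁻³ | μm⁴ → `K_d ∈ [10, 10⁴]` |
| off rate `k_off` | 10⁰–10¹ | s⁻¹ |

Dose sweeps extend `L_max` one order of magnitude beyond the measured
range (to 10³), since dose–response experiments routinely span wider
dose ranges; `counts_from_density()` returns real values and rounding
(to the nearest integer, minimum 1) happens only at the simulation
boundary, because the measured densities are order-of-magnitude
estimates. Where a default had to be invented — `parse_config()` needs
a complete parameter set for an empty configuration — we chose
`L_max = 1000` (the value used to characterize the rate grid) and
`K_d = 100` (the geometric middle of the measured affinity range).

## Simulation protocol and numerical choices

* **SSA.** Gillespie's direct method, exact, implemented in C++ with
  R's RNG so `set.seed()` makes trajectories bit-reproducible.
  Occupancy averages are holding-time weighted (each state weighted by
  the exponential duration it is held), since per-event counting is
  biased.
* **Signalling-rate protocol.** Each replicate runs until the first of
  `S > S_stop` (default 10⁴), the next event falling past `t_stop`
  (default 10⁴ s), or total propensity zero; the rate is `S(t*)/t*`
  (defined as 0 when no time elapses) and the estimate averages
  `n_reps = 10` replicates, replicate `i` seeded `seed + i − 1`.
  The test suite uses `S_stop = t_stop = 10³` and shrinks some grids
  (e.g. 7 doses rather than 13 for the simulated dose sweep); these
  sizes give Monte-Carlo errors comfortably inside the tolerances
  being asserted while keeping the default run quick.
* **Log-space stationary weights.** `a(B)` overflows double precision
  for `U_max ≳ 10³` at small `K_d`, so all weights use `lchoose`/
  `lgamma` and the partition function uses log-sum-exp. `0 log 0 := 0`
  in the entropy; probabilities below 10⁻³⁰⁰ are treated as 0.
  `k_on/ν = 0` is a supported limiting case yielding `p(0) = 1`.
* **Adhesion probability.** Computed as `-expm1(-log Z)`, which equals
  `1 − p(0)` exactly since `a(0) = 1`; this avoids cancellation when
  `Z` is close to 1.
* **Mean field.** `deSolve::ode` (lsoda, rtol = atol = 10⁻⁸) on the
  mass-action equations matching the five propensities. At large copy
  numbers its equilibrium `B` solves
  `(L_max − B)(R_max − B) = K_d B` and agrees with the stochastic
  stationary mean to a few percent; late-time `dS/dt` is the
  deterministic signalling rate.
* **Bell-shape classification.** A dose–response row is "bell-shaped"
  when its maximum is strictly interior to the dose axis *and* exceeds
  both endpoint responses by more than 5% — the margin guards against
  float-level noise on flat curves. Optimal-dose ties break toward the
  smaller dose; optimal-affinity ties break toward the larger `K_d`
  (weaker binding).

## What the sweeps emulate — and what they do not

The dose grids emulate titration experiments: `L_max` plays the role of
antigen dose and `K_d` the ligand panel's 2D affinities. Passing shape
tests show that the *model* produces bell-shaped curves for
high-affinity ligands, affinity-insensitive peak amplitudes, and
largest low-dose responses for the strongest physiological binder.
They do not validate the model against any particular measured
dataset: real dose–response data report 3D affinities, cytokine
readouts and cell-population heterogeneity, none of which are modelled
here, and 3D↔2D kinetic conversion is deliberately out of scope. The
shape classification is also axis-dependent at the crossover affinity
(`K_d ≈ 10³` with doses capped at 10³): a bell whose peak sits beyond
the dose axis is reported as "boundary". The classification is only
compared across conditions on a fixed axis, at affinities far from the
crossover.

## Known limitations

* No spatial or reaction–diffusion detail: aggregation is a single
  mass-action reaction.
* No time-dependent (pre-stationary) adhesion probability.
* No kinetic proof-reading; the model has no minimum dwell-time
  requirement.
* The `⟨R_A⟩ ≈ Var(B)` and `⟨Ṡ⟩ ≈ ½ Var′(B)` approximations degrade
  outside ligand excess (see above); the package reports exact or
  simulated values and never substitutes the approximation.
* One supported alternative activation model family (requiring two
  ligands for signalling) is not implemented.
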