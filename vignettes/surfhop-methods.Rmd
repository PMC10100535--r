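---
title: "Methods: surface hopping, embedding and lifetime statistics in surfhop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface hopping, embedding and lifetime statistics in surfhop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfhop)
```

This vignette is the package's scientific account of what it computes,
which approximations it makes, and which numerical choices were taken
where more than one defensible option exists.

## 1. Scope and model

`surfhop` implements the standard nonadiabatic-dynamics protocol for
excited-state lifetimes — ground-state thermal sampling, vertical
excitation of a trajectory swarm, Tully fewest-switches surface hopping
(FSSH), occupancy statistics, sequential kinetic fitting and subset error
extrapolation — on **analytic model electronic structure** rather than a
quantum-chemistry backend.

The electronic models are diabatic Hamiltonians

$$V_{ii}(R) = e_i + a_i\cdot R + \tfrac12 k_i (R-r_{0,i})^2,\qquad
  V_{ij}(R) = A_{ij}\exp\!\big[-\textstyle\sum_d (R_d-r_{c,d})^2/w_d^2\big],$$

diagonalized on the fly. Because the diabatic matrix is analytic, the
adiabatic energies, gradients (Hellmann–Feynman) and nonadiabatic coupling
vectors

$$d_{ba} = \frac{\langle b|\nabla V|a\rangle}{E_a - E_b}$$

are exact, so every downstream algorithm can be validated against
finite-difference and ODE oracles at tight tolerance. The default
three-state model (`make_avoided_crossing_model(3)`) places an S2/S1 seam
and an S1/S0 seam at different geometries, producing the sequential decay
the kinetics layer targets. Diabatic oscillator strengths are fixed per
state and rotated into the adiabatic basis, so the selection filter sees a
smoothly varying adiabatic strength.

Units everywhere at the interfaces: eV, Å, fs, amu. States are 0-based
(S0 = 0). Internally, eV is converted to mechanical units with
`0.009648533212331` amu Å² fs⁻² per eV; ħ = 0.6582119569 eV fs;
k_B = 8.617333262 × 10⁻⁵ eV/K (`surfhop_constants()`).

### What the surrogate bath emulates — and what it does not

`make_solvent_bath()` packs point particles (default mass 18 amu,
alternating ±0.4 charges) at liquid-water number density around the solute
with a minimum-distance rejection criterion and Maxwell–Boltzmann
velocities. `bath_low_engine()` gives them a flat-bottom confinement, a
pairwise Gaussian repulsion and a charge-weighted Gaussian coupling to the
solute sites, all with analytic gradients. This reproduces the *roles* the
solvent plays in the protocol — thermal noise through the thermostat,
energy exchange, a low-level force field entering the subtractive
combination — but it is not water: there are no hydrogen bonds, no
long-range electrostatics, and no electrostatic polarization of the
excited states (see mechanical embedding below).

## 2. QM/MM embedding

The coupling is subtractive (ONIOM-style):

$$E = E^{\text{low}}(\text{full}) - E^{\text{low}}(\text{QM}) +
     E^{\text{high}}(\text{QM}),$$

with the gradient combined the same way
(`subtractive_energy_and_gradient()`). Engines are closures
`function(positions) -> list(energy, gradient)` that must be evaluable on
both the full coordinate vector and the QM subvector; the bath engine
returns exactly zero for QM-only input, which makes vacuum a strict
special case and lets two identities be tested at machine precision
(identical high/low engines cancel; a zero low engine reduces to the bare
QM model).

**Design decision — mechanical embedding.** The charges enter only the
low-level (MM) energy; the model Hamiltonian is not polarized by the bath.
Electrostatic embedding would require a field-dependent electronic model,
which would break the exactness of the analytic oracles that the test
suite is built on. The bath therefore shifts dynamics only through forces
and thermal noise, not through state-energy fluctuations.

## 3. Nuclear dynamics

Velocity Verlet with a cached force evaluation (one engine call per
step). The Andersen thermostat resamples Maxwell–Boltzmann velocities
with per-DOF collision probability `1 − exp(−ν Δt)` and is **restricted to
solvent DOFs**: it refuses masks touching the QM region, so the solute's
microcanonical dynamics — and the energy bookkeeping of surface hopping —
are never corrupted by the thermostat. Defaults: ground-state sampling
step 0.5 fs, hopping step 0.1 fs, 298 K, ν = 0.01 fs⁻¹.

Initial conditions are snapshots of the ground-state trajectory filtered
by an excitation-energy window and a minimum oscillator strength
(`select_initial_conditions()`), mimicking a vertical-excitation
window.

## 4. The FSSH engine

Amplitudes follow

$$i\hbar\,\dot c_k = \sum_j c_j\,(H_{kj} - i\hbar\,\sigma_{kj}),
\qquad \sigma_{kj} = \dot R\cdot d_{kj}.$$

**Design decision — coupling convention.** The package follows Tully's
index convention for $\sigma_{kj}$ and the hop probability

$$g_{a\to b} = \max\!\Big(0,\; \frac{2\,\Delta t\,
  \mathrm{Re}(c_b c_a^{*}\,\sigma_{ab})}{|c_a|^2}\Big),$$

clamped so the total per-step probability never exceeds 1. Since
$\sigma$ is antisymmetric, the alternative index order differs only by a
sign that must be kept consistent between the amplitude equation and the
hop formula; tests pin the implemented combination against a
hand-evaluated case and against hopping statistics.

Numerical choices:

* **Exact unitary substeps.** Each nuclear step is divided into
  `n_substeps` (default 20) electronic substeps; on each, the effective
  Hamiltonian $\mathrm{diag}(E) - i\hbar\sigma$ (linearly interpolated
  across the nuclear step, midpoint value per substep) is exponentiated
  exactly — analytically via a Pauli decomposition for two states, by
  complex eigendecomposition for three. Norm conservation is therefore at
  rounding level; drift beyond 1e-10 triggers substep doubling, beyond
  1e-8 a counted renormalization, beyond 1e-4 an abort. The acceptance
  suite requires zero renormalizations on a real trajectory.
* **NAC sign continuity.** Eigenvector gauge is arbitrary per geometry;
  coupling vectors are sign-aligned with the previous step by dot
  product, so $\sigma(t)$ is continuous along the trajectory.
* **Degeneracy protocol.** Gaps below 1e-10 eV are flagged, couplings set
  to `NA`, and the previous step's couplings are reused for that step
  rather than dividing by a vanishing gap.
* **Hops.** An accepted hop rescales velocities along the nonadiabatic
  coupling vector by solving the energy-conservation quadratic (smaller
  |γ| root), conserving total energy to better than 1e-8 eV. Frustrated
  hops (no real root) leave velocities unchanged by default; velocity
  reversal along $d$ is available via `frustrated_reversal = TRUE`.
  Optional energy-based decoherence damping (`decoherence = "edc"`) is
  off by default.

## 5. Occupancies, kinetics, and error bars

`normalized_occupancies()` converts a swarm into exact step-function
fractions on a time grid (default 20001 points); a state is occupied
strictly *before* its hop time (right-continuous curves). The partition
of unity $s_2+s_1+s_0=1$ holds exactly by construction.

The kinetic model is the **sequential two-step first-order decay**

$$\dot S_2 = -S_2/\tau_2,\quad \dot S_1 = S_2/\tau_2 - S_1/\tau_1,\quad
  S_0 = 1 - S_1 - S_2,\qquad S_2(0)=1,$$

with the closed-form solution implemented directly (including the
equal-lifetime limit $(t/\tau)e^{-t/\tau}$, switched on at relative gap
1e-8). **Design decision:** this sequential form — no direct S2 → S0
channel — matches the three-state model's geometry of consecutive seams;
two-state swarms fall back to a single-exponential fit with
`tau2_fs = NA`, and a swarm showing no decay at all reports an infinite
lifetime rather than a fitting error.

Fitting is joint unweighted least squares on $s_2$ and $s_1$ ($s_0$ is
redundant) with Levenberg–Marquardt (`minpack.lm::nls.lm`) on
log-lifetimes for positivity; starting values are deterministic 1/e
crossing times, so fits are reproducible without tuning.

**Error bars** come from reshuffled subsets: the swarm is split into
halves, thirds, … while more than `min_subset` (default 30) trajectories
remain per part, each part refitted, the spread across parts recorded,
reshuffled `n_reshuffles` (default 10) times and averaged, and the
per-level spreads extrapolated **linearly in 1/N** to the full swarm size
(floored at zero). A `1/sqrt(N)` abscissa — the conventional
standard-error scaling — is available via `abscissa = "1/sqrtN"`; the
1/N form is the default because the per-level spreads are measured at few,
closely spaced N values where the linear-in-1/N fit is better
conditioned.

Problem sizes used throughout validation: swarms of 40–190 trajectories,
horizons of 150 fs – 20 ps, grids of 2001–20001 points; a full FSSH step
costs well under a millisecond on the default models.

## 6. Pipeline and reproducibility

`run_pipeline()` derives independent child seeds for every stage (bath,
sampling, selection, each trajectory) from a single master seed via a
deterministic string hash, so runs are byte-identical for equal
configurations and fully decorrelated across stages. Artifacts are plain
text: `populations.tsv`, `fit.tsv`, `manifest.yaml` (configuration and
seed record), optional extended-XYZ trajectories.

## 7. Limitations

* FSSH itself is approximate: without decoherence corrections, ensemble
  surface populations and mean electronic populations
  $\langle|c_a|^2\rangle$ need not coincide (`swarm_consistency()`
  tabulates both; nothing asserts their equality).
* The kinetic model describes the swarm only on average; on models with a
  single localized seam, hopping is synchronized with seam passages and
  the first-order fit has a visibly nonzero residual.
* Mechanical embedding: no electrostatic polarization of state energies
  by the bath, and the bath is a structureless surrogate (Section 1).
* The analytic models have 1–2 nuclear DOFs by design; the algorithms are
  dimension-generic, but no claims are made about performance at
  condensed-phase dimensionality.
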