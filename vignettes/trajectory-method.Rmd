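---
title: "Trajectory-method cross sections and mobilities: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-method cross sections and mobilities: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmob)
```

## What is being modeled

A drift-tube ion mobility spectrometer measures how fast an ion swarm moves
through a neutral gas under a weak field. In the low-field limit the
mobility K is set by one molecular quantity, the orientation- and
energy-averaged momentum-transfer collision cross section Ω, through the
Mason–Schamp relation. `trajmob` computes Ω by the Trajectory Method: a
drift-gas probe is scattered classically off the rigid ion, the deflection
angle χ between incoming and outgoing asymptotes is recorded, and

Ω = ⟨ ∫ 2πb (1 − cos χ) db ⟩

is averaged over ion orientations and the Maxwell–Boltzmann distribution of
relative speeds (weight g⁵ e^(−μg²/2k_BT)). The collisions are elastic by
construction: the ion is held rigid, the gas is a structureless probe (or a
rigid two-site N₂), and the interaction potential is conservative.

The pipeline around the core is: charged-geometry input (or template
builders), potential and forces, trajectory integration, the averaged cross
section, Mason–Schamp mobility, drift-time conversion, the
Langevin/Blanc's-law correction from nitrogen to air, and mean-unsigned-error
scoring against packaged reference tables.

## The interaction potential

Between each ion atom i and each gas Lennard-Jones site the potential
contributes 4ε_i[(σ_i/r)¹² − (σ_i/r)⁶]; at the gas center the ion's partial
charges produce a field E and the induced-dipole term −(α/2)|E|²; the
two-site N₂ model adds three point charges (−0.4825 e on each nitrogen,
+0.965 e at the bond center, sites 1.10 Å apart) that represent the N₂
quadrupole interacting with the ion's charge distribution. Forces are
analytic gradients, unit-tested against central finite differences at
1 × 10⁻⁵ relative.

Parameter choices that matter:

* **ε, σ per ion element** (meV, Å): stored per ion-element–gas pair, the
  way such tables are published for nitrogen-gas trajectory codes, with
  physically informed defaults for H, C, N, O (ε ≈ 1.2–5 meV,
  σ ≈ 2.4–3.6 Å). Elements outside the table raise an error rather than
  receiving silent defaults, and the whole gas model can be replaced from a
  YAML/JSON config (`read_gas_config()`).
* **α = 1.710 Å³** for N₂, acting at the molecular center.
* **Two gas fidelities**: `"N2"` (two LJ sites + quadrupole charges,
  orientation frozen per trajectory after isotropic sampling) and
  `"N2-iso"` (one LJ site, no quadrupole), the default for desk-scale runs.
  The isotropic model keeps the probe state six-dimensional and is several
  times cheaper; the quadrupole matters most for strongly localized
  charges.

## Trajectory integration

The equivalent one-body problem (reduced mass μ) is integrated with an
adaptive Cash–Karp 4th/5th-order Runge–Kutta stepper. Numerical contracts:

* **Asymptote handling**: each trajectory starts and stops where
  |V| ≤ 10⁻³ × (½μg²) (`start_vfrac`), chosen per trajectory, so no fixed
  box truncates the r⁻⁴ tail.
* **Energy conservation**: a trajectory is accepted only if the relative
  total-energy drift is ≤ 10⁻³ (`energy_tol`); otherwise the local error
  tolerance is tightened tenfold and the trajectory re-run (up to three
  retries) before a non-conservation error is raised.
* **Guard radius**: approaches below 0.2 Å of any atom–site pair abort with
  a near-singularity error instead of silently stepping through the
  divergence.
* **Trapped orbits**: the attractive r⁻⁴ tail can capture slow probes into
  long-lived orbits. Trajectories that exhaust the step cap are counted and
  contribute the isotropic-scattering expectation 1 − cos χ = 1; if more
  than 1% of trajectories in a run are trapped the run errors out. This
  behavior is explicit because silent handling of capture would bias the
  low-energy part of the average.

The deflection oracle `deflection_integral_oracle()` — the classical
central-field quadrature χ = π − 2b ∫ dr / (r²√(1 − b²/r² − V/E)) — shares
no code with the integrator and pins it down on spherical potentials to
10⁻³ rad; time-reversal and step-halving checks guard the integrator
independently of any potential.

## The averaged cross section

`compute_ccs()` combines three averaging strategies, chosen so that each
piece is either exact or comes with an honest error bar:

* **Speeds**: deterministic generalized Gauss–Laguerre quadrature
  (`velocity_quadrature()`). Substituting t = μg²/2k_BT maps the g⁵ weight
  onto t²e^(−t), whose total mass Γ(3) = 2 is the closed form of the speed
  integral; weights are normalized to sum to 1, so a constant cross section
  passes through unchanged and nodes scale as √T.
* **Orientations**: uniform over SO(3) (uniform θ, γ; cos-uniform φ —
  the sin φ measure of the orientation integral), split into batches whose
  spread gives the reported standard error.
* **Impact parameter**: stratified-antithetic sampling in u = b², one
  mirrored pair per stratum, with stratum boundaries uniform in b so the
  strongly deflecting core is finely resolved. Width-weighted stratum means
  keep the estimator unbiased, and any integrand linear in b² is integrated
  exactly — which is precisely why the hard-sphere plug-in
  (χ = 2 acos(b/d), b_max = d) returns πd² to machine precision. That
  anchor defines the normalization; a garbled prefactor in common printed
  renderings of the cross-section formula makes the analytic limit the only
  trustworthy convention.

The cutoff b_max is found by `choose_bmax()`: the smallest b at which the
largest deflection over a deterministic orientation probe set falls below
10⁻³ rad at a low-side thermal speed √(2k_BT/μ), times a 1.2 safety factor
(sensitivity of Ω to that factor is below the Monte-Carlo noise; a probe at
b_max re-checks the criterion at run time and records a warning if it
fails). For singly charged ions the induced-dipole tail, not molecular
size, dominates b_max (25–45 Å), so most strata cover nearly deflection-free
territory — the uniform-in-b stretching exists to counteract exactly that.

Per-orientation estimates scatter strongly for elongated ions (each
orientation samples a single planar slice of impact geometries), so the
standard error is driven by the orientation count. The default
`sampling_plan()` (250 orientations × 16 speed nodes × 40 strata ≈ 1.6 × 10⁵
trajectory pairs) resolves a small ion to ~1–2% in minutes on one CPU.
Results are bit-reproducible for identical plans: the seed controls all
sampling, is echoed in the result, and the session RNG stream is restored
afterwards.

## Mobility conversions

`mason_schamp()` evaluates K in SI internally from CODATA constants
(conversions centralized in `physical_constants()`) and reports
cm²V⁻¹s⁻¹ plus the reduced mobility K0 = K·N/N₀ (N₀ at 273.15 K,
101325 Pa). K0 removes the density dependence; the explicit 1/√T of the
Mason–Schamp form remains, and the reference tables shipped with the
package do not distinguish K from K0 — they are treated as directly
comparable numbers, as is common for ambient-condition drift tubes.

The nitrogen-to-oxygen correction is implemented as the Langevin
polarization-limit ratio obtained from K ∝ 1/√(αμ) with α ∝ (D − 1): the
printed forms of this correction often lack explicit grouping, and this
reading is the one consistent with the correction being small. Dielectric
constants (N₂ 1.000548, O₂ 1.000495) and masses ship as an overridable
constants table. Air is 0.79 N₂ / 0.21 O₂ by Blanc's law, argon folded
into the nitrogen fraction; across 19–142 Da the air-versus-nitrogen shift
stays below 0.6%, comfortably inside the few-percent bound experimental
comparisons rely on.

## Template structures and what the tests do (and do not) show

The builders (`build_water_cluster()`, `build_benzene()`,
`build_toluene()`, `build_alkane()`) provide hydronium water clusters
(H₃O⁺)(H₂O)ₙ for n = 0–5, aromatic radical cations (electron-abstraction
ionization, hence +1 without protonation) bare or with one axial water
3 Å above the ring centroid, and all-anti n-alkane cations C₆–C₁₀ with one
water 3 Å off the chain midpoint. Geometries are textbook idealizations
(C–C 1.54 Å, aromatic C–C 1.39 Å, C–H 1.09 Å, tetrahedral angles) and the
partial-charge templates are synthetic: simple fixed distributions summing
exactly to the total charge. Where cluster attachment geometry is not
constrained by anything stronger (the aromatic water's axial placement, the
alkane water's orientation), the choice here is one of several plausible
ones and is documented as such.

Consequently the end-to-end tests check *structure of the physics*, not
reproduction of literature per-species values: hard-sphere and
quadrature-oracle anchors, rotation invariance of Ω (within three combined
standard errors), energy conservation, and the strict decrease of computed
K from hexane to decane at matched sampling plans (matched seeds make the
difference estimates much more precise than the individual ones). Computed
mobilities from the templates land 10–25% above the packaged reference
values — the expected signature of idealized geometries and synthetic
charges rather than quantum-chemically optimized inputs, which is exactly
the gap the packaged tables quantify for real calculations
(mean unsigned errors of ~2.6–11.7% for optimized structures).

Problem sizes used by the shipped checks: the oracle comparison runs a
single-atom system at 16 speed nodes × 180 quadrature points against a
24-orientation trajectory plan; the alkane ordering uses 256 orientations ×
8 nodes × 24 strata per molecule. Both finish in a few minutes on one CPU.

## Known limitations

* The ion is rigid and cold: no vibrational coupling, no conformer
  ensembles, no inelastic or charge-transfer channels.
* Low-field regime only; no field-dependent mobility.
* The shipped LJ/quadrupole parameters are informed defaults of the
  nitrogen-extended trajectory-code lineage, not a calibrated set; serious
  comparisons should supply their own table via the gas config.
* Negative-mode ions and dimers are out of scope; charges are inputs — the
  package takes no position on how Mulliken, Merz–Kollman–Singh or
  Hirshfeld charges should be computed, only on what they imply for Ω.
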