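# trajmob

Trajectory-method collision cross sections and ion mobilities for small
molecular ions in nitrogen and air.

Ion mobility spectrometry (IMS) separates gas-phase ions by how fast they
drift through a buffer gas in a weak electric field. The link between a
molecular structure and its measured drift time is the orientation-averaged
momentum-transfer collision cross section Ω. `trajmob` computes Ω by the
Trajectory Method — classical scattering of a drift-gas probe in the ion's
interaction potential — and carries the result all the way to the
quantities an IMS practitioner works with: mobilities, drift times, and
error statistics against reference tables. It is aimed at people who model
small ions (reactant-ion water clusters, aromatics, n-alkanes and
similar sub-200 Da species) and want to compare calculated and measured
mobilities.

## The model

The cross section is the averaged momentum-transfer integral

Ω = ⟨ ∫ 2πb (1 − cos χ(θ, φ, γ, b; g)) db ⟩

where χ is the angle between the asymptotic incoming and outgoing
velocities of a drift-gas probe launched at impact parameter b and relative
speed g against the rigid ion (orientation given by Euler angles θ, φ, γ).
The average runs over uniform orientations and the Maxwell–Boltzmann speed
weight g⁵ exp(−μg²/2k\_BT), with μ the reduced mass; the normalization is
anchored by the hard-sphere limit Ω = πd². The interaction potential is a
per-atom 12-6 Lennard-Jones sum plus the charge-induced-dipole term
−(α/2)|E|² built from the ion's partial charges (and, for the full
two-site N₂ model, point charges reproducing the gas quadrupole).
Trajectories are integrated with an adaptive Cash–Karp Runge–Kutta scheme
under an explicit energy-conservation tolerance.

Mobility follows from the Mason–Schamp equation

K = (3/16) (q/N) (1/M + 1/m)^{1/2} (2π/k\_BT)^{1/2} / Ω,

drift times from K = L²/(t\_D U) for a tube of length L and voltage drop U,
and mobilities in ambient air from the nitrogen value via the Langevin
polarization-limit ratio

K\_O₂ = K\_N₂ · sqrt[ (D\_N₂−1) M\_N₂ (m+M\_O₂) / ((D\_O₂−1) M\_O₂ (m+M\_N₂)) ]

mixed by Blanc's law, 1/K\_air = 0.79/K\_N₂ + 0.21/K\_O₂.

## Worked example

Reproduce the packaged comparison statistics, then compute a cross section
and mobility for the 91 Da reactant-ion water cluster (H₃O⁺)(H₂O)₄ from a
template geometry:

```r
library(trajmob)

build_comparison(reference_table("water_clusters"))
#> <comparison_result> [water_clusters]
#>   hirshfeld  MUE = 11.68%  (source prints 11.68)
#>   mk         MUE = 10.45%  (source prints 10.45)
#>   mulliken   MUE = 11.29%  (source prints 11.29)
#>   max per-row error 20.81%

ion <- build_water_cluster(4)          # (H3O+)(H2O)4, nominal mass 91 Da
gas <- drift_gas("N2-iso")             # single-site isotropic N2 model
res <- compute_ccs(ion, gas, temperature = 298,
                   plan = sampling_plan(128, 8, 32, seed = 42))
res
#> <ccs_result> (H3O+)(H2O)4 in N2-iso at 298.0 K: omega = 105.95 +/- 2.57 A^2
#>   (65536 trajectories, trapped 0.00%)

K <- mason_schamp(res, m = ion$mass, M = gas$mass)
K
#> <mobility_value> K = 2.3853 cm^2 V^-1 s^-1 (K0 = 2.1864) at 298.00 K, ...

air_from_n2(K$K, ion$mass)
#> [1] 2.385704
```

Ω is the momentum-transfer cross section in Å² with its Monte-Carlo
standard error; K is the mobility in cm²V⁻¹s⁻¹ under the stated conditions
(K0 its reduction to 273.15 K / 101325 Pa). The air correction is small —
well under 1% here — which is why nitrogen-phase calculations are routinely
compared with measurements in dry air. Template geometries carry synthetic
partial charges, so computed mobilities land near, not on, values derived
from quantum-chemically optimized structures; the packaged tables are the
reference for those.

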