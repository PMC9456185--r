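---
title: "Models and methods behind hostguest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hostguest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostguest)
```

`hostguest` analyses cyclodextrin host–guest inclusion complexes at three
levels: solution thermodynamics from phase-solubility experiments,
structural descriptors of simulated trajectories, and end-point binding
energetics from MM/PBSA component tables. This vignette explains the models,
their assumptions, the defaults and the numerical choices; it states no
result that the package's tests do not themselves compute.

## Phase solubility and the 1:1 stability constant

A phase-solubility experiment equilibrates excess guest against increasing
host concentrations and measures the dissolved guest. For 1:1 complexation
the dissolved guest rises linearly (the Higuchi–Connors A_L type):

$$ [\mathrm{guest}] = S_0 + \frac{K_c S_0}{1 + K_c S_0}\,[\mathrm{host}], $$

so the slope always lies in (0, 1) and the stability constant follows from
the ordinary least-squares line:

$$ K_c = \frac{\text{slope}}{S_0\,(1 - \text{slope})}. $$

`fit_diagram()` implements the unweighted OLS fit (no error model for the
individual points is assumed; replicate-level weighting is out of scope) via
`stats::lm()`. Choices that matter:

- **Linearity threshold.** A diagram is accepted as A_L only when
  r² ≥ 0.98 (configurable). Below the threshold, and for fitted
  slopes ≥ 1 — which cannot arise from 1:1 binding and would make the
  stability-constant denominator non-positive — the profile is reported
  `"nonlinear"` with a warning rather than an error, so batch analyses of
  many diagrams keep running. Higher-order (B-type) profile models are
  deliberately not fitted.
- **Units.** Concentrations are molar internally; `read_solubility_csv()`
  accepts an explicit `unit` column (`M`/`mM`) and converts. Absorbance
  data must be converted by the user's own linear calibration first — no
  extinction coefficient is assumed.
- **Degenerate diagrams.** A perfectly flat diagram (Kc = 0) has zero total
  variance; it is treated as a perfect linear fit rather than dividing by
  zero, and inverts to Kc = 0.

## Van't Hoff analysis

With stability constants at several temperatures, `vant_hoff_fit()`
regresses $\ln K_c$ on $1/T$:

$$ \ln K_c = -\frac{\Delta H}{R\,T} + \frac{\Delta S}{R}, \qquad
   \Delta G = \Delta H - T\,\Delta S. $$

The intercept is $\Delta S / R$ — the standard form of the integrated Van't
Hoff equation, which is also the only form consistent with the published
ΔG/TΔS tables this package reproduces in its tests. Conventions:

- R defaults to 1.985×10⁻³ kcal·mol⁻¹·K⁻¹ and the reference temperature for
  `thermo_table()` to 303 K, matching the published analysis the package is
  verified against; both are arguments. Celsius temperatures are converted
  with +273.15. At the printed 2-decimal precision ΔG is insensitive to the
  273 vs 273.15 choice.
- ΔG computed by `gibbs()` equals $-R\,T$ times the fitted line's predicted
  $\ln K_c$ at that temperature — an exact algebraic identity the test suite
  asserts at 1e-9.
- Enthalpies fitted from *rounded* published Kc values drift by a percent or
  two from enthalpies the original unrounded data would give, while ΔG is
  stable; the tests therefore check ΔG at printed precision but ΔH/TΔS only
  loosely.

## Trajectory descriptors

Trajectories are frame × atom × 3 arrays in ångström with an optional
orthorhombic box; topologies label each atom with a role (host / guest /
solvent) and, for host atoms, a 1-based glucose unit carrying one O2, O3 and
O4 site each. The minimum-image convention is applied whenever a box is
present; boxless trajectories are treated as non-periodic.

- **RMSD** (`rmsd_series()`) superposes every frame on the reference with
  the Kabsch SVD algorithm, constrained to proper rotations; collinear or
  coincident selections raise a degeneracy error instead of returning an
  arbitrary rotation. RMSD is non-mass-weighted by default.
- **Radius of gyration** (`rg_series()`) is mass-weighted when a topology
  (or mass vector) is given, unit-weighted otherwise — the two conventions
  in common use; the default follows standard practice for compactness
  plots.
- **Atom contacts** (`contact_series()`) counts inter-group pairs within a
  cutoff, 4.5 Å heavy-atom by default (a common contact convention; the
  choice is exposed). "Native" contacts are those also present in a
  user-chosen reference frame, by default frame 1 (the starting pose);
  nonnative = total − native.
- **Rim distances** (`rim_distances()`) report d(O3ₙ–O2ₙ₊₁) on the wider
  rim and the glycosidic d(O4ₙ–O4ₙ₊₁), with cyclic pairing (unit n pairs
  with unit 1). `hbond_fraction()` applies the pure distance criterion
  d32 ≤ 3.5 Å for a possible intramolecular hydrogen bond; angle- or
  energy-based hydrogen-bond definitions are out of scope.

## Free-energy landscape

`fel_2d()` bins two collective variables on a regular grid (0.1 Å default
bin width in both axes) and Boltzmann-inverts the empirical probabilities:

$$ F(x, y) = -k_B T \ln P(x, y), $$

with $k_B T$ taken as the molar $R\,T$ in kcal/mol (T = 303 K default).
Numerical choices: the grid is anchored on multiples of the bin width;
energies are shifted so the lowest occupied cell is exactly zero (the
absolute offset of a histogrammed free energy is arbitrary); empty cells are
masked `NA` rather than assigned a large penalty, so downstream statistics
are not polluted by sentinel values. The transform is exactly invertible —
renormalising $e^{-F/k_BT}$ over occupied cells reproduces the empirical
bin probabilities to 1e-12 — which the suite asserts on random data.

## Solvation structure

`rdf()` histograms centre–solvent distances over frames and centres and
normalises each shell by the ideal-gas expectation $4\pi r^2 \Delta r \rho$,
using the bin-centre radius. Bulk density defaults to
N<sub>solvent</sub>/V<sub>box</sub>; boxless systems need an explicit
density. Defaults dr = 0.05 Å and r_max = 10 Å cover a first solvation
peak near 2.5 Å and its minimum with room to spare.

`first_minimum()` smooths g(r) with a 3-bin moving average (raw simulation
histograms are noisy; the window is configurable and 1 disables it) and
scans for the first strict local maximum followed by the first strict local
minimum. Profiles without that pattern — e.g. buried atoms with no
solvation peak — return `NA` with `detected = FALSE`; `hydration_table()`
propagates this as an absent entry rather than an error, mirroring how such
atoms are dashed out in published hydration tables.

`coordination_number()` integrates $4\pi\rho\,g(r)\,r^2$ by the trapezoidal
rule from zero (prepending the exact boundary value 0 at r = 0), which makes
n(r) nondecreasing for any non-negative profile. `hydration_table()` detects
the first minimum per replicate, integrates each replicate's profile to its
own minimum, and reports mean ± SEM with the sample (n−1) standard
deviation over replicates (n = 3 in the usual design).

## MM/PBSA aggregation

The package consumes per-snapshot component tables (ΔE_vdW, ΔE_ele,
ΔG_solv,polar, ΔG_solv,non-polar) produced by an external solver — it never
computes electrostatics itself. `derive_terms()` forms the standard
combinations per snapshot; `summarize_mmpbsa()` averages per replicate
first, then across replicates, reporting SEM = sd/√n at the replicate level
(a pooled-snapshot SEM mode is available, since published tables are often
ambiguous about which was used). The entropy term enters once per replicate,
as normal-mode/quasi-harmonic entropies are not per-snapshot quantities; a
per-snapshot entropy column can be emulated by passing replicate means. All
additivity identities (ΔE_MM, ΔG_solv, ΔG_bind) hold exactly on the mean
values by construction, and derived terms are computed from full-precision
inputs — summing independently rounded component means can differ in the
last printed digit, which is a display artefact, not a computation choice.

## Synthetic data: what it emulates and what it does not

The generators produce inputs with exactly the statistical structure the
analyses assume, each invertible by its analysis stage at zero noise:

- `simulate_diagram()`: the A_L line with independent Gaussian measurement
  noise, host range 0–10 mM (the usual working range of these experiments).
- `simulate_vant_hoff()`: $K_c(T) = e^{-\Delta H/RT + \Delta S/R}$ with
  optional Gaussian noise on ln Kc, at 20–50 °C in 10 °C steps.
- `simulate_ring_trajectory()`: a *geometric* seven-unit macrocycle — O4
  sites on a regular heptagon (5 Å radius default), O3/O2 sites constructed
  so every cyclic rim pair sits at an exact configured separation (3 Å
  default, inside the hydrogen-bond criterion), per-frame Gaussian jitter,
  optional axial guest atoms, and uniform, non-interacting solvent
  resampled every frame in a periodic box.
- `simulate_energy_table()`: independent Gaussian component rows per
  snapshot, a fixed entropy term per replicate.

These emulate measurement noise, ring geometry with labelled sites, and
ideal (bulk-like) solvent. They do **not** emulate force-field energetics,
correlated conformational dynamics, solvent structuring around solutes, or
anharmonic entropy — so passing tests demonstrate the *estimators* are
correct (unbiased inversion, exact identities, ideal-gas limits), not that
any particular chemical system behaves this way. Quantities that depend on
real sampled dynamics (published RMSD/Rg magnitudes, hydration numbers of a
specific complex) are treated as format and semantics references only.

Determinism: every generator takes a `seed` and is byte-identical for a
fixed seed and configuration, without disturbing the caller's RNG stream.

## Problem sizes used in the checks

The self-checks run at desk scale, chosen to keep Monte-Carlo error well
inside the asserted tolerances: 200 random seeds for the noisy-diagram bias
check, 100 random instances for the contact oracle, and a 40 Å cube with
2000 solvent sites over 50 frames and 5 centres for the ideal-gas RDF limit
(≈2 % sampling error against a 5 % band).

## Known limitations

- Only 1:1 stoichiometry; B-type and 1:2 Higuchi–Connors models are not
  fitted.
- Minimum-image only for orthorhombic boxes; triclinic cells are not
  supported.
- The PDB dialect honours MODEL/ENDMDL, ATOM/HETATM and CRYST1 records
  only; binary trajectory formats (DCD/XTC) are out of scope.
- Uncertainty reporting is limited to regression standard errors and
  replicate SEMs; no error propagation through Kc into ΔH/ΔS.
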