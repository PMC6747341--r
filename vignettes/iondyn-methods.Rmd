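---
title: "Methods: trajectory analysis of metalloprotein ion dynamics with iondyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of metalloprotein ion dynamics with iondyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

iondyn implements the post-simulation analysis pipeline used to characterise
the conformational dynamics of matrix metalloproteinase-2 (MMP-2) and the
behaviour of its five crystallographically assigned divalent cations (two
Zn²⁺, three Ca²⁺) from a long explicit-solvent molecular dynamics
trajectory. This vignette is the package's account of the underlying
science: the models, the parameters that matter, the numerical choices, and
what the synthetic-data tests do and do not demonstrate.

## Units and conventions

All internal units follow the GROMACS convention: nm for length, kJ/mol for
energy, ns for time, elementary charges, kelvin. The electric conversion
factor is 1/(4πε₀) = 138.935458 kJ mol⁻¹ nm e⁻², and R = 8.314462618×10⁻³
kJ mol⁻¹ K⁻¹. Residue numbering is the 1-based author numbering of the PDB
entry; domain ranges are inclusive on both ends. For mature MMP-2 the
shipped config defines Cat 110–445, the fibronectin insert Fib 217–393
(listed after Cat so the insert's label wins over the overlap; the
Cat-with-Fib union is the selection `"domain Cat or domain Fib"`), the
linker Lnk 446–460, and Hpx 461–660. His protonation variants
(HSD/HSE/HSP/HID/HIE/HIP) are aliased to HIS at load.

## Conformational stability observables

RMSD and RMSF are measured against the *iteratively converged average
structure*: every frame is superposed (weighted Kabsch, proper rotations
only) onto a running mean, the mean is recomputed, and the loop repeats
until the mean moves less than 10⁻⁶ nm (two passes normally suffice). Ion
RMSF is measured after fitting on the protein Cα trace only, so it
quantifies ion motion *relative to the protein frame* — the quantity that
distinguishes a site-bound ion from one diffusing away.

The radius of gyration is mass-weighted over all selected atoms by default;
a Cα-only, unit-weight variant is available through the `selection` and
`mass_weighted` arguments since conventions differ between tools.
Inter-domain centre-of-mass distances use mass-weighted centres on
coordinates as stored; no minimum-image wrapping is applied across a
molecule, because domains must not be split over a periodic boundary —
whole (unwrapped) molecules are the caller's responsibility. The periodic
minimum distance checks all 26 neighbouring images of an orthorhombic cell
and is the box-adequacy diagnostic.

Configurational entropy uses Schlitter's quasi-harmonic upper bound
S ≤ (R/2) ln det(1 + kBT e² M^{1/2} C M^{1/2}/ħ²) on the mass-weighted Cα
covariance. The `+1` inside the determinant makes the formula robust to
singular covariances, so a static trajectory cleanly gives S = 0.
Equilibration is detected as the first window end after which the
growing-window entropy changes by less than 1% over three consecutive
windows; the pipeline accepts a fixed cutoff (e.g. 200 ns) instead, and all
downstream stages use only frames at or after the cutoff.

## Dihedral PCA and free-energy landscapes

Backbone φ/ψ angles (and only those — ω and side-chain torsions are
excluded) are embedded as (cos θ, sin θ) pairs, which removes the ±π
wrap-around that distorts PCA on raw angles. The covariance of the centred
embedding is diagonalised; projections onto the first two components span
the landscape. The free energy per bin is ΔG = −RT ln(ρ/ρ_max) on a grid
(default 100×100 over the data range padded by 1%). Empty bins carry +∞ —
the free energy is genuinely undefined at zero density — and plots cap them
at the maximum finite ΔG plus one RT.

Conformational families come from k-means (best of `n_init = 50` restarts,
fixed seed) with SSE, the average silhouette width S_avg, and the
silhouette coefficient SC = max over scanned k of S_avg(k) as model-selection
diagnostics; the definition of SC varies in the literature, and this maximum
convention is the one adopted here. For large frame counts silhouettes are
computed on a deterministic subsample (default 2000 frames) because the
O(n²) distance matrix is prohibitive; SSE and assignments always use all
frames. Representative structures are the member frame of each cluster
lying in the cluster's lowest-ΔG occupied bin (ties broken toward the
centroid), exported as PDB.

A basin-to-basin gap is estimated by `fel_basin_gap()`, which pools counts
in the 3×3 block around each basin's modal bin before Boltzmann inversion.
The pooling matters: the single maximal bin of a finite-sample histogram is
biased upward by max-statistics, which systematically shrinks the apparent
gap; with pooling the planted-equilibrium recovery error drops from ~5–12%
to ≤5% at 50,000 frames.

## Domain-motion analysis

The dynamic cross-correlation matrix is the Pearson normalisation
c_ij = ⟨Δr_i·Δr_j⟩ / sqrt(⟨Δr_i²⟩⟨Δr_j²⟩) of the 3N Cα covariance; +1 is
fully correlated, −1 fully anti-correlated motion. Atoms with zero
fluctuation are flagged and their rows set to NA rather than silently
propagating NaN; an entirely static input is an error. The quaternion-based
variant of domain-movement analysis is out of scope; Pearson coefficients
are what the matrix reports.

Superposition before the covariance removes six rigid-body degrees of
freedom, so Cartesian PCA reports variance fractions both over all modes
and over internal modes only (the six smallest eigenvalues excluded from
the denominator) — summaries like "the first five PCs account for X% of the
domain motions" depend on this choice, and both numbers are emitted.
Per-PC RMSF profiles come from reconstructing the trajectory from a single
eigenvector and measuring each atom's fluctuation in that reconstruction.
When the collective motion of interest is itself a lab-frame rigid-body
displacement — as in the synthetic domain-motion scenario — the fit would
absorb part of the signal; `covariance_matrix(fit = FALSE)` analyses
lab-frame displacements instead.

## Ion hydration

The radial distribution function g(r) uses minimum-image distances,
shell-volume normalisation and the mean target density
ρ₀ = N_target/⟨V_box⟩, with r_max capped at half the smallest box edge.
Coordination numbers integrate CN(r) = 4πρ₀ ∫ g r² dr by the trapezoid rule
with the endpoint interpolated so the integral covers [0, r] exactly
(stopping at the last bin centre loses ~7% at typical bin widths); the
direct per-frame neighbour count is computed alongside as a cross-check and
the two agree within 2% on synthetic scenarios. Default shell boundaries
follow the trough radii observed for these ions (Zn²⁺ 0.31/0.50 nm, Ca²⁺
0.31/0.55 nm) but are auto-detectable from profile extrema.

The shell "statistical density" is implemented as an occupancy probability:
the fraction of sampled frames with at least one solvent oxygen within r.
The literal one-dimensional integral ∫₀^r g dr is not a probability
dimensionally (it has units of length and does not approach 1 at large r);
the prose definition — the probability of a solvent molecule being located
within r — is the meaningful quantity and the one tabulated, while the raw
integral remains available as `density_integral()` for comparison.

SASA is Shrake–Rupley with 960 quasi-uniform (golden-spiral) points per
atom, probe 0.14 nm, Bondi radii — choices that track the defaults of the
common simulation tools. 960 points give the isolated-sphere area to well
under 1%.

## Ion energetics and interaction entropy

The molecular-mechanics ion–protein interaction energy is the pairwise sum
E = Σ_j 4ε_ij[(σ_ij/r_ij)¹² − (σ_ij/r_ij)⁶] + Σ_j f q_i q_j/r_ij with
Lorentz–Berthelot combination (arithmetic-mean σ, geometric-mean ε), no
distance cutoff (it is a gas-phase MM term), and minimum-image distances
when a box is present. Divalent cations use the σ/ε of the CM non-bonded
ion model (shipped in the parameter table) and formal charge +2. The
per-residue decomposition assigns each pair term to the protein atom's
residue and sums exactly to the total.

The interaction entropy is −TΔS = RT ln⟨e^{βΔE}⟩ with ΔE = E − ⟨E⟩ and
β = 1/(RT) on molar energies — the molar convention keeps RT ln⟨·⟩
dimensionally consistent when E is in kJ/mol. The ensemble average is
computed with a max-shifted log-sum-exp so strongly fluctuating series
never overflow; by Jensen's inequality the estimate is non-negative, and
for Gaussian fluctuations of standard deviation σ_E it converges to
βσ_E²/2 (σ_E = RT gives RT/2 ≈ 1.289 kJ/mol at 310 K) — the closed form the
tests check. Standard errors come from bootstrap resampling of frames
(n = 5000 in production, deterministic given the seed).

Continuum solvation is deliberately simple: the nonpolar term is
γ·SASA + b with the g_mmpbsa-style defaults γ = 2.27 kJ mol⁻¹ nm⁻²,
b = 3.85 kJ/mol, and the polar term is a Born-style exposure-scaled
desolvation penalty ΔG_polar = (f q²/2a)(1/ε_in − 1/ε_w)(1 − φ), with
ε_in = 4, ε_w = 80, a the effective Born radius (σ/2 plus a water-probe
offset) and φ the ion's exposed-area fraction. This is an explicit
approximation of a finite-difference Poisson–Boltzmann term: it preserves
the sign structure (burying a divalent cation costs a large positive
ΔG_polar; a fully solvated ion costs nothing) but not PB's geometry
dependence, and it is labelled as such wherever it is reported. A full PB
solver is out of scope.

Significantly interacting residues are called by Tukey's fences on the
per-residue mean contributions: [Q1 − k·IQR, Q3 + k·IQR] with
linear-interpolation (type-7) quartiles — the quartile convention must be
stated because the fence definition alone does not fix it — with k = 1.5
for outliers and k = 3 for extreme outliers; values at or beyond a fence
are flagged. With a degenerate IQR of zero the fences collapse onto the
common value and the at-or-beyond rule flags the ties along with the true
extreme; this edge case is accepted rather than special-cased.

Coordination geometry is classified from the protein N/O atoms within
0.35 nm of the ion: observed inter-ligand angles are matched against ideal
templates (linear, trigonal pyramidal, tetrahedral, square planar, seesaw,
trigonal bipyramidal, octahedral) of the same ligand count or with one
vacancy, minimising the angle RMSD over all site assignments; a best RMSD
above 20° (or fewer than two ligands) is reported as not-coordinated. The
vacancy allowance mirrors how crystallographic tools label, for example, a
four-ligand site as trigonal bipyramidal when a water completes the
polyhedron.

## The synthetic-data generators

Each generator plants a known ground truth so every analysis stage has a
parameter-recovery test without any download:

* `gen_dihedral_states()` — a polyalanine-like N–CA–C backbone built by
  internal-coordinate (NeRF) placement from per-frame φ/ψ, with a hidden
  state per frame drawn from the requested populations and wrapped-normal
  jitter (default sd 0.15 rad) about each state's mean dihedrals. Defaults:
  a helix-like (−57°, −47°) and an extended (−140°, 150°) state over six
  residues — two well-separated basins, the minimal caricature of a
  two-family landscape.
* `gen_domain_motion()` — rigid blocks of Cα beads translating along the
  inter-domain axis with a shared (correlated/anti-correlated) or private
  (independent) standard-normal series, amplitude 0.3 nm, plus isotropic
  thermal noise of 0.03 nm per bead. With these defaults the planted
  block correlation is amp²/(amp² + 3σ²) ≈ 0.97; the noise scale was chosen
  as a realistic rigid-core fluctuation, small against a domain-scale
  motion.
* `gen_ion_pocket()` — one divalent ion among fixed charged LJ sites,
  sampled from a Gaussian about the pocket or by Metropolis at temperature
  T; every recorded frame's energy is recomputed inside the generator by a
  deliberately naive double loop that shares no code with the vectorised
  energetics module. That anti-circularity is the point: the generator is
  the oracle.
* `gen_hydration_shells()` — a central ion with solvent oxygens placed in
  shells of given radius/width/occupancy plus an optional uniform
  background in a periodic cube. Fractional occupancies are realised as
  floor + Bernoulli per frame; unoccupied shell slots are parked on a
  distant sphere (0.45 box) so the atom count stays constant — analyses
  must therefore stay below that parking radius, which all defaults do.

What these tests show — and what they do not: the generators validate the
estimators (superposition, PCA, Boltzmann inversion, RDF integration,
energy sums, entropy and outlier statistics) against planted truth and
closed forms. They do not emulate force-field realism, water–water
structure, thermostat artefacts, or the conformational coupling of a real
protein; agreement on synthetic data is evidence the arithmetic and
statistics are right, not that a production trajectory is converged.

## Problem sizes

The test-suite and acceptance computations use sizes chosen to put sampling
error well inside each tolerance while remaining desk-scale: 50,000 frames
for the two-state landscape recovery (binomial error on a 10% population
≈ 0.4%), 10,000 frames for DCCM block recovery (null correlation
≈ 1/√N = 1%), 100,000 samples for the Gaussian interaction-entropy closed
form, 1,000 frames for the energy-oracle comparison, 300–400 frames of
dense synthetic solvent for hydration statistics, and 1,000 random datasets
for the outlier-calling cross-check.

## Known limitations

* The polar solvation term is a Born-style approximation, not a PB
  solution; absolute ΔG_polar values are indicative only.
* Orthorhombic boxes only for minimum-image operations (the trajectory
  container stores box edge lengths; triclinic cells are not imaged).
* Trajectory formats: multi-model PDB and DCD. The compressed XTC format
  has no reader in this stack and is not supported.
* Silhouettes are subsampled beyond 2000 points; S_avg then carries
  sampling noise of a few percent.
* The crystal-structure checks require the user to supply the PDB entry
  (1CK7) locally; it is not redistributed.
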