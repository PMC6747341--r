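# iondyn

Post-simulation analysis of metalloprotein molecular dynamics trajectories,
built around the workflow used to characterise matrix metalloproteinase-2
(MMP-2) — a Zn²⁺-dependent collagenase with catalytic (Cat), fibronectin
(Fib) and hemopexin (Hpx) domains joined by a flexible linker — and the
dynamic behaviour of its five associated divalent cations (2 Zn²⁺, 3 Ca²⁺).
It is written for structural-bioinformatics practitioners who have a
structure, a nonbonded parameter table and a trajectory, and want the full
ion-and-domain analysis stack in one tested, scriptable R package.

What it computes:

* **Conformational stability** — Kabsch superposition onto an iteratively
  converged average structure; Cα RMSD/RMSF, radius of gyration,
  inter-domain centre-of-mass distances, periodic minimum-image distance,
  and Schlitter configurational entropy
  S ≤ (R/2) ln det(1 + k_BT e² M^{1/2}CM^{1/2}/ħ²) for equilibration
  detection.
* **Dihedral PCA and free-energy landscapes** — φ/ψ angles embedded as
  (cos θ, sin θ), PCA, ΔG = −RT ln(ρ_xy/ρ_max) on a 2-D grid, k-means
  conformational families with SSE/silhouette diagnostics, lowest-ΔG
  representative structures.
* **Domain-movement analysis** — 3N Cα covariance, Pearson dynamic
  cross-correlation matrix (DCCM, −1 anti-correlated … +1 correlated),
  Cartesian PCA with per-PC RMSF profiles and internal-mode variance
  fractions.
* **Ion hydration** — radial distribution functions, hydration-shell
  occupancy probabilities, coordination numbers
  CN = 4πρ₀∫g(r)r²dr, Shrake–Rupley SASA.
* **Ion energetics** — Lennard-Jones + Coulomb interaction energies
  (Lorentz–Berthelot combination, f = 138.935458 kJ mol⁻¹ nm e⁻²),
  MMPBSA-style binding budgets with a Born-style polar-solvation
  approximation, interaction entropy −TΔS = RT ln⟨e^{βΔE}⟩ with bootstrap
  errors, Tukey-fence identification of significantly interacting residues,
  and coordination-geometry classification (linear … octahedral) of metal
  sites.
* **Synthetic ground truth** — generators for multi-state dihedral
  dynamics, rigid correlated domain motion, an ion in a pocket of charged
  LJ sites (with an independent naive-loop energy oracle), and hydration
  shells, so every stage has a parameter-recovery test with no downloads.

Everything user-facing takes data frames / returns tibbles and composes
with the pipe; fitted objects have broom-style `tidy()`/`glance()` methods
and `autoplot()` visualisations.

## Worked example

A divalent ion sampled by Metropolis in a pocket of six carboxylate-like
sites, analysed for binding energetics and interaction entropy:

```r
library(iondyn)

pocket <- gen_ion_pocket(n_frames = 2000, sampling = "metropolis",
                         temperature = 310, seed = 7)
energy <- interaction_energy(pocket$traj, pocket$system,
                             ion_sel = select_atoms(pocket$system, "domain ion"),
                             protein_sel = select_atoms(pocket$system, "not domain ion"))
energy
#> <energy_series> 2000 frames; <E> = -3330.39 kJ/mol (LJ 4.12, Coul -3334.51)

report <- binding_report(energy, temperature = 310, n_boot = 1000,
                         seed = 7, label = "Zn2+ pocket")
tidy(report)
#> # A tibble: 7 × 4
#>   ion         term       estimate     se
#>   <chr>       <chr>         <dbl>  <dbl>
#> 1 Zn2+ pocket e_vdw          4.12 0.0651
#> 2 Zn2+ pocket e_elec     -3335.   0.0326
#> 3 Zn2+ pocket g_polar        0    0
#> 4 Zn2+ pocket g_nonpolar     0    0
#> 5 Zn2+ pocket minus_TdS      3.59 0.329
#> 6 Zn2+ pocket e_binding  -3330.   0.0621
#> 7 Zn2+ pocket g_binding  -3327.   0.0621
```

The mean interaction energy is dominated by electrostatics (−3335 kJ/mol
for a +2 ion among six −0.5 e oxygens at ~0.25 nm), the van der Waals term
is small and repulsive at contact, and the interaction entropy contributes
a +3.6 kJ/mol penalty from the energy fluctuations at 310 K — the same
structure the full analysis reports for protein-bound cations.

A planted 90/10 two-state backbone ensemble, recovered through the
dihedral-PCA landscape:

```r
g <- gen_dihedral_states(n_frames = 20000, populations = c(0.9, 0.1), seed = 7)
pc <- dpca(extract_dihedrals(g$traj, g$system))
pc
#> <pc_model> 20000 frames, 20 dims; leading variance fractions: 0.920 0.008 ...

fel <- free_energy_landscape(pc, grid = 80, temperature = 310)
km <- kmeans_cluster(pc$projections[, 1:2], k = 2, seed = 7)
km
#> <cluster_model> k = 2, SSE = 538, S_avg = 0.962, sizes: 2000 18000

fel_basin_gap(fel, km$assignments)
#> 5.56  # kJ/mol; the planted equilibrium gives RT ln 9 = 5.66
autoplot(fel)
```

The two conformational families separate completely along dPC1 (92% of the
embedded variance), the cluster sizes reproduce the planted 90/10 split,
and the landscape's basin gap recovers RT ln 9 within binning error.

A command-line front end (`inst/cli/iondyn`) exposes the generators and the
main observables (`synth`, `geometry`, `rdf`, `energy`, `run`) for shell
pipelines; `run_all(run_config(...))` drives the whole workflow from one
config with per-stage TSV/JSON/PDB outputs and provenance headers.

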