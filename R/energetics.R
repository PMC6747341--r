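# Nonbonded ion-protein energies, continuum solvation terms, interaction
# entropy, bootstrap errors, Tukey-fence outlier calling, coordination
# geometry classification.

#' Ion-protein nonbonded interaction energy series
#'
#' Per-frame Lennard-Jones + Coulomb interaction between an ion selection
#' and a protein selection,
#' \eqn{E = \sum_j 4\epsilon_{ij}[(\sigma_{ij}/r_{ij})^{12} -
#' (\sigma_{ij}/r_{ij})^6] + f\, q_i q_j / r_{ij}} with Lorentz-Berthelot
#' combination (arithmetic-mean sigma, geometric-mean epsilon) and
#' \eqn{f = 138.935458} kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}. No distance
#' cutoff (gas-phase molecular-mechanics term); minimum-image distances are
#' used when box information is present. Vectorised over pairs; the
#' synthetic generator's naive-loop energies serve as its independent oracle
#' in tests.
#'
#' @param traj A `trajectory`.
#' @param system A `molecular_system` carrying charges and LJ parameters.
#' @param ion_sel Atom indices of the ion(s) (typically one).
#' @param protein_sel Atom indices of the interacting partner.
#' @param decompose Also return the per-residue energy matrix.
#' @return An `energy_series`: tibble `series` (`time`, `lj`, `coulomb`,
#'   `total` kJ/mol) plus, when `decompose`, `per_residue` (frames x
#'   residues matrix of summed pair terms assigned to the protein atom's
#'   residue) with residue ids as column names.
#' @export
interaction_energy <- function(traj, system, ion_sel, protein_sel,
                               decompose = TRUE) {
  if (length(ion_sel) == 0 || length(protein_sel) == 0) stop("empty selection")
  a <- system$atoms
  f <- iondyn_constants$f_coulomb
  nf <- n_frames(traj)
  np <- length(protein_sel)
  resids <- a$resid[protein_sel]
  res_levels <- sort(unique(resids))
  res_col <- match(resids, res_levels)
  lj_t <- numeric(nf); coul_t <- numeric(nf)
  per_res <- if (decompose) matrix(0, nf, length(res_levels)) else NULL
  for (ii in ion_sel) {
    qi <- a$charge[ii]; si <- a$sigma[ii]; ei <- a$epsilon[ii]
    sij <- (si + a$sigma[protein_sel]) / 2
    eij <- sqrt(ei * a$epsilon[protein_sel])
    qq <- f * qi * a$charge[protein_sel]
    for (fr in seq_len(nf)) {
      x <- frame_coords(traj, fr)
      d <- sweep(x[protein_sel, , drop = FALSE], 2, x[ii, ])
      if (!is.null(traj$box)) {
        L <- traj$box[fr, ]
        for (k in 1:3) d[, k] <- .min_image(d[, k], L[k])
      }
      r <- sqrt(rowSums(d^2))
      if (any(r < 1e-4)) {
        stop(sprintf("atomic overlap at frame %d: r = %.2g nm", fr, min(r)))
      }
      sr6 <- (sij / r)^6
      lj <- 4 * eij * (sr6^2 - sr6)
      coul <- qq / r
      lj_t[fr] <- lj_t[fr] + sum(lj)
      coul_t[fr] <- coul_t[fr] + sum(coul)
      if (decompose) {
        per_res[fr, ] <- per_res[fr, ] +
          as.numeric(rowsum(lj + coul, res_col, reorder = TRUE))
      }
    }
  }
  out <- structure(list(
    series = tibble::tibble(time = traj$times, lj = lj_t, coulomb = coul_t,
                            total = lj_t + coul_t),
    per_residue = per_res, residues = res_levels
  ), class = "energy_series")
  if (decompose) colnames(out$per_residue) <- res_levels
  out
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series> %d frames; <E> = %.2f kJ/mol (LJ %.2f, Coul %.2f)\n",
              nrow(x$series), mean(x$series$total), mean(x$series$lj),
              mean(x$series$coulomb)))
  invisible(x)
}

#' Continuum solvation terms for an ion
#'
#' Nonpolar term: \eqn{\gamma \cdot SASA + b} on the ion's
#' solvent-accessible area in the complex (g_mmpbsa-style constants). Polar
#' term: a Born-style exposure-scaled desolvation penalty — an explicit
#' approximation of a Poisson-Boltzmann binding term that preserves its sign
#' structure: burying a charged ion costs
#' \eqn{\Delta G_{polar} = \frac{f q^2}{2 a}(1/\epsilon_{in} -
#' 1/\epsilon_{w})(\phi - 1)} where \eqn{\phi} is the exposed-area fraction
#' (1 fully solvated — no penalty; 0 fully buried — full Born penalty).
#'
#' @param traj A `trajectory`.
#' @param system A `molecular_system`.
#' @param ion_sel Index of the ion atom.
#' @param context_sel Occluding atoms for the SASA (default non-solvent).
#' @param born_radius Effective Born radius (nm); default the ion's
#'   LJ sigma/2 + probe-sized water offset (0.14 nm).
#' @param eps_in,eps_w Solute and water dielectric constants.
#' @param gamma,b Nonpolar surface coefficients (kJ/mol/nm^2, kJ/mol).
#' @param probe,n_points SASA parameters.
#' @return Tibble `time`, `sasa`, `g_polar`, `g_nonpolar` (kJ/mol).
#' @export
solvation_terms <- function(traj, system, ion_sel, context_sel = NULL,
                            born_radius = NULL, eps_in = 4, eps_w = 80,
                            gamma = 2.27, b = 3.85, probe = 0.14,
                            n_points = 960) {
  stopifnot(length(ion_sel) == 1)
  a <- system$atoms
  if (is.null(born_radius)) born_radius <- max(a$sigma[ion_sel] / 2 + 0.14, 0.05)
  ss <- sasa_series(traj, system, ion_sel, context_sel = context_sel,
                    probe = probe, n_points = n_points)
  area_free <- 4 * pi * (.vdw_radius(a$element[ion_sel]) + probe)^2
  phi <- pmin(1, ss$sasa / area_free)
  q <- a$charge[ion_sel]
  # water -> solute-interior transfer penalty for the buried charge fraction
  born_penalty <- iondyn_constants$f_coulomb * q^2 / (2 * born_radius) *
    (1 / eps_in - 1 / eps_w)
  g_polar <- born_penalty * (1 - phi)
  g_nonpolar <- gamma * ss$sasa + b
  tibble::tibble(time = ss$time, sasa = ss$sasa, g_polar = g_polar,
                 g_nonpolar = g_nonpolar)
}

#' Interaction entropy
#'
#' \eqn{-T\Delta S = RT \ln \langle e^{\beta \Delta E} \rangle} with
#' \eqn{\Delta E = E - \langle E \rangle} and \eqn{\beta = 1/(RT)} on molar
#' energies. Computed with a max-shifted log-sum-exp so large fluctuations
#' never overflow; by Jensen's inequality the result is always >= 0.
#'
#' @param energy An `energy_series`, or a numeric vector of per-frame
#'   interaction energies (kJ/mol).
#' @param temperature Temperature (K).
#' @return `-TdS` in kJ/mol (scalar, >= 0).
#' @export
interaction_entropy <- function(energy, temperature = 310) {
  e <- if (inherits(energy, "energy_series")) energy$series$total else as.numeric(energy)
  if (length(e) < 2) stop("interaction entropy needs >= 2 frames")
  RT <- iondyn_constants$R_kj * temperature
  de <- e - mean(e)
  z <- de / RT
  m <- max(z)
  RT * (m + log(mean(exp(z - m))))
}

#' Bootstrap standard error by frame resampling
#'
#' Resamples frames with replacement and reports the bootstrap standard
#' error of the mean energy and of the interaction entropy. Deterministic
#' given `seed`.
#'
#' @param energy An `energy_series` or numeric vector (kJ/mol).
#' @param n_boot Number of bootstrap replicates.
#' @param temperature Temperature (K) for the entropy statistic.
#' @param seed RNG seed.
#' @param statistic `"mean"`, `"ie"`, or both.
#' @return Tibble `statistic`, `estimate`, `se`.
#' @export
bootstrap_se <- function(energy, n_boot = 5000, temperature = 310, seed = 1,
                         statistic = c("mean", "ie")) {
  e <- if (inherits(energy, "energy_series")) energy$series$total else as.numeric(energy)
  if (length(e) < 2) stop("bootstrap needs >= 2 frames")
  statistic <- match.arg(statistic, several.ok = TRUE)
  set.seed(seed)
  n <- length(e)
  reps <- matrix(NA_real_, n_boot, length(statistic))
  for (bb in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    eb <- e[idx]
    col <- 1
    if ("mean" %in% statistic) { reps[bb, col] <- mean(eb); col <- col + 1 }
    if ("ie" %in% statistic) reps[bb, col] <- interaction_entropy(eb, temperature)
  }
  est <- c(mean = mean(e),
           ie = interaction_entropy(e, temperature))[statistic]
  tibble::tibble(statistic = statistic, estimate = as.numeric(est),
                 se = apply(reps, 2, stats::sd))
}

#' Tukey's fences outlier calling
#'
#' Fences \eqn{[Q_1 - k\,IQR,\; Q_3 + k\,IQR]} with linear-interpolation
#' (type-7) quartiles; values at or beyond a fence are flagged (`k = 1.5`
#' outlier, `k = 3` extreme outlier).
#'
#' @param values Numeric vector (>= 4 values).
#' @param k Fence multiplier.
#' @return List with `lower`, `upper`, `outlier` (logical vector), `q1`,
#'   `q3`.
#' @export
tukey_fences <- function(values, k = 1.5) {
  values <- as.numeric(values)
  if (length(values) < 4) stop("Tukey fences need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  list(lower = lower, upper = upper,
       outlier = values <= lower | values >= upper,
       q1 = q[1], q3 = q[2])
}

# Ideal coordination templates: unit ligand directions; vacancies allowed
# when the observed ligand count is one short of the template.
.geometry_templates <- function() {
  s <- 1 / sqrt(3)
  list(
    linear = rbind(c(1, 0, 0), c(-1, 0, 0)),
    `trigonal pyramidal` = rbind(c(s, s, s), c(s, -s, -s), c(-s, s, -s)),
    tetrahedral = rbind(c(s, s, s), c(s, -s, -s), c(-s, s, -s), c(-s, -s, s)),
    `square planar` = rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)),
    seesaw = rbind(c(0, 0, 1), c(0, 0, -1),
                   c(1, 0, 0), c(cos(2 * pi / 3), sin(2 * pi / 3), 0)),
    `trigonal bipyramidal` = rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0),
                                   c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
                                   c(cos(4 * pi / 3), sin(4 * pi / 3), 0)),
    octahedral = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))
  )
}

.pairwise_angles <- function(dirs) {
  n <- nrow(dirs)
  out <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out <- c(out, acos(pmin(1, pmax(-1, sum(dirs[i, ] * dirs[j, ])))))
  }
  out
}

.permutations <- function(n, r) {
  if (r == 0) return(matrix(integer(0), 1, 0))
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- .permutations(n - 1, r - 1)
    rest[rest >= i] <- rest[rest >= i] + 1L
    cbind(i, rest)
  }))
}

#' Classify the coordination geometry of a metal site
#'
#' Ligands are the N/O atoms (by default) within `cutoff` of the ion.
#' Observed ligand directions are matched against ideal geometry templates
#' of the same ligand count, and against templates with one vacancy, by
#' minimising the RMSD between observed and ideal inter-ligand angles over
#' all site assignments; the label with the smallest angle-RMSD wins.
#' Fewer than 2 ligands, or a best RMSD above `rmsd_max`, yields
#' `"not-coordinated"`.
#'
#' @param coords `n x 3` single-frame coordinates (nm).
#' @param system A `molecular_system`.
#' @param ion_idx Index of the ion atom.
#' @param cutoff Ligand search radius (nm).
#' @param ligand_elements Elements counted as ligating.
#' @param rmsd_max Angle-RMSD threshold (degrees).
#' @param box Optional box lengths (nm) for minimum-image distances.
#' @return A `coordination_assignment`: `label`, `angle_rmsd` (degrees),
#'   `ligands` (tibble `atom`, `resid`, `resname`, `name`, `distance`).
#' @export
assign_geometry <- function(coords, system, ion_idx, cutoff = 0.35,
                            ligand_elements = c("N", "O"), rmsd_max = 20,
                            box = NULL) {
  coords <- as.matrix(coords)
  a <- system$atoms
  d <- sweep(coords, 2, coords[ion_idx, ])
  if (!is.null(box)) for (k in 1:3) d[, k] <- .min_image(d[, k], box[k])
  r <- sqrt(rowSums(d^2))
  lig <- which(r <= cutoff & toupper(a$element) %in% toupper(ligand_elements) &
                 seq_len(nrow(a)) != ion_idx & a$domain != "ion")
  ligands <- tibble::tibble(atom = lig, resid = a$resid[lig],
                            resname = a$resname[lig], name = a$name[lig],
                            distance = r[lig])
  not_coord <- function(msg_rmsd = NA_real_) {
    structure(list(label = "not-coordinated", angle_rmsd = msg_rmsd,
                   ligands = ligands), class = "coordination_assignment")
  }
  k <- length(lig)
  if (k < 2) return(not_coord())
  dirs <- .unit_rows(d[lig, , drop = FALSE])
  obs <- sort(.pairwise_angles(dirs))
  best <- list(label = NA_character_, rmsd = Inf)
  for (nm in names(.geometry_templates())) {
    tpl <- .geometry_templates()[[nm]]
    m <- nrow(tpl)
    if (m != k && m != k + 1) next   # exact count or one vacancy
    perms <- .permutations(m, k)
    tpl_ang_cache <- NULL
    for (p in seq_len(nrow(perms))) {
      sub <- tpl[perms[p, ], , drop = FALSE]
      ta <- sort(.pairwise_angles(sub))
      rmsd <- sqrt(mean((obs - ta)^2)) * 180 / pi
      if (rmsd < best$rmsd) best <- list(label = nm, rmsd = rmsd)
    }
  }
  if (!is.finite(best$rmsd) || best$rmsd > rmsd_max) return(not_coord(best$rmsd))
  structure(list(label = best$label, angle_rmsd = best$rmsd, ligands = ligands),
            class = "coordination_assignment")
}

#' @export
print.coordination_assignment <- function(x, ...) {
  cat(sprintf("<coordination_assignment> %s (angle RMSD %.1f deg), %d ligand(s)\n",
              x$label, x$angle_rmsd, nrow(x$ligands)))
  invisible(x)
}

#' Ion-to-atom distance statistics
#'
#' Mean and sd of minimum-image distances between an ion and listed atoms
#' over all frames; single-frame trajectories give the crystal-structure
#' distances with sd 0.
#'
#' @param traj A `trajectory`.
#' @param system A `molecular_system`.
#' @param ion_idx Ion atom index.
#' @param atom_idx Indices of partner atoms.
#' @return Tibble `atom`, `resid`, `resname`, `name`, `mean`, `sd` (nm).
#' @export
ion_site_distances <- function(traj, system, ion_idx, atom_idx) {
  a <- system$atoms
  if (length(atom_idx) == 0) stop("no atoms given")
  nf <- n_frames(traj)
  dmat <- matrix(NA_real_, nf, length(atom_idx))
  for (f in seq_len(nf)) {
    dmat[f, ] <- .pair_dists(traj, f, ion_idx, atom_idx)
  }
  tibble::tibble(atom = atom_idx, resid = a$resid[atom_idx],
                 resname = a$resname[atom_idx], name = a$name[atom_idx],
                 mean = colMeans(dmat),
                 sd = if (nf > 1) apply(dmat, 2, stats::sd) else rep(0, length(atom_idx)))
}

#' MMPBSA-style binding report for an ion
#'
#' Assembles the per-ion free-energy budget: molecular-mechanics van der
#' Waals and electrostatic means, continuum polar and nonpolar solvation
#' means, the interaction entropy, the enthalpic sum
#' \eqn{\Delta E_{bind} = \Delta E_{vdw} + \Delta E_{elec} +
#' \Delta G_{polar} + \Delta G_{nonpolar}} and
#' \eqn{\Delta G_{bind} = \Delta E_{bind} + (-T\Delta S)}, each with a
#' bootstrap standard error.
#'
#' @param energy An `energy_series` from [interaction_energy()].
#' @param solvation Tibble from [solvation_terms()] (same frames), or NULL
#'   to omit solvation terms (treated as zero).
#' @param temperature Temperature (K).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @param label Row label (e.g. `"Zn ion 1"`).
#' @return A `binding_report` tibble: one row with `ion`, `e_vdw`, `e_elec`,
#'   `g_polar`, `g_nonpolar`, `minus_TdS`, `e_binding`, `g_binding` and
#'   matching `*_se` columns.
#' @export
binding_report <- function(energy, solvation = NULL, temperature = 310,
                           n_boot = 5000, seed = 1, label = "ion") {
  s <- energy$series
  gp <- if (is.null(solvation)) rep(0, nrow(s)) else solvation$g_polar
  gn <- if (is.null(solvation)) rep(0, nrow(s)) else solvation$g_nonpolar
  total_bind <- s$lj + s$coulomb + gp + gn
  ie <- interaction_entropy(s$total, temperature)
  set.seed(seed)
  n <- nrow(s)
  boot <- matrix(NA_real_, n_boot, 6)
  for (bb in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[bb, ] <- c(mean(s$lj[idx]), mean(s$coulomb[idx]), mean(gp[idx]),
                    mean(gn[idx]), interaction_entropy(s$total[idx], temperature),
                    mean(total_bind[idx]))
  }
  se <- apply(boot, 2, stats::sd)
  out <- tibble::tibble(
    ion = label,
    e_vdw = mean(s$lj), e_vdw_se = se[1],
    e_elec = mean(s$coulomb), e_elec_se = se[2],
    g_polar = mean(gp), g_polar_se = se[3],
    g_nonpolar = mean(gn), g_nonpolar_se = se[4],
    minus_TdS = ie, minus_TdS_se = se[5],
    e_binding = mean(total_bind), e_binding_se = se[6],
    g_binding = mean(total_bind) + ie, g_binding_se = se[6]
  )
  class(out) <- c("binding_report", class(out))
  out
}

#' Significant residue contributions by Tukey-fence outlier analysis
#'
#' Applies Tukey's fences to the per-residue mean interaction energies of a
#' decomposed [interaction_energy()] result: residues whose mean
#' contribution lies at or beyond a fence are the statistically significant
#' interactors (`k = 1.5`), extreme ones additionally flagged at `k = 3`.
#'
#' @param energy A decomposed `energy_series`.
#' @param k,k_extreme Fence multipliers.
#' @return Tibble `resid`, `energy` (mean kJ/mol), `significant`, `extreme`,
#'   with fence bounds as attributes `fences` and `fences_extreme`.
#' @export
significant_residues <- function(energy, k = 1.5, k_extreme = 3) {
  if (is.null(energy$per_residue)) stop("energy series has no per-residue decomposition")
  means <- colMeans(energy$per_residue)
  f1 <- tukey_fences(means, k)
  f3 <- tukey_fences(means, k_extreme)
  out <- tibble::tibble(resid = energy$residues, energy = as.numeric(means),
                        significant = f1$outlier, extreme = f3$outlier)
  attr(out, "fences") <- c(f1$lower, f1$upper)
  attr(out, "fences_extreme") <- c(f3$lower, f3$upper)
  out
}
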