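# Synthetic trajectory generators with planted ground truth. These emulate
# the statistical structure of a metalloprotein simulation (multi-state
# backbone dynamics, rigid-body domain motion, an ion in a pocket of
# LJ+Coulomb sites, solvent shells around an ion) without being an MD engine.

.unit_rows <- function(m) m / sqrt(rowSums(m^2))

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Place atom D for every frame given positions A, B, C (F x 3), bond length r
# (C-D), bond angle theta at C (B-C-D) and torsion tau (A-B-C-D), radians.
.nerf_place <- function(A, B, C, r, theta, tau) {
  bc <- .unit_rows(C - B)
  n <- .unit_rows(.cross_rows(B - A, bc))
  m <- .cross_rows(n, bc)
  C + r * (-cos(theta) * bc + sin(theta) * cos(tau) * m + sin(theta) * sin(tau) * n)
}

# Backbone geometry (nm / degrees): standard peptide internal coordinates.
.bb <- list(b_n_ca = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329,
            a_n_ca_c = 111.0 * pi / 180, a_ca_c_n = 116.6 * pi / 180,
            a_c_n_ca = 121.9 * pi / 180, omega = pi)

#' Build backbone coordinates from phi/psi series
#'
#' Constructs an N-CA-C polyalanine-like backbone for every frame from
#' per-frame phi/psi dihedrals by sequential internal-coordinate (NeRF)
#' placement, vectorised over frames. Omega is fixed trans.
#'
#' @param phi,psi Matrices `n_frames x n_res` of dihedrals (radians). `phi`
#'   of the first residue and `psi` of the last are ignored (undefined).
#' @return Array `n_frames x (3 n_res) x 3` of coordinates (nm); atom order
#'   N, CA, C per residue.
#' @export
build_backbone <- function(phi, psi) {
  stopifnot(all(dim(phi) == dim(psi)))
  nf <- nrow(phi); nres <- ncol(phi)
  coords <- array(NA_real_, c(nf, 3 * nres, 3))
  one <- function(v) matrix(rep(v, each = nf), nf, 3)
  # First residue: N at origin, CA on x, C in the xy-plane.
  N1 <- one(c(0, 0, 0))
  CA1 <- one(c(.bb$b_n_ca, 0, 0))
  C1 <- one(c(.bb$b_n_ca - .bb$b_ca_c * cos(.bb$a_n_ca_c),
              .bb$b_ca_c * sin(.bb$a_n_ca_c), 0))
  coords[, 1, ] <- N1; coords[, 2, ] <- CA1; coords[, 3, ] <- C1
  A <- N1; B <- CA1; C <- C1
  for (i in seq_len(nres - 1)) {
    Nn <- .nerf_place(A, B, C, .bb$b_c_n, .bb$a_ca_c_n, psi[, i])
    CAn <- .nerf_place(B, C, Nn, .bb$b_n_ca, .bb$a_c_n_ca, rep(.bb$omega, nf))
    Cn <- .nerf_place(C, Nn, CAn, .bb$b_ca_c, .bb$a_n_ca_c, phi[, i + 1])
    j <- 3 * i
    coords[, j + 1, ] <- Nn; coords[, j + 2, ] <- CAn; coords[, j + 3, ] <- Cn
    A <- Nn; B <- CAn; C <- Cn
  }
  coords
}

.backbone_system <- function(nres) {
  molecular_system(tibble::tibble(
    serial = seq_len(3 * nres),
    name = rep(c("N", "CA", "C"), nres),
    element = rep(c("N", "C", "C"), nres),
    resid = rep(seq_len(nres), each = 3),
    resname = "ALA",
    chain = "A",
    domain = "other"
  ))
}

# Wrap angles to (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Synthetic multi-state backbone-dihedral trajectory
#'
#' Samples a hidden conformational state per frame from `populations`, then
#' draws each residue's phi/psi from a wrapped normal around that state's
#' mean dihedrals, and builds backbone coordinates. The per-frame state
#' labels are the planted ground truth for dPCA/clustering recovery tests.
#'
#' @param n_frames Number of frames.
#' @param populations State probabilities, summing to 1.
#' @param state_phi,state_psi Matrices `K x n_res` of state-mean dihedrals
#'   (radians). Defaults: a helix-like and an extended state over 6 residues
#'   for `K <= 2`.
#' @param jitter_sd Wrapped-normal jitter (radians), scalar.
#' @param dt Frame spacing (ns).
#' @param seed RNG seed (recorded in the output).
#' @return List with `system`, `traj`, `labels` (integer states per frame),
#'   `spec` (the generating parameters).
#' @export
gen_dihedral_states <- function(n_frames = 1000, populations = c(0.9, 0.1),
                                state_phi = NULL, state_psi = NULL,
                                jitter_sd = 0.15, dt = 0.1, seed = 1) {
  if (abs(sum(populations) - 1) > 1e-8) stop("populations must sum to 1")
  if (n_frames < 1) stop("n_frames must be >= 1")
  K <- length(populations)
  if (is.null(state_phi)) {
    base <- rbind(rep(-57, 6), rep(-140, 6), rep(60, 6))[seq_len(K), , drop = FALSE]
    state_phi <- base * pi / 180
  }
  if (is.null(state_psi)) {
    base <- rbind(rep(-47, 6), rep(150, 6), rep(45, 6))[seq_len(K), , drop = FALSE]
    state_psi <- base * pi / 180
  }
  stopifnot(nrow(state_phi) == K, all(dim(state_phi) == dim(state_psi)))
  nres <- ncol(state_phi)
  set.seed(seed)
  labels <- sample.int(K, n_frames, replace = TRUE, prob = populations)
  jit <- function(mu) wrap_angle(mu[labels, , drop = FALSE] +
                                   matrix(stats::rnorm(n_frames * nres, 0, jitter_sd),
                                          n_frames, nres))
  phi <- jit(state_phi)
  psi <- jit(state_psi)
  coords <- build_backbone(phi, psi)
  list(system = .backbone_system(nres),
       traj = trajectory(coords, times = dt * (seq_len(n_frames) - 1)),
       labels = labels,
       spec = list(scenario = "dihedral_states", n_frames = n_frames,
                   populations = populations, jitter_sd = jitter_sd,
                   dt = dt, seed = seed))
}

#' Synthetic rigid-domain motion trajectory
#'
#' Builds `length(modes)` rigid pseudo-domains of C-alpha beads. Domains with
#' mode `"+"` translate along the inter-domain (y) axis following one shared
#' standard-normal series, `"-"` in anti-phase, `"0"` each follow an
#' independent series. Isotropic thermal noise is added per bead. The planted
#' pairwise correlation-sign matrix (+1 / -1 / 0) is returned as ground
#' truth. The displacements are planted in the lab frame, so recover them
#' with `covariance_matrix(..., fit = FALSE)`; a superposition fit would
#' absorb part of the planted rigid-body motion into the reference frame.
#'
#' @param n_frames Number of frames.
#' @param modes Character vector over domains, entries `"+"`, `"-"`, `"0"`.
#' @param beads_per_domain Beads per domain.
#' @param amplitude Rigid-motion amplitude (nm, sd of the collective shift).
#' @param noise_sd Per-bead isotropic thermal noise sd (nm).
#' @param dt Frame spacing (ns).
#' @param seed RNG seed.
#' @return List with `system`, `traj`, `sign_matrix` (domains x domains),
#'   `domain_of_bead`, `spec`.
#' @export
gen_domain_motion <- function(n_frames = 2000, modes = c("+", "-"),
                              beads_per_domain = 16, amplitude = 0.3,
                              noise_sd = 0.03, dt = 0.1, seed = 1) {
  stopifnot(all(modes %in% c("+", "-", "0")), length(modes) >= 2)
  set.seed(seed)
  nd <- length(modes)
  nb <- beads_per_domain
  # beads on a 4-spaced grid per domain, domains offset 3 nm apart in y
  grid_n <- ceiling(nb^(1 / 3))
  g <- as.matrix(expand.grid(x = seq_len(grid_n), y = seq_len(grid_n),
                             z = seq_len(grid_n)))[seq_len(nb), , drop = FALSE] * 0.4
  base <- do.call(rbind, lapply(seq_len(nd), function(d) {
    sweep(g, 2, c(0, 3 * (d - 1), 0), `+`)
  }))
  domain_of_bead <- rep(seq_len(nd), each = nb)
  shared <- stats::rnorm(n_frames)
  coeff <- c(`+` = 1, `-` = -1, `0` = 0)[modes]
  series <- matrix(0, n_frames, nd)
  for (d in seq_len(nd)) {
    series[, d] <- if (coeff[d] != 0) coeff[d] * shared else stats::rnorm(n_frames)
  }
  coords <- array(0, c(n_frames, nd * nb, 3))
  for (d in seq_len(nd)) {
    idx <- which(domain_of_bead == d)
    shift <- amplitude * series[, d]
    for (k in 1:3) {
      disp <- if (k == 2) shift else 0
      coords[, idx, k] <- matrix(base[idx, k], n_frames, nb, byrow = TRUE) + disp
    }
  }
  coords <- coords + array(stats::rnorm(length(coords), 0, noise_sd), dim(coords))
  sign_matrix <- outer(coeff, coeff)
  diag(sign_matrix) <- 1
  atoms <- tibble::tibble(
    serial = seq_len(nd * nb), name = "CA", element = "C",
    resid = seq_len(nd * nb), resname = "GLY", chain = "A",
    domain = paste0("D", domain_of_bead)
  )
  list(system = molecular_system(atoms),
       traj = trajectory(coords, times = dt * (seq_len(n_frames) - 1)),
       sign_matrix = sign_matrix, domain_of_bead = domain_of_bead,
       spec = list(scenario = "domain_motion", n_frames = n_frames,
                   modes = modes, amplitude = amplitude, noise_sd = noise_sd,
                   dt = dt, seed = seed))
}

#' Naive-loop ion-site nonbonded energy (reference oracle)
#'
#' Deliberately plain double-loop Lennard-Jones + Coulomb sum, sharing no
#' code with the vectorised [interaction_energy()]; it exists to serve as
#' that function's independent oracle. Lorentz-Berthelot combination rules;
#' no periodic imaging (the pocket is assumed whole).
#'
#' @param ion_xyz Length-3 ion position (nm).
#' @param sites Data frame `x`, `y`, `z`, `q`, `sigma`, `epsilon`.
#' @param ion_q,ion_sigma,ion_epsilon Ion parameters (e, nm, kJ/mol).
#' @return Named vector `lj`, `coulomb`, `total` (kJ/mol).
#' @export
naive_ion_energy <- function(ion_xyz, sites, ion_q, ion_sigma, ion_epsilon) {
  f <- 138.935458
  e_lj <- 0; e_coul <- 0
  for (j in seq_len(nrow(sites))) {
    dx <- ion_xyz[1] - sites$x[j]
    dy <- ion_xyz[2] - sites$y[j]
    dz <- ion_xyz[3] - sites$z[j]
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    sij <- (ion_sigma + sites$sigma[j]) / 2
    eij <- sqrt(ion_epsilon * sites$epsilon[j])
    if (eij > 0) {
      sr6 <- (sij / r)^6
      e_lj <- e_lj + 4 * eij * (sr6 * sr6 - sr6)
    }
    e_coul <- e_coul + f * ion_q * sites$q[j] / r
  }
  c(lj = e_lj, coulomb = e_coul, total = e_lj + e_coul)
}

#' Synthetic ion-in-pocket trajectory with oracle energies
#'
#' One divalent ion moves among fixed charged Lennard-Jones sites. Positions
#' are sampled either from an isotropic Gaussian about `center` or by
#' Metropolis sampling of the nonbonded energy at temperature `T`. The exact
#' per-frame energy is computed here by a naive double loop, independent of
#' the vectorised energetics module, and returned as the oracle.
#'
#' @param n_frames Number of recorded frames.
#' @param sites Data frame of fixed sites: `x,y,z` (nm), `q` (e), `sigma`
#'   (nm), `epsilon` (kJ/mol), optional `resid`, `resname`, `name`. Default:
#'   a 6-site octahedral pocket of carboxylate-like oxygens at 0.25 nm.
#' @param ion Named list `q`, `sigma`, `epsilon` (defaults: Zn-like +2).
#' @param sampling `"gaussian"` or `"metropolis"`.
#' @param center,spread Gaussian sampling centre (nm) and sd (nm).
#' @param temperature Metropolis temperature (K).
#' @param step Metropolis proposal sd (nm).
#' @param burnin Discarded initial Metropolis sweeps.
#' @param box Cubic box edge (nm).
#' @param dt Frame spacing (ns).
#' @param seed RNG seed.
#' @return List with `system` (sites then ion as last atom), `traj`,
#'   `energies` (tibble `frame`, `lj`, `coulomb`, `total` in kJ/mol from the
#'   naive oracle), `spec`.
#' @export
gen_ion_pocket <- function(n_frames = 1000, sites = NULL,
                           ion = list(q = 2, sigma = 0.2264664541, epsilon = 0.0138191662),
                           sampling = c("gaussian", "metropolis"),
                           center = c(0, 0, 0), spread = 0.05,
                           temperature = 310, step = 0.02, burnin = 200,
                           box = 4, dt = 0.1, seed = 1) {
  sampling <- match.arg(sampling)
  set.seed(seed)
  if (is.null(sites)) {
    d <- 0.25
    sites <- tibble::tibble(
      x = c(d, -d, 0, 0, 0, 0), y = c(0, 0, d, -d, 0, 0),
      z = c(0, 0, 0, 0, d, -d),
      q = -0.5, sigma = 0.302, epsilon = 0.502
    )
  }
  sites <- tibble::as_tibble(sites)
  if (!"resid" %in% names(sites)) sites$resid <- seq_len(nrow(sites))
  if (!"resname" %in% names(sites)) sites$resname <- "ASP"
  if (!"name" %in% names(sites)) sites$name <- "OD1"
  ns <- nrow(sites)
  energy <- function(p) naive_ion_energy(p, sites, ion$q, ion$sigma, ion$epsilon)
  ion_pos <- matrix(NA_real_, n_frames, 3)
  if (sampling == "gaussian") {
    i <- 1
    while (i <= n_frames) {
      p <- center + stats::rnorm(3, 0, spread)
      rmin <- sqrt(min((p[1] - sites$x)^2 + (p[2] - sites$y)^2 + (p[3] - sites$z)^2))
      if (rmin < 0.05) next  # overlap: reject and resample
      ion_pos[i, ] <- p
      i <- i + 1
    }
  } else {
    RT <- 8.314462618e-3 * temperature
    p <- center
    e <- energy(p)["total"]
    total_steps <- burnin + n_frames
    k <- 0
    for (s in seq_len(total_steps)) {
      cand <- p + stats::rnorm(3, 0, step)
      rmin <- sqrt(min((cand[1] - sites$x)^2 + (cand[2] - sites$y)^2 +
                         (cand[3] - sites$z)^2))
      if (rmin >= 0.05) {
        ec <- energy(cand)["total"]
        if (stats::runif(1) < exp(min(0, -(ec - e) / RT))) {
          p <- cand; e <- ec
        }
      }
      if (s > burnin) {
        k <- k + 1
        ion_pos[k, ] <- p
      }
    }
  }
  energies <- t(apply(ion_pos, 1, energy))
  site_atoms <- tibble::tibble(
    serial = seq_len(ns), name = sites$name, element = substr(sites$name, 1, 1),
    resid = sites$resid, resname = sites$resname, chain = "A",
    charge = sites$q, sigma = sites$sigma, epsilon = sites$epsilon,
    domain = "Cat"
  )
  ion_atom <- tibble::tibble(
    serial = ns + 1L, name = "ZN", element = "ZN", resid = max(sites$resid) + 1L,
    resname = "ZN", chain = "A", charge = ion$q, sigma = ion$sigma,
    epsilon = ion$epsilon, domain = "ion"
  )
  sys <- molecular_system(dplyr::bind_rows(site_atoms, ion_atom))
  coords <- array(NA_real_, c(n_frames, ns + 1, 3))
  for (k in 1:3) {
    coords[, seq_len(ns), k] <-
      matrix(as.matrix(sites[, c("x", "y", "z")])[, k], n_frames, ns, byrow = TRUE)
  }
  coords[, ns + 1, ] <- ion_pos
  list(system = sys,
       traj = trajectory(coords, times = dt * (seq_len(n_frames) - 1),
                         box = rep(box, 3)),
       energies = tibble::tibble(frame = seq_len(n_frames),
                                 lj = energies[, "lj"],
                                 coulomb = energies[, "coulomb"],
                                 total = energies[, "total"]),
       spec = list(scenario = "ion_pocket", n_frames = n_frames,
                   sampling = sampling, temperature = temperature,
                   spread = spread, seed = seed))
}

#' Synthetic hydration-shell trajectory
#'
#' A central divalent ion with solvent-oxygen points placed in spherical
#' shells of given mean radius, width and occupancy, plus an optional
#' uniform ideal-gas background, in a periodic cubic box. Fractional
#' occupancies are realised per frame as floor + Bernoulli; shell slots
#' unoccupied in a frame are parked on a distant sphere (0.45 box) so the
#' atom count stays constant.
#'
#' @param n_frames Number of frames.
#' @param shells Data frame `radius` (nm), `width` (nm sd), `occupancy`
#'   (mean molecules per frame); `NULL` for none.
#' @param background_density Ideal-gas background number density (nm^-3); 0
#'   for none.
#' @param box Cubic box edge (nm).
#' @param dt Frame spacing (ns).
#' @param seed RNG seed.
#' @return List with `system` (ion first, then oxygens), `traj`, `spec`.
#' @export
gen_hydration_shells <- function(n_frames = 500, shells = NULL,
                                 background_density = 0, box = 3, dt = 0.1,
                                 seed = 1) {
  set.seed(seed)
  if (!is.null(shells)) {
    shells <- tibble::as_tibble(shells)
    if (any(shells$radius >= box / 2)) stop("shell radius exceeds half box")
  }
  n_shell_slots <- if (is.null(shells)) integer(0) else ceiling(shells$occupancy)
  n_bg <- round(background_density * box^3)
  n_ox <- sum(n_shell_slots) + n_bg
  if (n_ox == 0) stop("no solvent: give shells or a background density")
  coords <- array(NA_real_, c(n_frames, 1 + n_ox, 3))
  center <- rep(box / 2, 3)
  coords[, 1, ] <- matrix(center, n_frames, 3, byrow = TRUE)
  rand_dirs <- function(n) {
    v <- matrix(stats::rnorm(3 * n), n, 3)
    .unit_rows(v)
  }
  for (f in seq_len(n_frames)) {
    pos <- matrix(NA_real_, n_ox, 3)
    at <- 0
    if (!is.null(shells)) {
      for (s in seq_len(nrow(shells))) {
        slots <- n_shell_slots[s]
        occ <- shells$occupancy[s]
        n_here <- floor(occ) + stats::rbinom(1, 1, occ - floor(occ))
        u <- rand_dirs(slots)
        r <- abs(stats::rnorm(slots, shells$radius[s], shells$width[s]))
        r[r < 0.02] <- 0.02
        if (n_here < slots) r[(n_here + 1):slots] <- 0.45 * box  # parked
        pos[at + seq_len(slots), ] <- sweep(u * r, 2, center, `+`)
        at <- at + slots
      }
    }
    if (n_bg > 0) {
      pos[at + seq_len(n_bg), ] <- matrix(stats::runif(3 * n_bg, 0, box), n_bg, 3)
    }
    coords[f, -1, ] <- pos
  }
  atoms <- tibble::tibble(
    serial = seq_len(1 + n_ox),
    name = c("ZN", rep("OW", n_ox)),
    element = c("ZN", rep("O", n_ox)),
    resid = seq_len(1 + n_ox),
    resname = c("ZN", rep("SOL", n_ox)),
    chain = "A",
    charge = c(2, rep(0, n_ox)),
    domain = c("ion", rep("solvent", n_ox))
  )
  list(system = molecular_system(atoms),
       traj = trajectory(coords, times = dt * (seq_len(n_frames) - 1),
                         box = rep(box, 3)),
       spec = list(scenario = "hydration_shells", n_frames = n_frames,
                   shells = if (is.null(shells)) NULL else as.list(shells),
                   background_density = background_density, box = box,
                   seed = seed))
}

#' Write a synthetic scenario bundle to disk
#'
#' Writes the system + first frame as PDB, the trajectory as DCD, and the
#' planted ground truth (spec, labels, energies, sign matrix — whatever the
#' generator produced) as JSON sidecar.
#'
#' @param bundle A list returned by one of the `gen_*()` generators.
#' @param dir Output directory (created if needed).
#' @param name Scenario file stem; defaults to the generator's scenario name.
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir, name = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  name <- name %||% bundle$spec$scenario
  pdb <- file.path(dir, paste0(name, ".pdb"))
  dcd <- file.path(dir, paste0(name, ".dcd"))
  json <- file.path(dir, paste0(name, "_truth.json"))
  write_trajectory_pdb(bundle$traj, bundle$system, pdb, frames = 1)
  write_trajectory_dcd(bundle$traj, dcd)
  truth <- bundle[setdiff(names(bundle), c("system", "traj"))]
  jsonlite::write_json(truth, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(pdb = pdb, dcd = dcd, truth = json))
}
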