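# Backbone dihedral extraction, dihedral PCA, free-energy landscapes,
# conformational-family clustering, Schlitter configurational entropy.

# Torsion angle of four atom-position matrices (F x 3 each), radians in
# (-pi, pi], by the atan2 formulation.
.torsion_rows <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- .cross_rows(b1, b2)
  n2 <- .cross_rows(b2, b3)
  b2u <- .unit_rows(b2)
  x <- rowSums(n1 * n2)
  y <- rowSums(.cross_rows(n1, n2) * b2u)
  atan2(y, x)
}

#' Extract phi/psi backbone dihedral series
#'
#' Computes per-frame phi (C[i-1]-N-CA-C) and psi (N-CA-C-N[i+1]) for every
#' residue in `resid_range` that has complete backbone atoms. The first
#' residue of a chain has no phi, the last no psi; residues flanking chain
#' breaks (non-consecutive numbering) are likewise skipped on the broken
#' side. Angles are wrapped to (-pi, pi].
#'
#' @param traj A `trajectory`.
#' @param system A `molecular_system` with N/CA/C backbone atoms.
#' @param resid_range Length-2 integer vector (inclusive); default all.
#' @return A `dihedral_series`: list with `resid`, `phi` and `psi`
#'   (`n_frames x n_res` matrices with NA for undefined angles).
#' @export
extract_dihedrals <- function(traj, system, resid_range = NULL) {
  a <- system$atoms
  bb <- which(a$name %in% c("N", "CA", "C") & a$domain != "solvent")
  res <- sort(unique(a$resid[bb]))
  if (!is.null(resid_range)) res <- res[res >= resid_range[1] & res <= resid_range[2]]
  idx_of <- function(rid, nm) {
    i <- which(a$resid == rid & a$name == nm)
    if (length(i) == 1) i else NA_integer_
  }
  nf <- n_frames(traj)
  phi <- matrix(NA_real_, nf, length(res))
  psi <- matrix(NA_real_, nf, length(res))
  P <- function(i) matrix(traj$coords[, i, ], ncol = 3)
  for (k in seq_along(res)) {
    rid <- res[k]
    iN <- idx_of(rid, "N"); iCA <- idx_of(rid, "CA"); iC <- idx_of(rid, "C")
    if (any(is.na(c(iN, iCA, iC)))) next
    iCp <- if ((rid - 1) %in% res) idx_of(rid - 1, "C") else NA_integer_
    iNn <- if ((rid + 1) %in% res) idx_of(rid + 1, "N") else NA_integer_
    if (!is.na(iCp)) phi[, k] <- .torsion_rows(P(iCp), P(iN), P(iCA), P(iC))
    if (!is.na(iNn)) psi[, k] <- .torsion_rows(P(iN), P(iCA), P(iC), P(iNn))
  }
  structure(list(resid = res, phi = phi, psi = psi), class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("<dihedral_series> %d frames x %d residues (%d..%d)\n",
              nrow(x$phi), length(x$resid), min(x$resid), max(x$resid)))
  invisible(x)
}

#' Dihedral principal component analysis
#'
#' Embeds every defined dihedral as (cos, sin) — removing angular
#' periodicity — and diagonalises the covariance of the embedded,
#' mean-centred frame vectors. Constant input yields all-zero eigenvalues,
#' not an error.
#'
#' @param dihedrals A `dihedral_series` (or a plain numeric matrix of angles,
#'   frames x angles, radians).
#' @return A `pc_model`: `mean`, `vectors` (columns, orthonormal), `values`
#'   (descending, >= 0), `projections` (frames x components, centred),
#'   `var_fraction`.
#' @export
dpca <- function(dihedrals) {
  if (inherits(dihedrals, "dihedral_series")) {
    ang <- cbind(dihedrals$phi, dihedrals$psi)
  } else {
    ang <- as.matrix(dihedrals)
  }
  ang <- ang[, colSums(is.na(ang)) == 0, drop = FALSE]
  if (nrow(ang) < 2) stop("dPCA needs at least 2 frames")
  X <- cbind(cos(ang), sin(ang))
  .pc_model_from_data(X)
}

.pc_model_from_data <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- stats::cov(Xc)
  eg <- eigen(C, symmetric = TRUE)
  values <- pmax(eg$values, 0)
  vectors <- eg$vectors
  proj <- Xc %*% vectors
  tot <- sum(values)
  structure(list(mean = mu, vectors = vectors, values = values,
                 projections = proj,
                 var_fraction = if (tot > 0) values / tot else rep(0, length(values))),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  k <- min(5, length(x$values))
  cat(sprintf("<pc_model> %d frames, %d dims; leading variance fractions: %s\n",
              nrow(x$projections), length(x$values),
              paste(sprintf("%.3f", x$var_fraction[seq_len(k)]), collapse = " ")))
  invisible(x)
}

#' Free-energy landscape over two principal components
#'
#' Bins the projections on a regular 2-D grid and converts bin probabilities
#' to free energies relative to the most populated bin:
#' \eqn{\Delta G = -RT \ln(\rho_{xy}/\rho_{max})}. Empty bins carry
#' `Inf` (the free energy is undefined at zero density).
#'
#' @param pc A `pc_model` (or a 2-column matrix of projections).
#' @param components Which two components to use.
#' @param grid Number of bins per axis.
#' @param temperature Temperature (K).
#' @param pad Fractional range padding on each side.
#' @return A `fel` object: tibble `grid` (`x`, `y` bin centres, `count`,
#'   `prob`, `dG` kJ/mol), plus `x_breaks`, `y_breaks`, `temperature`,
#'   `bin_of_frame` (grid row index per frame).
#' @export
free_energy_landscape <- function(pc, components = c(1, 2), grid = 100,
                                  temperature = 310, pad = 0.01) {
  stopifnot(temperature > 0)
  P <- if (inherits(pc, "pc_model")) pc$projections[, components, drop = FALSE]
       else as.matrix(pc)
  if (nrow(P) == 0) stop("empty projections")
  rng <- function(v) {
    r <- range(v); w <- diff(r); if (w == 0) w <- 1
    c(r[1] - pad * w, r[2] + pad * w)
  }
  xb <- seq(rng(P[, 1])[1], rng(P[, 1])[2], length.out = grid + 1)
  yb <- seq(rng(P[, 2])[1], rng(P[, 2])[2], length.out = grid + 1)
  ix <- findInterval(P[, 1], xb, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(P[, 2], yb, rightmost.closed = TRUE, all.inside = TRUE)
  bin <- (iy - 1L) * grid + ix
  counts <- tabulate(bin, nbins = grid * grid)
  prob <- counts / sum(counts)
  RT <- iondyn_constants$R_kj * temperature
  dG <- ifelse(prob > 0, -RT * log(prob / max(prob)), Inf)
  centers_x <- (xb[-1] + xb[-length(xb)]) / 2
  centers_y <- (yb[-1] + yb[-length(yb)]) / 2
  gr <- tibble::tibble(
    x = rep(centers_x, times = grid),
    y = rep(centers_y, each = grid),
    count = counts, prob = prob, dG = dG
  )
  structure(list(grid = gr, x_breaks = xb, y_breaks = yb,
                 temperature = temperature, bin_of_frame = bin),
            class = "fel")
}

#' @export
print.fel <- function(x, ...) {
  occ <- sum(x$grid$count > 0)
  cat(sprintf("<fel> %d x %d grid at T = %g K; %d occupied bins; max dG %.2f kJ/mol\n",
              length(x$x_breaks) - 1, length(x$y_breaks) - 1, x$temperature,
              occ, max(x$grid$dG[is.finite(x$grid$dG)])))
  invisible(x)
}

#' K-means clustering with silhouette diagnostics
#'
#' Best-of-`n_init` k-means (Hartigan-Wong via [stats::kmeans()]) with
#' Euclidean silhouettes. For large inputs silhouettes are computed on a
#' deterministic subsample of `max_sil_n` points (the O(n^2) distance matrix
#' is otherwise prohibitive); SSE and assignments always use all points.
#'
#' @param points Numeric matrix (n x d) of coordinates (e.g. dPC1/dPC2
#'   projections).
#' @param k Number of clusters (>= 1, <= n).
#' @param n_init Random restarts.
#' @param seed RNG seed; the result is deterministic given it.
#' @param max_sil_n Silhouette subsample ceiling.
#' @return A `cluster_model`: `k`, `assignments`, `centroids`, `sse`,
#'   `silhouette` (per-sampled-point widths or NULL for k = 1), `s_avg`,
#'   `sizes`, `seed`.
#' @export
kmeans_cluster <- function(points, k, n_init = 50, seed = 1, max_sil_n = 2000) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds number of points")
  set.seed(seed)
  if (k == 1) {
    centroid <- matrix(colMeans(points), 1)
    sse <- sum(sweep(points, 2, centroid)^2)
    km <- list(cluster = rep(1L, n), centers = centroid, tot.withinss = sse)
  } else {
    km <- stats::kmeans(points, centers = k, nstart = n_init, iter.max = 200)
  }
  sil <- NULL; s_avg <- NA_real_
  if (k > 1) {
    take <- if (n > max_sil_n) sort(sample.int(n, max_sil_n)) else seq_len(n)
    sw <- cluster::silhouette(km$cluster[take], stats::dist(points[take, , drop = FALSE]))
    sil <- as.numeric(sw[, "sil_width"])
    s_avg <- mean(sil)
  }
  structure(list(k = k, assignments = as.integer(km$cluster),
                 centroids = km$centers, sse = km$tot.withinss,
                 silhouette = sil, s_avg = s_avg,
                 sizes = tabulate(km$cluster, k), seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, SSE = %.4g, S_avg = %s, sizes: %s\n",
              x$k, x$sse, ifelse(is.na(x$s_avg), "NA", sprintf("%.3f", x$s_avg)),
              paste(x$sizes, collapse = " ")))
  invisible(x)
}

#' Scan k for k-means model selection
#'
#' Runs [kmeans_cluster()] over a set of k values and reports SSE and the
#' average silhouette width per k. The silhouette coefficient SC is the
#' maximum S_avg over the scanned k.
#'
#' @param points Numeric matrix.
#' @param ks Integer vector of k values.
#' @inheritParams kmeans_cluster
#' @return Tibble `k`, `sse`, `s_avg`, with attribute `sc`.
#' @export
kmeans_scan <- function(points, ks = 1:8, n_init = 50, seed = 1,
                        max_sil_n = 2000) {
  rows <- lapply(ks, function(k) {
    cm <- kmeans_cluster(points, k, n_init = n_init, seed = seed,
                         max_sil_n = max_sil_n)
    tibble::tibble(k = k, sse = cm$sse, s_avg = cm$s_avg)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "sc") <- suppressWarnings(max(out$s_avg, na.rm = TRUE))
  out
}

#' Lowest-free-energy representative frame per cluster
#'
#' For each cluster, finds the occupied landscape bin of lowest free energy
#' among the cluster's member frames and returns the member frame in that
#' bin whose projection is closest to the cluster centroid. Optionally
#' writes each representative as a PDB snapshot.
#'
#' @param cluster A `cluster_model` fitted on the same projections as `fel`.
#' @param fel A `fel` from [free_energy_landscape()].
#' @param pc The `pc_model` (for centroid distances).
#' @param traj,system Optional: supply both (plus `dir`) to write PDB files.
#' @param dir Output directory for PDB snapshots.
#' @param components Components used for the landscape.
#' @return Tibble `cluster`, `frame`, `dG` (bin free energy, kJ/mol), `size`,
#'   and `file` when snapshots are written.
#' @export
extract_centroids <- function(cluster, fel, pc, traj = NULL, system = NULL,
                              dir = NULL, components = c(1, 2)) {
  if (length(fel$bin_of_frame) != length(cluster$assignments)) {
    stop("cluster and landscape were not computed on the same projections")
  }
  P <- pc$projections[, components, drop = FALSE]
  dG_of_bin <- fel$grid$dG
  rows <- lapply(seq_len(cluster$k), function(cl) {
    members <- which(cluster$assignments == cl)
    if (length(members) == 0) return(NULL)
    bins <- fel$bin_of_frame[members]
    best_bin <- bins[which.min(dG_of_bin[bins])]
    in_bin <- members[bins == best_bin]
    cen <- cluster$centroids[cl, , drop = FALSE]
    d2 <- rowSums(sweep(P[in_bin, , drop = FALSE], 2, as.numeric(cen))^2)
    tibble::tibble(cluster = cl, frame = in_bin[which.min(d2)],
                   dG = dG_of_bin[best_bin], size = length(members))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(traj) && !is.null(system) && !is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$file <- vapply(seq_len(nrow(out)), function(i) {
      f <- file.path(dir, sprintf("centroid_cluster%02d.pdb", out$cluster[i]))
      write_trajectory_pdb(traj, system, f, frames = out$frame[i])
      f
    }, character(1))
  }
  out
}

#' Schlitter configurational entropy as a function of time
#'
#' Computes the quasi-harmonic upper-bound entropy of Schlitter,
#' \eqn{S \le \frac{R}{2} \ln\det(1 + \frac{k_B T e^2}{\hbar^2} M^{1/2} C M^{1/2})},
#' on the mass-weighted coordinate covariance of the growing window
#' `[t_min, t]` for each requested window end. Frames are superposed on the
#' window's converged mean before the covariance is formed. A rise-then-
#' plateau profile signals equilibration.
#'
#' @param traj A `trajectory`.
#' @param selection Atom indices (e.g. the C-alpha trace).
#' @param masses Per-atom masses (amu) over the selection; default carbon.
#' @param temperature Temperature (K).
#' @param window_ends Window end times (ns); default 10 evenly spaced.
#' @param fit Superpose frames on the window mean first (default TRUE); use
#'   FALSE when coordinates are already in a common frame.
#' @return Tibble `time` (ns), `entropy` (kJ mol^-1 K^-1), `n_frames`.
#' @export
configurational_entropy_series <- function(traj, selection = NULL, masses = NULL,
                                           temperature = 310, window_ends = NULL,
                                           fit = TRUE) {
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[2])
  if (length(selection) == 0) stop("empty selection")
  if (is.null(masses)) masses <- rep(12.011, length(selection))
  if (is.null(window_ends)) {
    window_ends <- stats::quantile(traj$times, probs = seq(0.1, 1, by = 0.1),
                                   names = FALSE, type = 7)
  }
  out <- lapply(window_ends, function(tend) {
    frames <- which(traj$times <= tend)
    if (length(frames) < 2) {
      return(tibble::tibble(time = tend, entropy = 0, n_frames = length(frames)))
    }
    sub <- subset_trajectory(traj, frames = frames)
    tibble::tibble(time = tend,
                   entropy = schlitter_entropy(sub, selection, masses, temperature,
                                               fit = fit),
                   n_frames = length(frames))
  })
  dplyr::bind_rows(out)
}

#' Schlitter entropy of a trajectory window
#'
#' @inheritParams configurational_entropy_series
#' @return Entropy in kJ mol^-1 K^-1.
#' @export
schlitter_entropy <- function(traj, selection = NULL, masses = NULL,
                              temperature = 310, fit = TRUE) {
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[2])
  if (is.null(masses)) masses <- rep(12.011, length(selection))
  coords <- if (fit) {
    mean_structure(traj, selection)$fitted$coords
  } else {
    traj$coords[, selection, , drop = FALSE]
  }
  X <- .flatten_frames(coords)                     # F x 3n, nm
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / nrow(Xc)                    # population covariance, nm^2
  cc <- iondyn_constants
  alpha <- cc$kB_J * temperature * exp(2) / cc$hbar_J^2  # 1/(kg m^2)
  m_kg <- rep(masses, each = 3) * cc$amu_kg
  Mh <- sqrt(m_kg)
  Cw <- (Mh %o% Mh) * C * 1e-18                    # kg m^2
  ev <- eigen(Cw, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  0.5 * cc$R_kj * sum(log1p(alpha * ev))
}

.flatten_frames <- function(coords) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  out <- matrix(NA_real_, nf, 3 * na)
  for (k in 1:3) out[, seq(k, 3 * na, by = 3)] <- coords[, , k]
  out
}

#' Detect the equilibration time from an entropy profile
#'
#' First window end after which the Schlitter entropy changes by less than
#' `tol` (relative) over the next `span` windows.
#'
#' @param entropy_series Tibble from [configurational_entropy_series()].
#' @param tol Relative change threshold.
#' @param span Number of consecutive quiet windows required.
#' @return Time (ns), or the last window end if no plateau is found.
#' @export
detect_equilibration <- function(entropy_series, tol = 0.01, span = 3) {
  s <- entropy_series$entropy
  t <- entropy_series$time
  n <- length(s)
  for (i in seq_len(max(0, n - span))) {
    seg <- s[i:(i + span)]
    if (all(abs(diff(seg)) <= tol * pmax(abs(seg[-length(seg)]), 1e-12))) {
      return(t[i])
    }
  }
  t[n]
}

#' Free-energy gap between two basins of a landscape
#'
#' Estimates the basin-to-basin free-energy difference from a landscape and
#' a frame partition (e.g. k-means assignments): each basin's modal bin is
#' located and the occupation of the `(2 pool + 1)^2` block around it pooled
#' before Boltzmann inversion — pooling suppresses the max-statistics bias a
#' single-bin estimate suffers at finite sampling.
#'
#' @param fel A `fel` from [free_energy_landscape()].
#' @param assignments Integer basin label per frame (two or more basins).
#' @param basins Which two labels to compare (default the two largest).
#' @param pool Neighbourhood half-width in bins.
#' @return Free-energy gap (kJ/mol, >= 0) between the two basin modes.
#' @export
fel_basin_gap <- function(fel, assignments, basins = NULL, pool = 1) {
  grid <- length(fel$x_breaks) - 1
  cnt <- matrix(fel$grid$count, grid, grid)
  if (is.null(basins)) {
    basins <- as.integer(names(sort(table(assignments), decreasing = TRUE)))[1:2]
  }
  pooled <- function(lab) {
    bins <- unique(fel$bin_of_frame[assignments == lab])
    b <- bins[which.max(fel$grid$count[bins])]
    ix <- (b - 1) %% grid + 1
    iy <- (b - 1) %/% grid + 1
    xs <- max(1, ix - pool):min(grid, ix + pool)
    ys <- max(1, iy - pool):min(grid, iy + pool)
    sum(cnt[xs, ys])
  }
  RT <- iondyn_constants$R_kj * fel$temperature
  abs(RT * log(pooled(basins[1]) / pooled(basins[2])))
}
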