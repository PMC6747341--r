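#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` with optional
#' per-atom weights (e.g. masses). Only proper rotations (det = +1) are
#' allowed, so mirror images do not superpose to zero.
#'
#' @param mobile,reference `n x 3` coordinate matrices (nm), `n >= 3`,
#'   non-collinear.
#' @param weights Per-atom weights; default unit weights.
#' @return List with `rotation` (3x3), `translation` (length 3; the transform
#'   is `coords %*% rotation + translation`), `rmsd` (nm, weighted), and
#'   `transformed` (the superposed mobile coordinates).
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be equal-sized n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 atoms")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0) stop("bad weights")
  wn <- w / sum(w)
  cm <- colSums(mobile * wn)
  cr <- colSums(reference * wn)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  if (qr(P)$rank < 2 || qr(Q)$rank < 2) {
    stop("degenerate geometry: collinear or coincident points")
  }
  H <- t(P * wn) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # coords %*% t(R) rotates row vectors; express as coords %*% rotation
  rotation <- t(R)
  transformed <- sweep(P %*% rotation, 2, cr, `+`)
  rmsd <- sqrt(sum(wn * rowSums((transformed - reference)^2)))
  list(rotation = rotation,
       translation = cr - as.numeric(cm %*% rotation),
       rmsd = rmsd, transformed = transformed)
}

#' Iteratively converged average structure
#'
#' Superposes every frame onto a running mean and recomputes the mean until
#' it moves less than `tol`; this is the reference conformation used for RMSD
#' and RMSF ("deviation from the average sampled conformation").
#'
#' @param traj A `trajectory`.
#' @param selection Atom indices used for fitting (default all atoms).
#' @param weights Per-atom fit weights over the selection.
#' @param max_iter,tol Iteration control (nm).
#' @return List with `mean` (`n_sel x 3` matrix) and `fitted` trajectory of
#'   the selection superposed on it.
#' @export
mean_structure <- function(traj, selection = NULL, weights = NULL,
                           max_iter = 10, tol = 1e-6) {
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[2])
  if (length(selection) == 0) stop("empty selection")
  sub <- traj$coords[, selection, , drop = FALSE]
  nf <- dim(sub)[1]
  ref <- matrix(sub[1, , ], ncol = 3)
  fitted <- sub
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(nf)) {
      fitted[i, , ] <- superpose(matrix(sub[i, , ], ncol = 3), ref,
                                 weights = weights)$transformed
    }
    new_ref <- apply(fitted, c(2, 3), mean)
    shift <- sqrt(max(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (shift < tol) break
  }
  list(mean = ref, fitted = trajectory(fitted, times = traj$times, box = traj$box))
}

#' Per-frame RMSD to the average structure
#'
#' @param traj A `trajectory`.
#' @param selection Atom indices (e.g. the C-alpha trace); default all.
#' @param reference Optional `n_sel x 3` reference; default the iteratively
#'   converged average structure of the selection.
#' @param weights Optional per-atom weights.
#' @return A tibble with columns `time` (ns) and `rmsd` (nm).
#' @export
rmsd_series <- function(traj, selection = NULL, reference = NULL, weights = NULL) {
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[2])
  if (length(selection) == 0) stop("empty selection")
  ms <- mean_structure(traj, selection, weights = weights)
  ref <- if (is.null(reference)) ms$mean else as.matrix(reference)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    superpose(traj$coords[i, selection, , drop = TRUE], ref, weights = weights)$rmsd
  }, numeric(1))
  tibble::tibble(time = traj$times, rmsd = vals)
}

#' Per-residue (or per-atom) root mean square fluctuation
#'
#' Frames are superposed onto the converged mean of `fit_selection` (default:
#' the measured selection itself); RMSF is then the square root of the
#' time-mean squared deviation of each atom from its time-mean position. Use
#' a protein C-alpha `fit_selection` with an ion `selection` to measure ion
#' RMSF relative to the protein frame.
#'
#' @param traj A `trajectory`.
#' @param system A `molecular_system` (for residue aggregation); optional.
#' @param selection Atom indices measured.
#' @param fit_selection Atom indices used for the superposition fit.
#' @param weights Fit weights over `fit_selection`.
#' @return A tibble with `atom`, `resid`, `rmsf` (nm); one row per selected
#'   atom, plus attribute `per_residue` (tibble `resid`, `rmsf` with atomic
#'   MSFs averaged within each residue).
#' @export
rmsf_per_residue <- function(traj, system = NULL, selection = NULL,
                             fit_selection = NULL, weights = NULL) {
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[2])
  if (length(selection) == 0) stop("empty selection")
  if (is.null(fit_selection)) fit_selection <- selection
  nf <- n_frames(traj)
  ms <- mean_structure(traj, fit_selection, weights = weights)
  # apply each frame's fit transform to the measured selection
  dev2 <- matrix(0, nf, length(selection))
  fitted <- array(NA_real_, c(nf, length(selection), 3))
  for (i in seq_len(nf)) {
    tr <- superpose(traj$coords[i, fit_selection, , drop = TRUE], ms$mean,
                    weights = weights)
    fitted[i, , ] <- sweep(traj$coords[i, selection, , drop = FALSE][1, , ] %*%
                             tr$rotation, 2, tr$translation, `+`)
  }
  mean_pos <- apply(fitted, c(2, 3), mean)
  for (i in seq_len(nf)) {
    dev2[i, ] <- rowSums((matrix(fitted[i, , ], ncol = 3) - mean_pos)^2)
  }
  rmsf <- sqrt(colMeans(dev2))
  resid <- if (!is.null(system)) system$atoms$resid[selection] else selection
  out <- tibble::tibble(atom = selection, resid = resid, rmsf = rmsf)
  per_res <- dplyr::summarise(dplyr::group_by(out, .data$resid),
                              rmsf = sqrt(mean(.data$rmsf^2)), .groups = "drop")
  attr(out, "per_residue") <- per_res
  out
}

#' Per-frame radius of gyration
#'
#' @param traj A `trajectory`.
#' @param selection Atom indices; default all.
#' @param masses Per-atom masses over the selection; unit masses if `NULL`
#'   and `mass_weighted = FALSE`.
#' @param mass_weighted Weight by mass (default) or treat atoms equally.
#' @return A tibble with `time` (ns) and `rg` (nm).
#' @export
radius_of_gyration <- function(traj, selection = NULL, masses = NULL,
                               mass_weighted = TRUE) {
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[2])
  if (length(selection) == 0) stop("empty selection")
  n <- length(selection)
  w <- if (mass_weighted && !is.null(masses)) masses else rep(1, n)
  w <- w / sum(w)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- matrix(traj$coords[i, selection, ], ncol = 3)
    com <- colSums(x * w)
    sqrt(sum(w * rowSums(sweep(x, 2, com)^2)))
  }, numeric(1))
  tibble::tibble(time = traj$times, rg = vals)
}

#' Per-frame centre-of-mass distance between two selections
#'
#' Computed on coordinates as stored (assumed whole/unwrapped); no periodic
#' wrapping is applied across a molecule.
#'
#' @param traj A `trajectory`.
#' @param selection_a,selection_b Atom index vectors, non-empty.
#' @param masses_a,masses_b Optional per-atom masses (default unit).
#' @return A tibble with `time` (ns) and `distance` (nm).
#' @export
com_distance <- function(traj, selection_a, selection_b,
                         masses_a = NULL, masses_b = NULL) {
  if (length(selection_a) == 0 || length(selection_b) == 0) stop("empty selection")
  wa <- if (is.null(masses_a)) rep(1, length(selection_a)) else masses_a
  wb <- if (is.null(masses_b)) rep(1, length(selection_b)) else masses_b
  wa <- wa / sum(wa); wb <- wb / sum(wb)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    ca <- colSums(matrix(traj$coords[i, selection_a, ], ncol = 3) * wa)
    cb <- colSums(matrix(traj$coords[i, selection_b, ], ncol = 3) * wb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  tibble::tibble(time = traj$times, distance = vals)
}

#' Minimum distance between a selection and its nearest periodic image
#'
#' Checks all 26 neighbouring image translations of an orthorhombic box per
#' frame. For a single atom this is the shortest box edge.
#'
#' @param traj A `trajectory` with box information.
#' @param selection Atom indices; default all.
#' @return A tibble with `time` (ns) and `distance` (nm).
#' @export
min_periodic_distance <- function(traj, selection = NULL) {
  if (is.null(traj$box)) stop("missing box: trajectory has no periodic cell")
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[2])
  if (length(selection) == 0) stop("empty selection")
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- matrix(traj$coords[i, selection, ], ncol = 3)
    L <- traj$box[i, ]
    best <- Inf
    for (s in seq_len(nrow(shifts))) {
      img <- sweep(x, 2, shifts[s, ] * L, `+`)
      d2 <- .cross_min_dist2(x, img)
      best <- min(best, d2)
    }
    sqrt(best)
  }, numeric(1))
  tibble::tibble(time = traj$times, distance = vals)
}

.cross_min_dist2 <- function(a, b) {
  # min squared distance between rows of a and rows of b
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * a %*% t(b)
  min(pmax(d2, 0))
}
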