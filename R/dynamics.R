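# Cartesian covariance, dynamic cross-correlation, PCA of the C-alpha trace.

#' Cartesian covariance matrix of a selection
#'
#' Frames are superposed on the converged mean structure of the selection
#' (set `fit = FALSE` to analyse lab-frame displacements, e.g. when global
#' motion is itself the signal), coordinates centred, and the 3N x 3N
#' covariance formed (population normalisation, 1/N over frames).
#'
#' @param traj A `trajectory`.
#' @param selection Atom indices; default all.
#' @param weights Superposition weights.
#' @param fit Superpose frames on the mean structure first (default TRUE).
#' @return A symmetric positive-semidefinite `3N x 3N` matrix (nm^2) with
#'   attribute `fitted` (the superposed selection trajectory) and `mean`.
#' @export
covariance_matrix <- function(traj, selection = NULL, weights = NULL,
                              fit = TRUE) {
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[2])
  if (length(selection) == 0) stop("empty selection")
  if (fit) {
    ms <- mean_structure(traj, selection, weights = weights)
  } else {
    sub <- traj$coords[, selection, , drop = FALSE]
    ms <- list(mean = apply(sub, c(2, 3), mean),
               fitted = trajectory(sub, times = traj$times, box = traj$box))
  }
  X <- .flatten_frames(ms$fitted$coords)
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / nrow(Xc)
  attr(C, "fitted") <- ms$fitted
  attr(C, "mean") <- ms$mean
  C
}

#' Dynamic cross-correlation matrix
#'
#' Pearson correlation of atomic displacement vectors,
#' \eqn{c_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#' \sqrt{\langle \Delta r_i^2 \rangle \langle \Delta r_j^2 \rangle}}.
#' Atoms with zero fluctuation get NA rows and are listed in the `flagged`
#' attribute rather than propagating NaN silently; an all-static input is an
#' error.
#'
#' @param cov A `3N x 3N` covariance from [covariance_matrix()].
#' @param resid Optional residue ids for labelling (length N).
#' @return A `dccm` object: `matrix` (N x N, entries in `[-1, 1]`, diagonal
#'   1), `resid`, `flagged`.
#' @export
dccm <- function(cov, resid = NULL) {
  n3 <- nrow(cov)
  if (n3 %% 3 != 0) stop("covariance must be 3N x 3N")
  n <- n3 / 3
  dot <- matrix(0, n, n)
  for (k in 1:3) {
    idx <- seq(k, n3, by = 3)
    dot <- dot + cov[idx, idx]
  }
  msf <- diag(dot)
  if (all(msf <= 0)) stop("no fluctuations: all atoms are static")
  flagged <- which(msf <= 0)
  denom <- sqrt(msf %o% msf)
  m <- dot / denom
  m[flagged, ] <- NA_real_
  m[, flagged] <- NA_real_
  ok <- is.finite(m)
  m[ok] <- pmin(pmax(m[ok], -1), 1)
  dd <- diag(m)
  dd[setdiff(seq_len(n), flagged)] <- 1
  diag(m) <- dd
  structure(list(matrix = m,
                 resid = resid %||% seq_len(n),
                 flagged = flagged),
            class = "dccm")
}

#' @export
print.dccm <- function(x, ...) {
  cat(sprintf("<dccm> %d x %d; %d static atom(s) flagged\n",
              nrow(x$matrix), ncol(x$matrix), length(x$flagged)))
  invisible(x)
}

#' Mean cross-correlation between two residue blocks
#'
#' @param dccm A `dccm` object.
#' @param block_a,block_b Integer indices (rows of the matrix) for the two
#'   blocks.
#' @return Mean Pearson coefficient over the inter-block entries.
#' @export
dccm_block_mean <- function(dccm, block_a, block_b) {
  mean(dccm$matrix[block_a, block_b], na.rm = TRUE)
}

#' Cartesian principal component analysis of domain motions
#'
#' Eigendecomposition of the superposed-coordinate covariance. Variance
#' fractions are reported both over all modes and over internal modes only
#' (the 6 smallest eigenvalues — the rigid-body residual left by the
#' superposition — excluded from the denominator). Per-PC RMSF profiles are
#' the per-atom fluctuation of the trajectory reconstructed from that single
#' component.
#'
#' @param cov Covariance from [covariance_matrix()] (carries the fitted
#'   trajectory).
#' @param n_components How many leading components to project and profile.
#' @return A `cartesian_pc` object: `values`, `vectors`, `var_fraction`
#'   (all-mode), `var_fraction_internal`, `projections`
#'   (frames x n_components), `pc_rmsf` (tibble `atom`, `component`, `rmsf`).
#' @export
cartesian_pca <- function(cov, n_components = 5) {
  fitted <- attr(cov, "fitted")
  if (is.null(fitted)) stop("covariance lacks the fitted trajectory attribute")
  eg <- eigen(cov, symmetric = TRUE)
  values <- pmax(eg$values, 0)
  vectors <- eg$vectors
  n3 <- length(values)
  n_components <- min(n_components, n3)
  tot <- sum(values)
  n_int <- max(1, n3 - 6)
  tot_int <- sum(values[seq_len(n_int)])
  X <- .flatten_frames(fitted$coords)
  Xc <- sweep(X, 2, colMeans(X))
  proj <- Xc %*% vectors[, seq_len(n_components), drop = FALSE]
  n_atoms <- n3 / 3
  pc_rmsf <- dplyr::bind_rows(lapply(seq_len(n_components), function(p) {
    rec <- outer(proj[, p], vectors[, p])    # frames x 3N single-PC reconstruction
    msf_xyz <- colMeans(rec^2)
    msf_atom <- vapply(seq_len(n_atoms), function(a) {
      sum(msf_xyz[(3 * (a - 1) + 1):(3 * a)])
    }, numeric(1))
    tibble::tibble(atom = seq_len(n_atoms), component = p, rmsf = sqrt(msf_atom))
  }))
  structure(list(values = values, vectors = vectors,
                 var_fraction = if (tot > 0) values / tot else values,
                 var_fraction_internal =
                   if (tot_int > 0) c(values[seq_len(n_int)] / tot_int,
                                      rep(0, n3 - n_int)) else values,
                 projections = proj, pc_rmsf = pc_rmsf),
            class = "cartesian_pc")
}

#' @export
print.cartesian_pc <- function(x, ...) {
  k <- min(5, length(x$values))
  cat(sprintf("<cartesian_pc> first %d variance fractions (internal): %s; cumulative %.1f%%\n",
              k, paste(sprintf("%.3f", x$var_fraction_internal[seq_len(k)]), collapse = " "),
              100 * sum(x$var_fraction_internal[seq_len(k)])))
  invisible(x)
}
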