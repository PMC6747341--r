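#' Trajectory container
#'
#' Coordinates are stored as an array `[frame, atom, xyz]` in nm, with frame
#' times in ns and per-frame orthorhombic box lengths (nm) when periodic
#' boundary information is available.
#'
#' @param coords Numeric array `n_frames x n_atoms x 3` (nm), or a single
#'   `n_atoms x 3` matrix for a one-frame trajectory.
#' @param times Numeric vector of frame times (ns), strictly increasing.
#'   Defaults to `0, 1, 2, ...`.
#' @param box `NULL`, a length-3 vector (constant box), or an
#'   `n_frames x 3` matrix of box lengths (nm).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, times = NULL, box = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  nf <- dim(coords)[1]
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
    stopifnot(nrow(box) == nf, ncol(box) == 3)
  }
  structure(list(coords = coords, times = as.numeric(times), box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %.4g..%.4g ns%s\n",
              n_frames(x), dim(x$coords)[2], min(x$times), max(x$times),
              if (is.null(x$box)) "" else ", periodic"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an `n_atoms x 3` matrix
#' @param traj A `trajectory`.
#' @param i Frame index.
#' @return Matrix of coordinates (nm).
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Subset a trajectory
#' @param traj A `trajectory`.
#' @param frames Integer frame indices (default all).
#' @param atoms Integer atom indices (default all).
#' @return A `trajectory`.
#' @export
subset_trajectory <- function(traj, frames = NULL, atoms = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (is.null(atoms)) atoms <- seq_len(dim(traj$coords)[2])
  trajectory(traj$coords[frames, atoms, , drop = FALSE],
             times = traj$times[frames],
             box = if (!is.null(traj$box)) traj$box[frames, , drop = FALSE])
}

#' Keep only frames at or after an equilibration cutoff
#' @param traj A `trajectory`.
#' @param cutoff_ns Time (ns); frames with `t >= cutoff_ns` are kept.
#' @return A `trajectory`.
#' @export
equilibrated_window <- function(traj, cutoff_ns) {
  keep <- which(traj$times >= cutoff_ns)
  if (length(keep) == 0) stop("no frames at or after t = ", cutoff_ns, " ns")
  subset_trajectory(traj, frames = keep)
}

#' Load a coordinate trajectory
#'
#' Supports multi-model PDB (`.pdb`, parsed with \pkg{bio3d}) and DCD
#' (`.dcd`, read with [bio3d::read.dcd()]). Coordinates are converted from
#' Angstrom to nm. Frame times default to `dt * (0:(n-1))`.
#'
#' @param traj_file Path to the trajectory file.
#' @param system A `molecular_system`; atom counts must match.
#' @param dt Time between frames (ns) used when the format stores none.
#' @return A `trajectory`.
#' @export
load_trajectory <- function(traj_file, system, dt = 1) {
  if (!file.exists(traj_file)) stop("trajectory file not found: ", traj_file)
  ext <- tolower(tools::file_ext(traj_file))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(traj_file, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nf <- nrow(xyz)
    na <- ncol(xyz) / 3
    coords <- array(NA_real_, c(nf, na, 3))
    for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3), drop = FALSE] / 10
    box <- .read_cryst1(traj_file)
  } else if (ext == "dcd") {
    hdr <- .read_dcd_header(traj_file)
    xyz <- bio3d::read.dcd(traj_file, cell = FALSE, verbose = FALSE)
    nf <- nrow(xyz)
    na <- ncol(xyz) / 3
    coords <- array(NA_real_, c(nf, na, 3))
    for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3), drop = FALSE] / 10
    box <- NULL
    if (hdr$has_cell) {
      cell <- bio3d::read.dcd(traj_file, cell = TRUE, verbose = FALSE)
      box <- cell[, 1:3, drop = FALSE] / 10
    }
  } else {
    stop("unreadable trajectory format: .", ext,
         " (supported: multi-model PDB, DCD)")
  }
  if (na != n_atoms(system)) {
    stop(sprintf("atom-count mismatch: trajectory has %d, system has %d",
                 na, n_atoms(system)))
  }
  trajectory(coords, times = dt * (seq_len(nf) - 1), box = box)
}

.read_dcd_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "integer", 1, size = 4)
  readChar(con, 4, useBytes = TRUE)
  icntrl <- readBin(con, "integer", 20, size = 4)
  list(has_cell = icntrl[11] == 1)
}

#' Write a trajectory as CHARMM-style DCD
#'
#' Coordinates are written in Angstrom (the conventional DCD unit) as
#' single-precision floats; the round trip through [load_trajectory()] is
#' exact to float precision (~1e-5 nm). Orthorhombic box lengths are stored
#' in the unit-cell records when present.
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- dim(traj$coords)[2]
  has_cell <- !is.null(traj$box)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L
  rec <- function(writer) {
    # Fortran unformatted record: byte count, payload, byte count
    raw_payload <- writer()
    writeBin(length(raw_payload), con, size = 4)
    writeBin(raw_payload, con)
    writeBin(length(raw_payload), con, size = 4)
  }
  rec(function() c(charToRaw("CORD"), writeBin(icntrl, raw(), size = 4)))
  title <- sprintf("%-80s", "iondyn trajectory")
  rec(function() c(writeBin(1L, raw(), size = 4), charToRaw(title)))
  rec(function() writeBin(as.integer(na), raw(), size = 4))
  for (i in seq_len(nf)) {
    if (has_cell) {
      b <- traj$box[i, ] * 10
      # XTLABC lower-triangle order: a, gamma, b, beta, alpha, c (cosines 0 => 90 deg)
      rec(function() writeBin(as.numeric(c(b[1], 0, b[2], 0, 0, b[3])),
                              raw(), size = 8))
    }
    for (k in 1:3) {
      v <- as.numeric(traj$coords[i, , k] * 10)
      rec(function() writeBin(v, raw(), size = 4))
    }
  }
  invisible(path)
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj A `trajectory`.
#' @param system A `molecular_system` supplying atom identities.
#' @param path Output path.
#' @param frames Frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, system, path, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  a <- system$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$box)) {
    b <- traj$box[frames[1], ] * 10
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       b[1], b[2], b[3]), con)
  }
  het <- .is_nonprotein(a)
  rectype <- ifelse(het, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  for (m in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frame_coords(traj, frames[m]) * 10
    lines <- sprintf("%s%5d %s %-3s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     rectype, a$serial %% 100000, name4,
                     substr(a$resname, 1, 3), substr(a$chain, 1, 1), a$resid %% 10000,
                     xyz[, 1], xyz[, 2], xyz[, 3], toupper(a$element))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
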