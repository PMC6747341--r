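# Ion hydration analysis: radial distribution function, shell occupancy
# probabilities, coordination numbers, Shrake-Rupley SASA.

# Minimum-image displacement components for an orthorhombic box.
.min_image <- function(d, L) d - L * round(d / L)

# Per-frame minimum-image distances from one centre atom to target atoms.
.pair_dists <- function(traj, frame, center_idx, target_idx) {
  x <- frame_coords(traj, frame)
  L <- if (!is.null(traj$box)) traj$box[frame, ] else NULL
  d <- sweep(x[target_idx, , drop = FALSE], 2, x[center_idx, ])
  if (!is.null(L)) for (k in 1:3) d[, k] <- .min_image(d[, k], L[k])
  sqrt(rowSums(d^2))
}

#' Radial distribution function around a centre selection
#'
#' Standard shell-volume-normalised g(r) of target atoms around centre
#' atoms, averaged over frames and centres, with minimum-image distances.
#' The reference density is the mean target number density
#' \eqn{\rho_0 = N_{target}/\langle V_{box}\rangle}. Also records, per radial
#' bin edge, the per-frame probability that at least one target lies within
#' r of a centre (the shell "statistical density" of Table-4-style
#' summaries) and the mean cumulative neighbour count.
#'
#' @param traj A `trajectory` with periodic box.
#' @param center_sel,target_sel Atom index vectors.
#' @param bin_width Bin width (nm).
#' @param r_max Maximum radius (nm); must not exceed half the smallest box
#'   edge.
#' @return An `rdf_profile`: tibble `profile` (`r` bin centres, `g`,
#'   `occupancy` = P(>=1 target within r), `mean_count`), `rho0` (nm^-3),
#'   `bin_width`, `n_frames`.
#' @export
rdf <- function(traj, center_sel, target_sel, bin_width = 0.002, r_max = NULL) {
  if (is.null(traj$box)) stop("rdf needs periodic box information")
  if (length(center_sel) == 0 || length(target_sel) == 0) stop("empty selection")
  half_min <- min(traj$box) / 2
  if (is.null(r_max)) r_max <- half_min
  if (r_max > half_min + 1e-9) {
    stop(sprintf("r_max (%.3f nm) exceeds half the smallest box edge (%.3f nm)",
                 r_max, half_min))
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  nf <- n_frames(traj)
  nc <- length(center_sel)
  # per-frame-and-centre cumulative counts, for occupancy and direct CN
  cum_ge1 <- numeric(nb)
  cum_sum <- numeric(nb)
  vols <- numeric(nf)
  for (f in seq_len(nf)) {
    vols[f] <- prod(traj$box[f, ])
    for (ci in center_sel) {
      r <- .pair_dists(traj, f, ci, target_sel)
      r <- r[r < r_max]
      b <- findInterval(r, edges, rightmost.closed = TRUE, all.inside = TRUE)
      counts <- counts + tabulate(b, nbins = nb)
      cc <- cumsum(tabulate(b, nbins = nb))
      cum_ge1 <- cum_ge1 + (cc >= 1)
      cum_sum <- cum_sum + cc
    }
  }
  rho0 <- length(target_sel) / mean(vols)
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  g <- counts / (nf * nc) / (shell_vol * rho0)
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  structure(list(profile = tibble::tibble(r = centers, g = g,
                                          occupancy = cum_ge1 / (nf * nc),
                                          mean_count = cum_sum / (nf * nc)),
                 rho0 = rho0, bin_width = bin_width, n_frames = nf,
                 edges = edges),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  pk <- x$profile$r[which.max(x$profile$g)]
  cat(sprintf("<rdf_profile> %d bins to %.3f nm; rho0 = %.4g nm^-3; main peak at %.3f nm\n",
              nrow(x$profile), max(x$profile$r), x$rho0, pk))
  invisible(x)
}

#' Locate hydration-shell peaks and troughs of a g(r) profile
#'
#' Local maxima/minima of a lightly smoothed g(r) (running mean over
#' `smooth` bins).
#'
#' @param profile An `rdf_profile`.
#' @param smooth Half-width (bins) of the running-mean smoother.
#' @param min_g Peaks below this g value are ignored.
#' @return Tibble `type` ("peak"/"trough"), `r`, `g`.
#' @export
shell_boundaries <- function(profile, smooth = 3, min_g = 0.5) {
  p <- profile$profile
  g <- stats::filter(p$g, rep(1 / (2 * smooth + 1), 2 * smooth + 1), sides = 2)
  g <- as.numeric(g)
  n <- length(g)
  rows <- list()
  for (i in seq(smooth + 2, n - smooth - 1)) {
    if (is.na(g[i - 1]) || is.na(g[i + 1])) next
    if (g[i] > g[i - 1] && g[i] >= g[i + 1] && g[i] > min_g) {
      rows[[length(rows) + 1]] <- tibble::tibble(type = "peak", r = p$r[i], g = g[i])
    } else if (g[i] < g[i - 1] && g[i] <= g[i + 1] &&
               length(rows) > 0 && rows[[length(rows)]]$type[nrow(rows[[length(rows)]])] == "peak") {
      rows[[length(rows) + 1]] <- tibble::tibble(type = "trough", r = p$r[i], g = g[i])
    }
  }
  dplyr::bind_rows(rows)
}

#' Shell occupancy probability ("statistical density")
#'
#' The probability that at least one target atom lies within `r` of the
#' centre at a sampled frame — the prose definition of the shell statistical
#' density (the literal \eqn{\int_0^r g\,dr} integral is not a probability
#' dimensionally and is exposed separately via [density_integral()]).
#' Probability of occupying the annulus between two radii is available by
#' giving `r_inner`.
#'
#' @param profile An `rdf_profile`.
#' @param r Outer radius (nm).
#' @param r_inner Optional inner radius for an annulus.
#' @return Probability in `[0, 1]`.
#' @export
shell_density <- function(profile, r, r_inner = NULL) {
  p <- profile$profile
  if (r < 0 || r > max(profile$edges)) stop("r outside profile range")
  occ_at <- function(rr) {
    if (rr <= 0) return(0)
    i <- findInterval(rr + 1e-12, profile$edges) - 1L
    if (i < 1) 0 else p$occupancy[min(i, nrow(p))]
  }
  if (is.null(r_inner)) return(occ_at(r))
  # annulus occupancy from mean counts is not recoverable from cumulative
  # P(>=1); use the difference of mean counts capped to [0,1] as an estimate
  ci <- function(rr) {
    if (rr <= 0) return(0)
    i <- findInterval(rr + 1e-12, profile$edges) - 1L
    if (i < 1) 0 else p$mean_count[min(i, nrow(p))]
  }
  min(1, max(0, ci(r) - ci(r_inner)))
}

#' Raw radial integral of g(r)
#'
#' Trapezoid-rule \eqn{\int_0^r g(r')\,dr'}, the printed-form shell-density
#' integral; units nm.
#'
#' @param profile An `rdf_profile`.
#' @param r Upper limit (nm).
#' @return The integral value (nm).
#' @export
density_integral <- function(profile, r) {
  p <- profile$profile
  .trapz_to(p$r, p$g, r)
}

# Trapezoid integral of y(x) from 0 to r over bin-centre samples, with the
# endpoint value interpolated so the integral covers [0, r] exactly.
.trapz_to <- function(x, y, r) {
  keep <- x <= r
  xs <- c(0, x[keep]); ys <- c(0, y[keep])
  if (max(xs) < r) {
    yr <- stats::approx(x, y, xout = r, rule = 2)$y
    xs <- c(xs, r); ys <- c(ys, yr)
  }
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Coordination number by RDF integration
#'
#' \eqn{CN(r) = 4\pi\rho_0 \int_0^r g(r') r'^2 dr'} by the trapezoid rule,
#' with \eqn{\rho_0} the mean target density of the profile. The direct
#' per-frame neighbour count within `r` is returned alongside as a
#' cross-check (`count`); the two agree within quadrature error.
#'
#' @param profile An `rdf_profile`.
#' @param r Integration limit (nm), conventionally a trough radius.
#' @return List with `cn` (integral value), `count` (mean direct neighbour
#'   count), `rounded` (nearest integer to `cn`).
#' @export
coordination_number <- function(profile, r) {
  p <- profile$profile
  cn <- 4 * pi * profile$rho0 * .trapz_to(p$r, p$g * p$r^2, r)
  # mean_count[i] counts neighbours with distance < edges[i + 1]
  i <- findInterval(r + 1e-12, profile$edges) - 1L
  count <- if (i >= 1) p$mean_count[min(i, nrow(p))] else 0
  list(cn = cn, count = count, rounded = round(cn))
}

# Deterministic near-uniform sphere points (golden spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Classic probe-rolling SASA by rejection of surface points: each atom gets
#' `n_points` quasi-uniform points on its solvent-expanded sphere
#' (radius + probe); points inside any other context atom's expanded sphere
#' are buried. Radii are Bondi by element.
#'
#' @param coords `n x 3` coordinate matrix (nm) of all context atoms.
#' @param elements Character vector of elements (length n).
#' @param target Indices of atoms whose area is summed (default all).
#' @param probe Probe radius (nm).
#' @param n_points Surface points per atom.
#' @return List with `total` (nm^2 over `target`) and `per_atom` (tibble
#'   `atom`, `sasa`).
#' @export
sasa_frame <- function(coords, elements, target = NULL, probe = 0.14,
                       n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(elements) != n) stop("elements length must match coords")
  if (is.null(target)) target <- seq_len(n)
  radii <- .vdw_radius(elements) + probe
  sp <- .sphere_points(n_points)
  per <- vapply(target, function(i) {
    pts <- sweep(sp * radii[i], 2, coords[i, ], `+`)
    others <- setdiff(which(rowSums(sweep(coords, 2, coords[i, ])^2) <
                              (radii + radii[i])^2), i)
    acc <- rep(TRUE, n_points)
    for (j in others) {
      d2 <- rowSums(sweep(pts, 2, coords[j, ])^2)
      acc <- acc & d2 > radii[j]^2
      if (!any(acc)) break
    }
    4 * pi * radii[i]^2 * mean(acc)
  }, numeric(1))
  list(total = sum(per), per_atom = tibble::tibble(atom = target, sasa = per))
}

#' SASA of a selection along a trajectory
#'
#' Per-frame Shrake-Rupley SASA of `target_sel` in the context of
#' `context_sel` (default: everything that is not solvent), e.g. an ion's
#' exposure within the full solute.
#'
#' @param traj A `trajectory`.
#' @param system A `molecular_system` (elements for radii).
#' @param target_sel Atom indices measured.
#' @param context_sel Atom indices present as occluders (includes targets).
#' @param probe Probe radius (nm).
#' @param n_points Surface points per atom.
#' @return Tibble `time`, `sasa` (nm^2), with attribute `summary`
#'   (mean, sd).
#' @export
sasa_series <- function(traj, system, target_sel, context_sel = NULL,
                        probe = 0.14, n_points = 960) {
  if (length(target_sel) == 0) stop("empty selection")
  if (is.null(context_sel)) {
    context_sel <- which(system$atoms$domain != "solvent")
  }
  context_sel <- union(context_sel, target_sel)
  el <- system$atoms$element[context_sel]
  tpos <- match(target_sel, context_sel)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    sasa_frame(frame_coords(traj, f)[context_sel, , drop = FALSE], el,
               target = tpos, probe = probe, n_points = n_points)$total
  }, numeric(1))
  out <- tibble::tibble(time = traj$times, sasa = vals)
  attr(out, "summary") <- c(mean = mean(vals), sd = stats::sd(vals))
  out
}
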