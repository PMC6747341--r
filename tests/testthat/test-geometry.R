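test_that("superposition recovers rigid transforms and rejects mirrors", {
  set.seed(1)
  x <- matrix(rnorm(15), 5, 3)
  y <- random_rigid(x, seed = 2)
  fit <- superpose(y, x)
  expect_close(fit$rmsd, 0, 1e-10)
  expect_close(fit$transformed, x, 1e-9)
  expect_close(det(fit$rotation), 1, 1e-10)
  # reflection cannot be superposed to zero by a proper rotation
  mirror <- x %*% diag(c(-1, 1, 1))
  expect_gt(superpose(mirror, x)$rmsd, 0.1)
  expect_error(superpose(matrix(0, 5, 3), x), "degenerate")
  expect_error(superpose(x[1:2, ], x[1:2, ]), "at least 3")
})

test_that("superposition RMSD matches the bio3d Kabsch implementation", {
  set.seed(3)
  for (i in 1:5) {
    a <- matrix(rnorm(24), 8, 3)
    b <- a + matrix(rnorm(24, sd = 0.1), 8, 3)
    ours <- superpose(b, a)$rmsd
    ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    expect_close(ours, ref, 5e-4)  # bio3d reports 3 decimals
  }
})

test_that("RMSD is symmetric and invariant to global rigid motion", {
  set.seed(4)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.2), 10, 3)
  expect_close(superpose(a, b)$rmsd, superpose(b, a)$rmsd, 1e-10)
  expect_close(superpose(random_rigid(a, 5), random_rigid(b, 6))$rmsd,
               superpose(a, b)$rmsd, 1e-9)
})

test_that("rmsd_series is zero for static input and sees planted displacements", {
  x <- matrix(rnorm(30), 10, 3)
  static <- trajectory(array(rep(x, each = 4), c(4, 10, 3)))
  expect_close(rmsd_series(static)$rmsd, 0, 1e-9)
  # two-state trajectory: a 15/5 split with atom 1 displaced by d in the
  # minority state sits asymmetrically about the mean structure, giving two
  # distinct RMSD levels with the planted geometry
  d <- 0.4
  coords <- array(rep(x, each = 20), c(20, 10, 3))
  coords[16:20, 1, 1] <- coords[16:20, 1, 1] + d
  rs <- rmsd_series(trajectory(coords))$rmsd
  expect_equal(length(unique(round(rs, 6))), 2)
  # level ratio follows the displacement split: minority deviates ~3x more
  expect_close(max(rs) / min(rs), 3, 0.2)
})

test_that("RMSF matches the isotropic closed form and ranks loops above sheets", {
  set.seed(6)
  sigma <- 0.04
  base <- matrix(rnorm(60, sd = 2), 20, 3)
  nf <- 4000
  coords <- array(rep(base, each = nf), c(nf, 20, 3)) +
    array(rnorm(nf * 60, sd = sigma), c(nf, 20, 3))
  # rigid anchor atoms keep the fit clean
  coords[, 1:10, ] <- array(rep(base[1:10, ], each = nf), c(nf, 10, 3))
  r <- rmsf_per_residue(trajectory(coords), selection = 1:20,
                        fit_selection = 1:10)
  expect_close(mean(r$rmsf[11:20]), sigma * sqrt(3), 0.005)
  expect_close(r$rmsf[1:10], 0, 1e-9)
  expect_true(all(r$rmsf[11:20] > r$rmsf[1:10]))
})

test_that("radius of gyration matches closed forms and scales linearly", {
  # equilateral triangle, side 1: Rg = 1/sqrt(3)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  tr <- trajectory(tri)
  expect_close(radius_of_gyration(tr)$rg, 1 / sqrt(3), 1e-12)
  # single atom: 0
  expect_close(radius_of_gyration(trajectory(matrix(1, 1, 3)))$rg, 0, 1e-12)
  # invariance under rigid motion; linear under scaling
  expect_close(radius_of_gyration(trajectory(random_rigid(tri, 7)))$rg,
               1 / sqrt(3), 1e-9)
  expect_close(radius_of_gyration(trajectory(tri * 2.5))$rg,
               2.5 / sqrt(3), 1e-12)
  # mass weighting moves Rg toward the heavy atom
  rg_w <- radius_of_gyration(tr, masses = c(10, 1, 1))$rg
  expect_lt(rg_w, 1 / sqrt(3))
})

test_that("COM distance handles point masses and mass weighting", {
  coords <- array(0, c(2, 4, 3))
  coords[, 2, 1] <- 1     # atoms 1,2: unit apart on x
  coords[, 3, 1] <- 10; coords[, 4, 1] <- 12
  tr <- trajectory(coords)
  expect_close(com_distance(tr, 1, 2)$distance, 1, 1e-12)
  # group b = atoms 3,4 with masses 1,3 -> COM at 11.5
  d <- com_distance(tr, 1, c(3, 4), masses_b = c(1, 3))$distance
  expect_close(d, 11.5, 1e-12)
  expect_error(com_distance(tr, integer(0), 2), "empty")
})

test_that("periodic minimum distance matches the all-images brute force", {
  # single atom in a cubic box: shortest edge
  one <- trajectory(matrix(c(1, 1, 1), 1, 3), box = c(3, 4, 5))
  expect_close(min_periodic_distance(one)$distance, 3, 1e-12)
  # two-atom rod of length d centred in box L: L - d
  L <- 4; d <- 1.2
  rod <- trajectory(rbind(c(0, 0, 0), c(d, 0, 0)), box = c(L, L, L))
  expect_close(min_periodic_distance(rod)$distance, L - d, 1e-12)
  # random cluster vs naive oracle over all 26 shifts
  set.seed(8)
  x <- matrix(runif(18, 0, 1.2), 6, 3)
  tr <- trajectory(x, box = c(3, 3.5, 4))
  got <- min_periodic_distance(tr)$distance
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  naive <- Inf
  for (s in seq_len(nrow(shifts))) {
    img <- sweep(x, 2, shifts[s, ] * c(3, 3.5, 4), `+`)
    for (i in 1:6) for (j in 1:6) {
      naive <- min(naive, sqrt(sum((x[i, ] - img[j, ])^2)))
    }
  }
  expect_close(got, naive, 1e-12)
  expect_error(min_periodic_distance(trajectory(x)), "missing box")
})

test_that("sum of squared RMSF equals the covariance trace", {
  d <- gen_domain_motion(n_frames = 300, seed = 9)
  sel <- seq_len(n_atoms(d$system))
  r <- rmsf_per_residue(d$traj, d$system, sel)
  cv <- covariance_matrix(d$traj, sel)
  expect_close(sum(r$rmsf^2), sum(diag(cv)), 1e-8)
})
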