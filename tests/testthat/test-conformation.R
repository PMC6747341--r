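test_that("torsion extraction matches the atan2 closed form and bio3d", {
  # four points with analytic torsions 0 and 90 degrees
  sys <- toy_system()
  sq0 <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))   # cis, 0
  sq90 <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))  # +90
  tor <- iondyn:::.torsion_rows
  expect_close(tor(sq0[1, , drop = FALSE], sq0[2, , drop = FALSE],
                   sq0[3, , drop = FALSE], sq0[4, , drop = FALSE]), 0, 1e-10)
  expect_close(tor(sq90[1, , drop = FALSE], sq90[2, , drop = FALSE],
                   sq90[3, , drop = FALSE], sq90[4, , drop = FALSE]),
               pi / 2, 1e-10)
  # independent oracle on random quadruples
  set.seed(10)
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    ours <- tor(p[1, , drop = FALSE], p[2, , drop = FALSE],
                p[3, , drop = FALSE], p[4, , drop = FALSE])
    ref <- bio3d::torsion.xyz(as.vector(t(p))) * pi / 180
    expect_close(ours, ref, 1e-8)
  }
})

test_that("helical and extended backbones give their defining dihedrals", {
  g <- gen_dihedral_states(n_frames = 2, populations = 1, jitter_sd = 0, seed = 1)
  dh <- extract_dihedrals(g$traj, g$system)
  # interior residues of an ideal alpha-helix
  expect_close(dh$phi[1, 2:6] * 180 / pi, -57, 1e-6)
  expect_close(dh$psi[1, 1:5] * 180 / pi, -47, 1e-6)
  expect_true(all(is.na(dh$phi[, 1])))  # first residue lacks phi
  expect_true(all(is.na(dh$psi[, 6])))  # last lacks psi
  # fully extended (trans) chain: |phi|, |psi| ~ 180
  ext <- gen_dihedral_states(n_frames = 1, populations = 1, jitter_sd = 0,
                             state_phi = matrix(pi, 1, 4),
                             state_psi = matrix(pi, 1, 4), seed = 1)
  dhe <- extract_dihedrals(ext$traj, ext$system)
  expect_close(abs(dhe$phi[1, 2:4]), pi, 1e-6)
})

test_that("dPCA embedding handles constant, two-valued and periodic input", {
  # constant dihedrals: zero total variance, no error
  const <- matrix(1.0, 50, 4)
  pc0 <- dpca(const)
  expect_close(sum(pc0$values), 0, 1e-12)
  # one alternating dihedral: exactly one nonzero eigenvalue, two-valued scores
  ang <- matrix(0.5, 40, 3)
  ang[seq(1, 40, by = 2), 2] <- 2.0
  pc1 <- dpca(ang)
  expect_equal(sum(pc1$values > 1e-10), 1)
  expect_equal(length(unique(round(pc1$projections[, 1], 8))), 2)
  # adding 2*pi to a dihedral leaves the embedding unchanged
  pc2 <- dpca(ang + 2 * pi)
  expect_close(pc2$values, pc1$values, 1e-10)
  # eigenvalue sum equals total embedded variance; eigenvectors orthonormal
  set.seed(11)
  ang3 <- matrix(runif(200, -pi, pi), 50, 4)
  pc3 <- dpca(ang3)
  X <- cbind(cos(ang3), sin(ang3))
  expect_close(sum(pc3$values), sum(apply(X, 2, stats::var)), 1e-8)
  G <- t(pc3$vectors) %*% pc3$vectors
  expect_close(G, diag(ncol(X)), 1e-8)
})

test_that("two-state trajectories separate along dPC1 with planted labels", {
  g <- gen_dihedral_states(n_frames = 4000, populations = c(0.9, 0.1), seed = 12)
  pc <- dpca(extract_dihedrals(g$traj, g$system))
  pred <- sign(pc$projections[, 1]) == sign(pc$projections[, 1])[1]
  lab <- g$labels == g$labels[1]
  purity <- max(mean(pred == lab), mean(pred != lab))
  expect_gte(purity, 0.99)
})

test_that("free-energy landscape follows the Boltzmann inversion identities", {
  RT <- 8.314462618e-3 * 310
  # hand-built projections: two occupied bins with populations p, p/e
  n1 <- 2718; n2 <- 1000
  pts <- rbind(matrix(rep(c(-1, 0), n1), ncol = 2, byrow = TRUE),
               matrix(rep(c(1, 0), n2), ncol = 2, byrow = TRUE))
  fel <- free_energy_landscape(pts, grid = 4, temperature = 310)
  occ <- fel$grid[fel$grid$count > 0, ]
  expect_close(min(occ$dG), 0, 1e-12)            # rho_max bin at 0
  gap <- max(occ$dG) - min(occ$dG)
  expect_close(gap, RT * log(n1 / n2), 1e-9)
  expect_close(gap, RT, 0.002)                   # populations differ by e
  expect_close(sum(fel$grid$prob), 1, 1e-12)
  expect_true(all(!is.finite(fel$grid$dG[fel$grid$count == 0])))
  # doubling every count leaves dG unchanged (normalisation invariance)
  fel2 <- free_energy_landscape(rbind(pts, pts), grid = 4, temperature = 310)
  o2 <- fel2$grid[fel2$grid$count > 0, ]
  expect_close(sort(o2$dG), sort(occ$dG), 1e-10)
  expect_error(free_energy_landscape(pts[0, ]), "empty")
})

test_that("k-means recovers planted clusters and SSE decreases in k", {
  set.seed(13)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  pts <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(200, sd = 0.4), 100, 2), 2, centers[i, ], `+`)
  }))
  truth <- rep(1:3, each = 100)
  cm <- kmeans_cluster(pts, 3, seed = 14)
  tab <- table(cm$assignments, truth)
  purity <- sum(apply(tab, 2, max)) / 300
  expect_gte(purity, 0.99)
  expect_gte(cm$s_avg, 0.8)
  # k = 1: centroid is the mean, SSE the total scatter
  c1 <- kmeans_cluster(pts, 1, seed = 14)
  expect_close(as.numeric(c1$centroids), colMeans(pts), 1e-10)
  expect_close(c1$sse, sum(scale(pts, scale = FALSE)^2), 1e-8)
  # SSE non-increasing over k on the same data/seed schedule
  scan <- kmeans_scan(pts, ks = 1:6, seed = 14)
  expect_true(all(diff(scan$sse) <= 1e-8))
  expect_close(attr(scan, "sc"), max(scan$s_avg, na.rm = TRUE), 1e-12)
  expect_error(kmeans_cluster(pts, 0), "k must be")
  expect_error(kmeans_cluster(pts[1:2, ], 5), "exceeds")
})

test_that("centroid extraction returns the lowest-energy member per cluster", {
  g <- gen_dihedral_states(n_frames = 3000, populations = c(0.5, 0.5), seed = 15)
  pc <- dpca(extract_dihedrals(g$traj, g$system))
  fel <- free_energy_landscape(pc, grid = 30, temperature = 310)
  cm <- kmeans_cluster(pc$projections[, 1:2], 2, seed = 16)
  dir <- tempfile()
  cen <- extract_centroids(cm, fel, pc, g$traj, g$system, dir = dir)
  expect_equal(nrow(cen), 2)
  expect_true(all(file.exists(cen$file)))
  # representatives carry the planted state conformations: the two
  # representative frames come from different planted states
  expect_equal(sort(unique(g$labels[cen$frame])), c(1L, 2L))
  # each representative sits in its cluster's lowest-dG occupied bin
  for (i in 1:2) {
    members <- which(cm$assignments == cen$cluster[i])
    bins <- fel$bin_of_frame[members]
    expect_close(cen$dG[i], min(fel$grid$dG[bins]), 1e-12)
  }
})

test_that("Schlitter entropy is zero for static input and matches the 1-D closed form", {
  x <- matrix(rnorm(12), 4, 3)
  static <- trajectory(array(rep(x, each = 3), c(3, 4, 3)))
  expect_close(schlitter_entropy(static, temperature = 310), 0, 1e-10)
  # one coordinate with planted variance sigma^2, mass m: molar Schlitter form
  set.seed(17)
  nf <- 20000
  sigma <- 0.05; m_amu <- 12.011; Temp <- 310
  coords <- array(rep(x, each = nf), c(nf, 4, 3))
  disp <- rnorm(nf, sd = sigma)
  coords[, 4, 1] <- coords[, 4, 1] + disp
  s <- schlitter_entropy(trajectory(coords), masses = rep(m_amu, 4),
                         temperature = Temp, fit = FALSE)
  cc <- iondyn_constants
  var_emp <- mean((disp - mean(disp))^2)
  expected <- 0.5 * cc$R_kj *
    log1p(cc$kB_J * Temp * exp(2) / cc$hbar_J^2 *
            (m_amu * cc$amu_kg) * var_emp * 1e-18)
  expect_close(s, expected, 1e-10)
})

test_that("entropy-vs-time detects a planted equilibration point", {
  set.seed(18)
  base <- matrix(rnorm(30), 10, 3)
  nf <- 600
  # amplitude ramps up over the first 200 frames then is stationary
  amp <- c(seq(0.01, 0.3, length.out = 200), rep(0.3, nf - 200))
  coords <- array(rep(base, each = nf), c(nf, 10, 3)) +
    array(rnorm(nf * 30), c(nf, 10, 3)) * amp
  tr <- trajectory(coords, times = 0.1 * (seq_len(nf) - 1))
  es <- configurational_entropy_series(tr, temperature = 310,
                                       window_ends = seq(5, 60, by = 5),
                                       fit = FALSE)
  expect_true(all(diff(es$entropy) > -1e-6))  # non-decreasing profile
  teq <- detect_equilibration(es, tol = 0.02)
  # ramp ends at t = 20 ns; the plateau must be detected within one window
  expect_lte(teq, 30)
  expect_gte(teq, 20)
})

test_that("downstream analyses use only frames past the equilibration cutoff", {
  g <- gen_dihedral_states(n_frames = 100, seed = 19)
  w <- equilibrated_window(g$traj, 5.0)
  expect_true(all(w$times >= 5.0))
  expect_equal(n_frames(w), sum(g$traj$times >= 5.0))
})
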