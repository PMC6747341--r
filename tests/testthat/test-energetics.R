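test_that("interaction energy matches closed forms and the naive oracle", {
  # +2 ion at 0.2 nm from a -1 e point charge, no LJ
  sites <- data.frame(x = 0.2, y = 0, z = 0, q = -1, sigma = 0, epsilon = 0)
  p <- gen_ion_pocket(n_frames = 4, sites = sites,
                      ion = list(q = 2, sigma = 0, epsilon = 0),
                      sampling = "gaussian", spread = 0, seed = 36)
  es <- interaction_energy(p$traj, p$system, 2, 1)
  expect_close(es$series$total, -1389.35458, 1e-9)
  # ion at r = sigma_ij from a neutral LJ site: zero total
  sites2 <- data.frame(x = 0.31, y = 0, z = 0, q = 0, sigma = 0.31,
                       epsilon = 0.6)
  p2 <- gen_ion_pocket(n_frames = 3, sites = sites2,
                       ion = list(q = 2, sigma = 0.31, epsilon = 0.6),
                       sampling = "gaussian", spread = 0, seed = 37)
  es2 <- interaction_energy(p2$traj, p2$system, 2, 1)
  expect_close(es2$series$lj, 0, 1e-10)
  # full pocket vs the generator's naive double loop, 1e-10 relative
  p3 <- gen_ion_pocket(n_frames = 500, seed = 38)
  es3 <- interaction_energy(p3$traj, p3$system, 7, 1:6)
  rel <- abs(es3$series$total - p3$energies$total) /
    pmax(abs(p3$energies$total), 1)
  expect_lt(max(rel), 1e-10)
})

test_that("per-residue decomposition sums exactly to the total", {
  p <- gen_ion_pocket(n_frames = 50, seed = 39)
  es <- interaction_energy(p$traj, p$system, 7, 1:6)
  expect_close(rowSums(es$per_residue), es$series$total, 1e-6)
})

test_that("interaction energy is invariant under rigid motion and i/j swap", {
  p <- gen_ion_pocket(n_frames = 10, seed = 40)
  es <- interaction_energy(p$traj, p$system, 7, 1:6)
  rot <- qr.Q(qr(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  moved <- p$traj
  for (f in 1:10) {
    moved$coords[f, , ] <- sweep(moved$coords[f, , ] %*% rot, 2,
                                 c(1.1, -0.4, 2.2), `+`)
  }
  moved$box <- NULL
  base <- p$traj; base$box <- NULL
  es_m <- interaction_energy(moved, p$system, 7, 1:6)
  es_b <- interaction_energy(base, p$system, 7, 1:6)
  expect_close(es_m$series$total, es_b$series$total, 1e-8)
  # combination-rule symmetry: a two-atom pair gives the same energy
  # whichever atom is treated as the "ion"
  pair <- molecular_system(tibble::tibble(
    serial = 1:2, name = c("ZN", "OD1"), element = c("ZN", "O"),
    resid = 1:2, resname = c("ZN", "ASP"), chain = "A",
    charge = c(2, -0.8), sigma = c(0.226, 0.302), epsilon = c(0.014, 0.5),
    domain = c("ion", "Cat")))
  ptr <- trajectory(rbind(c(0, 0, 0), c(0.27, 0.1, -0.05)))
  e_ab <- interaction_energy(ptr, pair, 1, 2)$series$total
  e_ba <- interaction_energy(ptr, pair, 2, 1)$series$total
  expect_close(e_ab, e_ba, 1e-10)
  # overlapping atoms are an error
  bad <- p$traj
  bad$coords[1, 7, ] <- bad$coords[1, 1, ]
  expect_error(interaction_energy(bad, p$system, 7, 1:6), "overlap")
})

test_that("interaction entropy obeys its closed forms and Jensen bound", {
  expect_equal(interaction_entropy(rep(3.7, 100), 310), 0)
  # brute-force check, N = 3 series {-1, 0, +1} kJ/mol at 310 K
  RT <- 8.314462618e-3 * 310
  e3 <- c(-1, 0, 1)
  hand <- RT * log(mean(exp((e3 - mean(e3)) / RT)))
  expect_close(interaction_entropy(e3, 310), hand, 1e-12)
  # Gaussian fluctuations: -TdS -> beta sigma^2 / 2; sigma = RT gives RT/2
  set.seed(41)
  g <- rnorm(200000, sd = RT)
  expect_close(interaction_entropy(g, 310) / (RT / 2), 1, 0.05)
  # Jensen: non-negative on arbitrary random series
  for (i in 1:20) {
    x <- rnorm(50, sd = runif(1, 0.1, 5))
    expect_gte(interaction_entropy(x, 310), 0)
  }
  # overflow-prone series stays finite via the log-sum-exp guard
  expect_true(is.finite(interaction_entropy(c(0, 5000, -5000), 310)))
  expect_error(interaction_entropy(1), ">= 2 frames")
})

test_that("bootstrap standard errors behave like the CLT", {
  expect_close(bootstrap_se(rep(2, 50), n_boot = 200, seed = 42)$se[1], 0, 1e-12)
  set.seed(43)
  x <- rnorm(1000, sd = 3)
  se <- bootstrap_se(x, n_boot = 2000, seed = 44)
  expect_close(se$se[se$statistic == "mean"] / (3 / sqrt(1000)), 1, 0.1)
  # doubling n_boot changes the estimate by < 2 %
  se2 <- bootstrap_se(x, n_boot = 4000, seed = 44)
  expect_close(se2$se[1] / se$se[1], 1, 0.02)
  # deterministic given seed
  expect_identical(bootstrap_se(x, n_boot = 100, seed = 7),
                   bootstrap_se(x, n_boot = 100, seed = 7))
})

test_that("Tukey fences match hand-computed quartiles and flag outliers", {
  tf <- tukey_fences(1:8, k = 1.5)
  expect_close(tf$q1, 2.75, 1e-12)
  expect_close(tf$q3, 6.25, 1e-12)
  expect_close(tf$lower, -2.5, 1e-12)
  expect_close(tf$upper, 11.5, 1e-12)
  expect_false(any(tf$outlier))
  # degenerate IQR = 0: the fences collapse onto the common value, and the
  # at-or-beyond rule flags the extreme point (and, vacuously, the ties)
  tf2 <- tukey_fences(c(0, 0, 0, 0, -100))
  expect_true(tf2$outlier[5])
  expect_equal(c(tf2$lower, tf2$upper), c(0, 0))
  # symmetric data give fences symmetric about the median
  x <- c(-5, -2, -1, 0, 1, 2, 5)
  tf3 <- tukey_fences(x)
  expect_close(tf3$lower + tf3$upper, 2 * stats::median(x), 1e-12)
  expect_error(tukey_fences(1:3), "at least 4")
})

test_that("fence flags agree with an independent sort-based quantile oracle", {
  sort_quartiles <- function(x) {
    # type-7 by hand on the sorted sample
    s <- sort(x); n <- length(s)
    qq <- function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h); hi <- ceiling(h)
      s[lo] + (h - lo) * (s[hi] - s[lo])
    }
    c(qq(0.25), qq(0.75))
  }
  set.seed(45)
  for (i in 1:200) {
    x <- switch(1 + i %% 3,
                rnorm(sample(4:40, 1)),
                rexp(sample(4:40, 1)),
                rt(sample(4:40, 1), df = 2))
    for (k in c(1.5, 3)) {
      tf <- tukey_fences(x, k)
      q <- sort_quartiles(x)
      lo <- q[1] - k * (q[2] - q[1]); hi <- q[2] + k * (q[2] - q[1])
      expect_close(c(tf$lower, tf$upper), c(lo, hi), 1e-9)
      expect_identical(tf$outlier, x <= lo | x >= hi)
    }
  }
})

test_that("significant-residue calling applies the fences to the decomposition", {
  # 3 strong coordinating sites against a background of 12 weak distal ones:
  # the fences sit inside the weak bulk, so only the strong ones are called
  set.seed(46)
  th <- seq(0, 2 * pi, length.out = 13)[1:12]
  weak <- data.frame(x = 2.0 * cos(th), y = 2.0 * sin(th),
                     z = rep(c(-0.5, 0.5), 6),
                     q = -0.05, sigma = 0.30, epsilon = 0.5)
  strong <- data.frame(x = c(0.22, -0.25, 0), y = c(0, 0, 0.25),
                       z = c(0, 0.05, -0.05),
                       q = -0.8, sigma = 0.30, epsilon = 0.5)
  sites <- rbind(strong, weak)
  p <- gen_ion_pocket(n_frames = 80, sites = sites, spread = 0.02, seed = 47)
  n <- nrow(sites)
  es <- interaction_energy(p$traj, p$system, n + 1, 1:n)
  sig <- significant_residues(es)
  expect_true(all(sig$significant[sig$resid %in% 1:3]))
  expect_false(any(sig$significant[sig$resid %in% 4:n]))
})

test_that("coordination geometries are classified from ideal and noisy sites", {
  mk_sys <- function(n, el = "O") molecular_system(tibble::tibble(
    serial = seq_len(n + 1), name = c(rep("OD1", n), "ZN"),
    element = c(rep(el, n), "ZN"), resid = seq_len(n + 1),
    resname = c(rep("ASP", n), "ZN"), chain = "A",
    domain = c(rep("Cat", n), "ion")))
  s <- 1 / sqrt(3)
  tet <- 0.23 * rbind(c(s, s, s), c(s, -s, -s), c(-s, s, -s), c(-s, -s, s))
  ga <- assign_geometry(rbind(tet, 0), mk_sys(4), 5)
  expect_equal(ga$label, "tetrahedral")
  expect_close(ga$angle_rmsd, 0, 1e-6)
  lin <- rbind(c(0.2, 0, 0), c(-0.2, 0, 0))
  expect_equal(assign_geometry(rbind(lin, 0), mk_sys(2), 3)$label, "linear")
  oct <- 0.25 * rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  expect_equal(assign_geometry(rbind(oct, 0), mk_sys(6), 7)$label, "octahedral")
  # 4 ligands arranged as a trigonal bipyramid with one equatorial vacancy
  tbp4 <- 0.22 * rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0),
                       c(cos(2 * pi / 3), sin(2 * pi / 3), 0))
  expect_equal(assign_geometry(rbind(tbp4, 0), mk_sys(4), 5)$label, "seesaw")
  # square planar is distinguished from tetrahedral at 4 ligands
  sq <- 0.24 * rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  expect_equal(assign_geometry(rbind(sq, 0), mk_sys(4), 5)$label, "square planar")
  # small angular noise keeps the label, grows the RMSD
  set.seed(48)
  noisy <- tet + matrix(rnorm(12, sd = 0.01), 4, 3)
  gn <- assign_geometry(rbind(noisy, 0), mk_sys(4), 5)
  expect_equal(gn$label, "tetrahedral")
  expect_gt(gn$angle_rmsd, 0)
  expect_lt(gn$angle_rmsd, 10)
  # <2 ligands or carbon-only neighbours: not coordinated
  expect_equal(assign_geometry(rbind(c(0.2, 0, 0), 0), mk_sys(1), 2)$label,
               "not-coordinated")
  expect_equal(assign_geometry(rbind(tet, 0), mk_sys(4, el = "C"), 5)$label,
               "not-coordinated")
  # far ligands are outside the 0.35 nm cutoff
  expect_equal(assign_geometry(rbind(tet * 3, 0), mk_sys(4), 5)$label,
               "not-coordinated")
})

test_that("ion-site distances report exact and planted statistics", {
  coords <- rbind(c(0, 0, 0), c(0.23, 0, 0), c(0, 0.31, 0))
  sys <- molecular_system(tibble::tibble(
    serial = 1:3, name = c("ZN", "NE2", "OD1"), element = c("ZN", "N", "O"),
    resid = 1:3, resname = c("ZN", "HIS", "ASP"), chain = "A",
    domain = c("ion", "Cat", "Cat")))
  d <- ion_site_distances(trajectory(coords), sys, 1, c(2, 3))
  expect_close(d$mean, c(0.23, 0.31), 1e-12)
  expect_close(d$sd, 0, 1e-12)
  # planted fluctuating distance
  set.seed(49)
  nf <- 4000
  arr <- array(0, c(nf, 2, 3))
  arr[, 2, 1] <- rnorm(nf, mean = 0.25, sd = 0.02)
  sys2 <- molecular_system(sys$atoms[1:2, ])
  d2 <- ion_site_distances(trajectory(arr), sys2, 1, 2)
  expect_close(d2$mean, 0.25, 3 * 0.02 / sqrt(nf) + 1e-3)
  expect_close(d2$sd, 0.02, 0.002)
})

test_that("solvation terms follow the Born-style sign structure", {
  # fully exposed ion alone: no desolvation penalty, nonpolar = gamma*A + b
  sysI <- molecular_system(tibble::tibble(
    serial = 1L, name = "ZN", element = "ZN", resid = 1L, resname = "ZN",
    chain = "A", charge = 2, sigma = 0.226, epsilon = 0.014, domain = "ion"))
  trI <- trajectory(matrix(0, 1, 3))
  st <- solvation_terms(trI, sysI, 1)
  expect_close(st$g_polar, 0, 1e-9)
  a_free <- 4 * pi * (0.139 + 0.14)^2
  expect_close(st$g_nonpolar, 2.27 * a_free + 3.85, 1e-6)
  # caged ion: full positive Born penalty, nonpolar = b
  cage <- 0.2 * rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1),
                      c(1,1,1)/sqrt(3), c(-1,1,1)/sqrt(3), c(1,-1,1)/sqrt(3),
                      c(1,1,-1)/sqrt(3), c(-1,-1,1)/sqrt(3), c(-1,1,-1)/sqrt(3),
                      c(1,-1,-1)/sqrt(3), c(-1,-1,-1)/sqrt(3))
  atoms <- dplyr::bind_rows(
    sysI$atoms,
    tibble::tibble(serial = 1L + seq_len(nrow(cage)), name = "C", element = "C",
                   resid = 2L, resname = "ALA", chain = "A", charge = 0,
                   sigma = 0.35, epsilon = 0.3, domain = "Cat"))
  sysC <- molecular_system(atoms)
  trC <- trajectory(rbind(c(0, 0, 0), cage))
  stC <- solvation_terms(trC, sysC, 1)
  born <- 138.935458 * 4 / (2 * (0.226 / 2 + 0.14)) * (1 / 4 - 1 / 80)
  expect_close(stC$g_polar, born, 1e-6)
  expect_gt(stC$g_polar, 0)   # burying a divalent ion is penalised
  expect_close(stC$g_nonpolar, 3.85, 1e-9)
})

test_that("binding reports respect their defining identities", {
  p <- gen_ion_pocket(n_frames = 150, sampling = "metropolis", seed = 50)
  es <- interaction_energy(p$traj, p$system, 7, 1:6)
  rep <- binding_report(es, NULL, temperature = 310, n_boot = 300, seed = 51,
                        label = "Zn_test")
  expect_close(rep$e_binding, rep$e_vdw + rep$e_elec + rep$g_polar + rep$g_nonpolar,
               1e-9)
  expect_close(rep$g_binding, rep$e_binding + rep$minus_TdS, 1e-9)
  expect_gte(rep$minus_TdS, 0)
  # pipeline mean equals the generator-oracle ensemble mean within bootstrap SE
  expect_close(rep$e_binding, mean(p$energies$total), 3 * rep$e_binding_se + 1e-9)
  long <- tidy(rep)
  expect_equal(nrow(long), 7)
  # entropy grows with planted energy variance
  wide <- gen_ion_pocket(n_frames = 500, sampling = "metropolis",
                         temperature = 600, step = 0.03, seed = 52)
  narrow <- gen_ion_pocket(n_frames = 500, sampling = "metropolis",
                           temperature = 150, seed = 52)
  ie_w <- interaction_entropy(wide$energies$total, 310)
  ie_n <- interaction_entropy(narrow$energies$total, 310)
  expect_gt(ie_w, ie_n)
})
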