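# Shared in-code fixtures for the test suite.

# A tiny explicit system: three heavy atoms of one alanine.
toy_system <- function() {
  molecular_system(tibble::tibble(
    serial = 1:3, name = c("N", "CA", "C"), element = c("N", "C", "C"),
    resid = 1L, resname = "ALA", chain = "A",
    charge = c(-0.47, 0.07, 0.51), sigma = c(0.329, 0.356, 0.356),
    epsilon = c(0.836, 0.12, 0.46), domain = "Cat"
  ))
}

# n_ion ion atoms plus a few protein atoms, for selection tests.
multi_ion_system <- function(n_ion = 5) {
  prot <- tibble::tibble(
    serial = 1:4, name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    resid = 1L, resname = "GLY", chain = "A", charge = 0, domain = "Cat"
  )
  ions <- tibble::tibble(
    serial = 4L + seq_len(n_ion), name = "ZN", element = "ZN",
    resid = 1L + seq_len(n_ion), resname = "ZN", chain = "A",
    charge = 2, domain = "ion"
  )
  molecular_system(dplyr::bind_rows(prot, ions))
}

# Write a minimal PDB file with a HETATM zinc for load_system tests.
write_toy_pdb <- function(path) {
  lines <- c(
    "CRYST1   40.000   40.000   40.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "HETATM    4 ZN    ZN A   2       5.000   5.000   5.000  1.00  0.00          ZN",
    "END"
  )
  writeLines(lines, path)
  path
}

# Random rigid transform applied to an n x 3 matrix.
random_rigid <- function(x, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(x %*% q, 2, stats::rnorm(3), `+`)
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max|diff| = %.3g (tol %.3g)",
                              max(abs(actual - expected)), tol))
}
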