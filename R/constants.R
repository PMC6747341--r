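# Physical constants, GROMACS unit conventions: nm, kJ/mol, ns, e, K.

#' Physical constants used throughout iondyn
#'
#' Internal units follow the GROMACS convention: lengths in nm, energies in
#' kJ/mol, times in ns, charges in elementary charge units, temperatures in K.
#'
#' @format A named list:
#' \describe{
#'   \item{f_coulomb}{Electric conversion factor \eqn{1/(4\pi\epsilon_0)} =
#'     138.935458 kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}.}
#'   \item{R_kj}{Molar gas constant, 8.314462618e-3 kJ mol\eqn{^{-1}} K\eqn{^{-1}}.}
#'   \item{kB_J}{Boltzmann constant, J/K.}
#'   \item{hbar_J}{Reduced Planck constant, J s.}
#'   \item{amu_kg}{Atomic mass unit, kg.}
#' }
#' @export
iondyn_constants <- list(
  f_coulomb = 138.935458,       # kJ mol^-1 nm e^-2
  R_kj      = 8.314462618e-3,   # kJ mol^-1 K^-1
  kB_J      = 1.380649e-23,     # J K^-1
  hbar_J    = 1.054571817e-34,  # J s
  amu_kg    = 1.66053906660e-27 # kg
)

# Bondi van der Waals radii (nm) used for SASA; fallback 0.17 nm.
.vdw_radii <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180, P = 0.180,
  ZN = 0.139, CA = 0.231, "NA" = 0.227, CL = 0.175, F = 0.147
)

# Approximate atomic masses (amu) by element.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  ZN = 65.38, CA = 40.078, "NA" = 22.99, CL = 35.45, F = 18.998
)

.vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 0.17
  unname(r)
}

.element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}
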