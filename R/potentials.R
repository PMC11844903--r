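#' Temperature-dependent relative dielectric permittivity of water
#'
#' Empirical law combining a 1/T term with a cubic polynomial in T.  Used by
#' the salt/temperature-dependent electrostatic schemes (CALVADOS2,
#' Mpipi-Recharged) to evaluate the Debye screening parameter at the
#' simulation temperature.
#'
#' @param T temperature in K.  Must lie inside the validity window
#'   (230, 450) K.
#' @return dimensionless relative permittivity (about 78.4 at 298.15 K).
#' @export
dielectric_of_temperature <- function(T) {
  if (any(!is.finite(T)) || any(T <= 230) || any(T >= 450)) {
    stop("temperature outside the validity window (230, 450) K")
  }
  5321 / T + 233.76 - 0.9297 * T + 1.417e-3 * T^2 - 8.292e-7 * T^3
}

#' Debye screening parameter from salt concentration
#'
#' kappa = sqrt(8 pi B c_s) with the Bjerrum length
#' B = e^2 / (4 pi eps0 eps_r kB T).  The salt concentration in mM is
#' converted to a number density in nm^-3 (1 mM = 6.02214076e-4 nm^-3).
#'
#' @param c_s monovalent salt concentration in mM (>= 0).
#' @param T temperature in K.
#' @param eps_r relative dielectric permittivity.
#' @return screening parameter kappa in nm^-1.
#' @examples
#' debye_kappa(150, 298, 80) # about 1.26 nm^-1 (physiological salt)
#' @export
debye_kappa <- function(c_s, T, eps_r) {
  if (any(c_s < 0)) stop("salt concentration must be non-negative")
  bjerrum <- .COULOMB / (eps_r * .kB * T)       # nm
  n <- c_s * 6.02214076e-4                      # nm^-3
  sqrt(8 * pi * bjerrum * n)
}

#' Harmonic bond energy
#'
#' E = k (r - r0)^2, with no 1/2 prefactor.  Distances in Angstrom and k in
#' kJ/(mol A^2), the units in which the bonded constants of the
#' coarse-grained models are conventionally quoted (k = 9.6 for most models,
#' 2.4 for HPS-cation-pi, 4.8 for HPS-Urry; r0 = 3.81 A).
#'
#' @param r bond length in Angstrom (> 0).
#' @param k force constant in kJ/(mol A^2).
#' @param r0 equilibrium length in Angstrom.
#' @return energy in kJ/mol.
#' @export
bond_energy <- function(r, k = 9.6, r0 = 3.81) {
  stopifnot(all(r > 0))
  k * (r - r0)^2
}

#' Ashbaugh-Hatch pair energy
#'
#' Hydropathy-scaled Lennard-Jones potential used by the HPS family and
#' CALVADOS2.  For r < 2^(1/6) sigma the full LJ is shifted up by
#' (1 - lambda) eps; beyond the minimum the attractive tail is scaled by
#' lambda.  The two branches are continuous at the split point, where both
#' evaluate to -lambda * eps.
#'
#' @param r separation in nm (> 0); vectorized.
#' @param eps LJ well depth eps_ij in kJ/mol.
#' @param sigma LJ diameter sigma_ij in nm.
#' @param lambda hydropathy lambda_ij (dimensionless, [0, 1] scale).
#' @param r_cut cutoff in nm; energies are exactly 0 at and beyond it.
#'   Default `Inf` gives the untruncated potential.
#' @return energy in kJ/mol.
#' @export
ashbaugh_hatch_energy <- function(r, eps, sigma, lambda, r_cut = Inf) {
  stopifnot(all(r > 0), sigma > 0)
  s6 <- (sigma / r)^6
  lj <- 4 * eps * (s6^2 - s6)
  split <- 2^(1 / 6) * sigma
  e <- ifelse(r < split, lj + (1 - lambda) * eps, lambda * lj)
  e[r >= r_cut] <- 0
  e
}

#' Wang-Frenkel pair energy
#'
#' E(r) = eps * alpha * [(sigma/r)^(2 mu) - 1] * [(rc/r)^(2 mu) - 1]^(2 nu)
#' with the normalizer alpha chosen so the minimum depth equals exactly
#' -eps.  E(sigma) = 0 and E(r >= rc) = 0 by construction; the potential
#' and its derivative vanish continuously at the cutoff.  Used by the
#' Mpipi-family models with mu = 1 and rc = 3 sigma.
#'
#' @param r separation in nm (> 0); vectorized.
#' @param eps well depth in kJ/mol.
#' @param sigma zero-crossing diameter in nm.
#' @param nu shape exponent nu_ij.
#' @param mu shape exponent (1 for all models shipped here).
#' @param r_c cutoff in nm, default 3 sigma.
#' @return energy in kJ/mol.
#' @export
wang_frenkel_energy <- function(r, eps, sigma, nu, mu = 1, r_c = 3 * sigma) {
  stopifnot(all(r > 0), sigma > 0, nu >= 1, mu >= 1, r_c > sigma)
  alpha <- wang_frenkel_alpha(sigma, nu, mu, r_c)
  s <- (sigma / r)^(2 * mu)
  cc <- (r_c / r)^(2 * mu)
  e <- eps * alpha * (s - 1) * (cc - 1)^(2 * nu)
  e[r >= r_c] <- 0
  e
}

# WF normalizer: alpha = 2 nu (rc/sigma)^(2mu) *
#   [ (1+2nu) / (2nu ((rc/sigma)^(2mu) - 1)) ]^(2nu+1)
wang_frenkel_alpha <- function(sigma, nu, mu = 1, r_c = 3 * sigma) {
  x <- (r_c / sigma)^(2 * mu)
  2 * nu * x * ((1 + 2 * nu) / (2 * nu * (x - 1)))^(2 * nu + 1)
}

# location of the WF minimum
wang_frenkel_rmin <- function(sigma, nu, mu = 1, r_c = 3 * sigma) {
  x <- (r_c / sigma)^(2 * mu)
  r_c * ((1 + 2 * nu) / (1 + 2 * nu * x))^(1 / (2 * mu))
}

#' Debye-Hueckel screened electrostatic pair energy
#'
#' E = (1 / 4 pi eps0 eps_r) q_i q_j exp(-kappa r) / r, with charges in
#' elementary-charge units; the Coulomb prefactor e^2/(4 pi eps0) is
#' 138.935458 kJ nm / mol.
#'
#' @param r separation in nm (> 0); vectorized.
#' @param qi,qj bead charges in e units.
#' @param eps_r relative dielectric permittivity.
#' @param kappa screening parameter in nm^-1 (0 gives bare Coulomb).
#' @param r_cut cutoff in nm; 0 at and beyond (default `Inf`).
#' @return energy in kJ/mol.
#' @export
debye_huckel_energy <- function(r, qi, qj, eps_r, kappa, r_cut = Inf) {
  stopifnot(all(r > 0), eps_r > 0, kappa >= 0)
  e <- .COULOMB * qi * qj * exp(-kappa * r) / (eps_r * r)
  e[r >= r_cut] <- 0
  e
}

#' Yukawa pair energy
#'
#' E = A_ij exp(-kappa r) / r, the pair-specific screened electrostatic
#' term of the Mpipi-Recharged model: A_ij carries the full pair amplitude
#' (kJ nm/mol) rather than a product of single-bead charges.
#'
#' @param r separation in nm (> 0); vectorized.
#' @param A pair amplitude A_ij in kJ nm/mol.
#' @param kappa screening parameter in nm^-1.
#' @param r_cut cutoff in nm (default `Inf`).
#' @return energy in kJ/mol.
#' @export
yukawa_energy <- function(r, A, kappa, r_cut = Inf) {
  stopifnot(all(r > 0), kappa >= 0)
  e <- A * exp(-kappa * r) / r
  e[r >= r_cut] <- 0
  e
}

#' Cation-pi pair energy (HPS-cation-pi model)
#'
#' Plain Lennard-Jones 4 eps [(sigma/r)^12 - (sigma/r)^6] applied between
#' positively charged residues (R, K) and aromatic residues (F, W, Y) only.
#'
#' @param r separation in nm (> 0); vectorized.
#' @param eps well depth in kJ/mol.
#' @param sigma LJ diameter in nm.
#' @param pair optional character vector of the two one-letter residue
#'   codes; if supplied, an error is raised unless one is in {R, K} and the
#'   other in {F, W, Y}.
#' @param r_cut cutoff in nm (default `Inf`).
#' @return energy in kJ/mol.
#' @export
cation_pi_energy <- function(r, eps, sigma, pair = NULL, r_cut = Inf) {
  stopifnot(all(r > 0), sigma > 0)
  if (!is.null(pair)) {
    ok <- (pair[1] %in% c("R", "K") && pair[2] %in% c("F", "W", "Y")) ||
          (pair[2] %in% c("R", "K") && pair[1] %in% c("F", "W", "Y"))
    if (!ok) {
      stop("cation-pi term only applies to {R,K} x {F,W,Y} pairs, got ",
           pair[1], "-", pair[2])
    }
  }
  s6 <- (sigma / r)^6
  e <- 4 * eps * (s6^2 - s6)
  e[r >= r_cut] <- 0
  e
}
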