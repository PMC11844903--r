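#' Physical constants used throughout the package
#'
#' CODATA values, expressed in the package's internal unit system:
#' length in nm, energy in kJ/mol, time in ps, temperature in K, charge in
#' units of the elementary charge, mass in g/mol.  In this system the
#' Boltzmann constant is the molar gas constant and one internal time unit
#' is exactly 1 ps.
#'
#' @format A list with elements:
#' \describe{
#'   \item{kB}{Boltzmann (gas) constant, 8.3144621e-3 kJ/(mol K).}
#'   \item{coulomb}{e^2/(4 pi eps0) in kJ nm/mol per squared elementary
#'     charge, 138.935458.}
#'   \item{e}{elementary charge, 1.602176634e-19 C.}
#'   \item{eps0}{vacuum permittivity, 8.8541878128e-12 F/m.}
#'   \item{N_A}{Avogadro constant, 6.02214076e23 1/mol.}
#'   \item{bar_per_internal}{conversion from internal pressure
#'     (kJ/(mol nm^3)) to bar, 16.6054.}
#'   \item{gcm3_per_internal}{conversion from internal density
#'     ((g/mol)/nm^3) to g/cm^3, 1.66054e-3.}
#' }
#' @export
cg_constants <- list(
  kB   = 8.3144621e-3,          # kJ/(mol K)
  coulomb = 138.935458,         # kJ nm / (mol e^2)
  e    = 1.602176634e-19,       # C
  eps0 = 8.8541878128e-12,      # F/m
  N_A  = 6.02214076e23,         # 1/mol
  bar_per_internal  = 16.6054,  # kJ/(mol nm^3) -> bar
  gcm3_per_internal = 1.66054e-3 # (g/mol)/nm^3 -> g/cm^3
)

# internal shorthands
.kB <- cg_constants$kB
.COULOMB <- cg_constants$coulomb
.BAR <- cg_constants$bar_per_internal
.GCM3 <- cg_constants$gcm3_per_internal
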