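#' @useDynLib cgphase, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor lm lm.fit optimize rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

MODEL_NAMES <- c("HPS", "HPS-cation-pi", "HPS-Urry", "CALVADOS2",
                 "Mpipi", "Mpipi-Recharged")

#' Construct a coarse-grained model definition
#'
#' Low-level constructor behind [load_model()] and [toy_model()].  All pair
#' tables are stored as full symmetric matrices over the model alphabet.
#'
#' @param name model name.
#' @param residues data.frame with columns `res`, `q` (e), `sigma` (nm),
#'   `mass` (g/mol) and optionally `lambda`.
#' @param hydrophobic either "ashbaugh_hatch" or "wang_frenkel".
#' @param eps_hyd,sigma_hyd,lambda_hyd,nu_hyd symmetric matrices of pair
#'   coefficients (lambda for AH, nu for WF).
#' @param electrostatic one of "debye_huckel_fixed", "debye_huckel_salt_T",
#'   "yukawa".
#' @param kappa fixed screening parameter (nm^-1) for the fixed scheme.
#' @param eps_r fixed relative permittivity for the fixed scheme.
#' @param salt salt concentration in mM for the salt/T-dependent schemes.
#' @param A_yukawa symmetric matrix of Yukawa amplitudes (kJ nm/mol), or NULL.
#' @param eps_catpi,sigma_catpi cation-pi LJ matrices (0 where absent), or
#'   NULL for models without the term.
#' @param bond_k bond constant in kJ/(mol A^2) (converted internally).
#' @param bond_r0 equilibrium bond length in Angstrom.
#' @param elec_cutoff electrostatic cutoff in nm.
#' @param hyd_cutoff_factor hydrophobic cutoff as a multiple of sigma_ij.
#' @return an object of class `cg_model`.
#' @export
cg_model <- function(name, residues, hydrophobic, eps_hyd, sigma_hyd,
                     lambda_hyd = NULL, nu_hyd = NULL,
                     electrostatic, kappa = NA_real_, eps_r = NA_real_,
                     salt = NA_real_, A_yukawa = NULL,
                     eps_catpi = NULL, sigma_catpi = NULL,
                     bond_k, bond_r0 = 3.81, elec_cutoff,
                     hyd_cutoff_factor = 3) {
  alphabet <- residues$res
  stopifnot(!anyDuplicated(alphabet),
            all(residues$sigma > 0), all(residues$mass > 0),
            hydrophobic %in% c("ashbaugh_hatch", "wang_frenkel"),
            electrostatic %in% c("debye_huckel_fixed", "debye_huckel_salt_T",
                                 "yukawa"),
            bond_k > 0, bond_r0 > 0, elec_cutoff > 0, hyd_cutoff_factor > 0)
  chk_sym <- function(m, what) {
    if (is.null(m)) return(invisible())
    stopifnot(is.matrix(m), nrow(m) == length(alphabet))
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12)
      stop("pair table not symmetric: ", what)
  }
  chk_sym(eps_hyd, "eps"); chk_sym(sigma_hyd, "sigma")
  chk_sym(lambda_hyd, "lambda"); chk_sym(nu_hyd, "nu")
  chk_sym(A_yukawa, "A"); chk_sym(eps_catpi, "cation-pi eps")
  if (any(sigma_hyd <= 0)) stop("sigma_ij must be positive")
  nm <- function(m) {
    if (!is.null(m)) dimnames(m) <- list(alphabet, alphabet)
    m
  }
  eps_hyd <- nm(eps_hyd); sigma_hyd <- nm(sigma_hyd)
  lambda_hyd <- nm(lambda_hyd); nu_hyd <- nm(nu_hyd)
  A_yukawa <- nm(A_yukawa)
  eps_catpi <- nm(eps_catpi); sigma_catpi <- nm(sigma_catpi)
  structure(list(
    name = name, alphabet = alphabet, residues = residues,
    hydrophobic = hydrophobic,
    eps_hyd = eps_hyd, sigma_hyd = sigma_hyd,
    lambda_hyd = lambda_hyd, nu_hyd = nu_hyd,
    electrostatic = electrostatic, kappa = kappa, eps_r = eps_r, salt = salt,
    A_yukawa = A_yukawa, eps_catpi = eps_catpi, sigma_catpi = sigma_catpi,
    bond_k = bond_k, bond_r0 = bond_r0, elec_cutoff = elec_cutoff,
    hyd_cutoff_factor = hyd_cutoff_factor), class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  cat("cg_model:", x$name, "\n")
  cat("  alphabet:", length(x$alphabet), "residue types\n")
  cat("  hydrophobic:", x$hydrophobic,
      sprintf("(cutoff %g sigma_ij)", x$hyd_cutoff_factor), "\n")
  cat("  electrostatic:", x$electrostatic,
      sprintf("(cutoff %g nm)", x$elec_cutoff), "\n")
  cat("  bonds: k =", x$bond_k, "kJ/(mol A^2), r0 =", x$bond_r0, "A\n")
  if (!is.null(x$eps_catpi)) cat("  cation-pi term present\n")
  invisible(x)
}

read_param_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Load one of the six packaged coarse-grained models
#'
#' Reads the model registry (YAML) and the per-model parameter tables
#' (CSV) shipped under `inst/extdata/params` and assembles a validated
#' [cg_model()].  Mixing-rule models (HPS family, CALVADOS2) build their
#' pair tables with Lorentz-Berthelot rules, lambda_ij = (lambda_i +
#' lambda_j)/2 and sigma_ij = (sigma_i + sigma_j)/2; the Mpipi-family
#' models read explicit pair tables.
#'
#' @param name one of "HPS", "HPS-cation-pi", "HPS-Urry", "CALVADOS2",
#'   "Mpipi", "Mpipi-Recharged".
#' @param param_dir directory holding `models.yaml` and the CSV tables;
#'   defaults to the packaged tables.
#' @return a [cg_model()] object.
#' @export
load_model <- function(name,
                       param_dir = system.file("extdata", "params",
                                               package = "cgphase")) {
  registry <- yaml::read_yaml(file.path(param_dir, "models.yaml"))
  if (!name %in% names(registry)) {
    stop("unknown model '", name, "'; available: ",
         paste(names(registry), collapse = ", "))
  }
  spec <- registry[[name]]
  res <- read_param_csv(file.path(param_dir, spec$residue_table))
  need <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
  missing <- setdiff(need, res$res)
  if (length(missing) > 0) {
    stop("residue table incomplete for ", name, "; missing: ",
         paste(missing, collapse = ", "))
  }
  res <- res[match(need, res$res), ]
  n <- nrow(res)
  sym_outer <- function(v, f) outer(v, v, f)

  if (spec$hydrophobic == "ashbaugh_hatch") {
    eps_hyd <- matrix(spec$ah_eps, n, n)
    sigma_hyd <- sym_outer(res$sigma, function(a, b) (a + b) / 2)
    lambda_hyd <- sym_outer(res$lambda, function(a, b) (a + b) / 2)
    nu_hyd <- NULL
  } else {
    pt <- read_param_csv(file.path(param_dir, spec$pair_table))
    eps_hyd <- sigma_hyd <- nu_hyd <- matrix(NA_real_, n, n,
                                             dimnames = list(need, need))
    idx_i <- match(pt$i, need); idx_j <- match(pt$j, need)
    eps_hyd[cbind(idx_i, idx_j)] <- pt$eps
    eps_hyd[cbind(idx_j, idx_i)] <- pt$eps
    sigma_hyd[cbind(idx_i, idx_j)] <- pt$sigma
    sigma_hyd[cbind(idx_j, idx_i)] <- pt$sigma
    nu_hyd[cbind(idx_i, idx_j)] <- pt$nu
    nu_hyd[cbind(idx_j, idx_i)] <- pt$nu
    if (anyNA(eps_hyd)) {
      bad <- which(is.na(eps_hyd) & upper.tri(eps_hyd, diag = TRUE),
                   arr.ind = TRUE)
      stop("pair table incomplete for ", name, "; missing pairs: ",
           paste(paste0(need[bad[, 1]], "-", need[bad[, 2]]),
                 collapse = ", "))
    }
    lambda_hyd <- NULL
  }
  dimnames(eps_hyd) <- dimnames(sigma_hyd) <- list(need, need)
  if (!is.null(lambda_hyd)) dimnames(lambda_hyd) <- list(need, need)

  A_yukawa <- NULL
  if (spec$electrostatic == "yukawa") {
    yt <- read_param_csv(file.path(param_dir, spec$yukawa_table))
    A_yukawa <- matrix(0, n, n, dimnames = list(need, need))
    A_yukawa[cbind(match(yt$i, need), match(yt$j, need))] <- yt$A
    A_yukawa[cbind(match(yt$j, need), match(yt$i, need))] <- yt$A
  }
  eps_catpi <- sigma_catpi <- NULL
  if (!is.null(spec$cation_pi_table)) {
    ct <- read_param_csv(file.path(param_dir, spec$cation_pi_table))
    eps_catpi <- sigma_catpi <- matrix(0, n, n, dimnames = list(need, need))
    ii <- match(ct$i, need); jj <- match(ct$j, need)
    eps_catpi[cbind(ii, jj)] <- ct$eps; eps_catpi[cbind(jj, ii)] <- ct$eps
    sigma_catpi[cbind(ii, jj)] <- ct$sigma
    sigma_catpi[cbind(jj, ii)] <- ct$sigma
  }
  cg_model(name = name, residues = res,
           hydrophobic = spec$hydrophobic,
           eps_hyd = eps_hyd, sigma_hyd = sigma_hyd,
           lambda_hyd = lambda_hyd, nu_hyd = nu_hyd,
           electrostatic = spec$electrostatic,
           kappa = spec$kappa %||% NA_real_,
           eps_r = spec$eps_r %||% NA_real_,
           salt = spec$salt %||% NA_real_,
           A_yukawa = A_yukawa,
           eps_catpi = eps_catpi, sigma_catpi = sigma_catpi,
           bond_k = spec$bond_k, bond_r0 = spec$bond_r0,
           elec_cutoff = spec$elec_cutoff,
           hyd_cutoff_factor = spec$hyd_cutoff_factor %||% 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve temperature-dependent quantities and flatten the model into the
# numeric tables consumed by the C++ engine and the R reference loops.
# The electrostatic term is unified as pref_ij * exp(-kappa r)/r: for the
# Debye-Hueckel schemes pref_ij = C q_i q_j / eps_r, for Yukawa pref = A_ij.
resolve_model <- function(model, T) {
  stopifnot(inherits(model, "cg_model"), is.finite(T), T > 0)
  n <- length(model$alphabet)
  if (model$electrostatic == "debye_huckel_fixed") {
    eps_r <- model$eps_r
    kappa <- model$kappa
  } else {
    eps_r <- dielectric_of_temperature(T)
    kappa <- debye_kappa(model$salt, T, eps_r)
  }
  if (model$electrostatic == "yukawa") {
    epref <- model$A_yukawa
  } else {
    q <- model$residues$q
    epref <- .COULOMB * outer(q, q) / eps_r
  }
  hscheme <- if (model$hydrophobic == "ashbaugh_hatch") 1L else 2L
  shape <- if (hscheme == 1L) model$lambda_hyd else model$nu_hyd
  list(
    hscheme = hscheme,
    heps = model$eps_hyd, hsig = model$sigma_hyd, hshape = shape,
    hcut = model$hyd_cutoff_factor * model$sigma_hyd,
    epref = epref, kappa = kappa, ecut = model$elec_cutoff, eps_r = eps_r,
    cpeps = model$eps_catpi %||% matrix(0, n, n),
    cpsig = model$sigma_catpi %||% matrix(1, n, n),
    bond_k = model$bond_k * 100,   # kJ/(mol A^2) -> kJ/(mol nm^2)
    bond_r0 = model$bond_r0 / 10,  # A -> nm
    mass = model$residues$mass, q = model$residues$q, T = T
  )
}

# per-type-pair energy at distance r (nm), R reference implementation,
# used by the oracle and the analysis modules.  Returns the sum of
# hydrophobic + electrostatic (+ cation-pi unless include_catpi = FALSE).
pair_energy_resolved <- function(rm, i, j, r, include_catpi = TRUE) {
  e_h <- if (rm$hscheme == 1L) {
    ashbaugh_hatch_energy(r, rm$heps[i, j], rm$hsig[i, j], rm$hshape[i, j],
                          r_cut = rm$hcut[i, j])
  } else {
    wang_frenkel_energy(r, rm$heps[i, j], rm$hsig[i, j], rm$hshape[i, j],
                        r_c = rm$hcut[i, j])
  }
  e_e <- yukawa_energy(r, rm$epref[i, j], rm$kappa, r_cut = rm$ecut)
  e <- e_h + e_e
  if (include_catpi && rm$cpeps[i, j] != 0) {
    e <- e + cation_pi_energy(r, rm$cpeps[i, j], rm$cpsig[i, j],
                              r_cut = 3 * rm$cpsig[i, j])
  }
  e
}

#' Normalized residue-pair interaction strength matrix
#'
#' For every type pair, evaluates the sum of the hydrophobic,
#' electrostatic and (if present) cation-pi terms at the pair's potential
#' minimum distance, converts to a positive-attractive convention and
#' divides by the largest attractive entry, so the maximum entry is 1.
#' For the models with hierarchical aromatic parametrization (Mpipi-family,
#' CALVADOS2, HPS-Urry) the aromatic self-interactions rank W > Y > F.
#'
#' @param model a [cg_model()].
#' @param T temperature in K (matters for the salt/T-dependent schemes).
#' @return symmetric matrix over the model alphabet; positive entries are
#'   attractive, the maximum entry is 1.
#' @export
interaction_strength_matrix <- function(model, T = 298) {
  rm <- resolve_model(model, T)
  n <- length(model$alphabet)
  E <- matrix(0, n, n, dimnames = list(model$alphabet, model$alphabet))
  for (i in seq_len(n)) {
    for (j in i:n) {
      r_min <- if (rm$hscheme == 1L) {
        2^(1 / 6) * rm$hsig[i, j]
      } else {
        wang_frenkel_rmin(rm$hsig[i, j], rm$hshape[i, j],
                          r_c = rm$hcut[i, j])
      }
      E[i, j] <- E[j, i] <- pair_energy_resolved(rm, i, j, r_min)
    }
  }
  S <- -E                      # attraction positive
  S / max(S)
}
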