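#' Create a bead configuration
#'
#' @param positions N x 3 matrix of bead positions in nm (wrapped into the
#'   box on construction).
#' @param box lengths (Lx, Ly, Lz) in nm of the orthorhombic periodic box.
#' @param chain integer chain id per bead; beads of a chain must be
#'   contiguous and bonds connect sequence neighbours within a chain.
#' @param residue one-letter residue code per bead.
#' @param velocities optional N x 3 velocity matrix (nm/ps).
#' @return object of class `cg_configuration`.
#' @export
configuration <- function(positions, box, chain, residue,
                          velocities = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(box) == 3, all(box > 0),
            length(chain) == nrow(positions),
            length(residue) == nrow(positions))
  if (is.unsorted(chain)) stop("chains must be contiguous")
  positions <- sweep(positions, 2, box, function(p, L) p - L * floor(p / L))
  structure(list(positions = positions, box = as.numeric(box),
                 chain = as.integer(chain), residue = as.character(residue),
                 velocities = velocities),
            class = "cg_configuration")
}

#' @export
print.cg_configuration <- function(x, ...) {
  cat(sprintf("cg_configuration: %d beads, %d chains, box %.2f x %.2f x %.2f nm\n",
              nrow(x$positions), length(unique(x$chain)),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

# bonds between sequence neighbours of each chain, 0-based for the engine
bond_list <- function(chain) {
  i <- seq_along(chain)[-length(chain)]
  keep <- chain[i] == chain[i + 1]
  cbind(i[keep] - 1L, i[keep]) |> matrix(ncol = 2)
}

# mass in g/mol per bead
bead_masses <- function(model, residue) {
  m <- model$residues$mass[match(residue, model$alphabet)]
  if (anyNA(m)) {
    stop("unknown residue code(s): ",
         paste(unique(residue[is.na(m)]), collapse = ", "))
  }
  m
}

bead_types <- function(model, residue) {
  t <- match(residue, model$alphabet) - 1L
  if (anyNA(t)) {
    stop("unknown residue code(s): ",
         paste(unique(residue[is.na(t)]), collapse = ", "))
  }
  t
}

#' Mass density of a configuration
#'
#' @param conf a [configuration()].
#' @param model the model providing residue masses.
#' @return density in g/cm^3.
#' @export
mass_density <- function(conf, model) {
  sum(bead_masses(model, conf$residue)) / prod(conf$box) * .GCM3
}

# flatten a model at temperature T into the C++ parameter pack
engine_params <- function(model, T) {
  rm <- resolve_model(model, T)
  n <- length(model$alphabet)
  halpha <- matrix(0, n, n)
  if (rm$hscheme == 2L) {
    halpha <- matrix(wang_frenkel_alpha(rm$hsig, rm$hshape,
                                        r_c = rm$hcut), n, n)
  }
  maxcut <- max(rm$hcut, rm$ecut, 3 * rm$cpsig * (rm$cpeps != 0))
  list(hscheme = rm$hscheme, heps = unname(rm$heps),
       hsig = unname(rm$hsig), hshape = unname(rm$hshape),
       halpha = halpha, hcut = unname(rm$hcut),
       epref = unname(rm$epref), kappa = rm$kappa, ecut = rm$ecut,
       cpeps = unname(rm$cpeps), cpsig = unname(rm$cpsig),
       bond_k = rm$bond_k, bond_r0 = rm$bond_r0, maxcut = maxcut)
}

#' Total potential energy and forces of a configuration
#'
#' Sums harmonic bonds, electrostatic, hydrophobic and (where defined)
#' cation-pi terms under the minimum-image periodic convention; directly
#' bonded pairs are excluded from the nonbonded terms.  Forces are exact
#' negative gradients of the energy.
#'
#' @param model a [cg_model()].
#' @param conf a [configuration()].
#' @param T temperature in K (resolves the T-dependent electrostatics).
#' @return list with `energy` (kJ/mol), `e_bond`, `e_pair`, `forces`
#'   (N x 3 in kJ/(mol nm)) and the pair+bond `virial` (3 x 3, kJ/mol).
#' @export
total_energy_forces <- function(model, conf, T = 298) {
  par <- engine_params(model, T)
  cpp_energy_forces(conf$positions, conf$box,
                    bead_types(model, conf$residue),
                    bond_list(conf$chain), par)
}

#' Simulation settings for Langevin dynamics
#'
#' @param timestep_fs integration time step in fs (default 10).
#' @param damping_ps Langevin thermostat relaxation time in ps (default 5).
#' @param temperature bath temperature in K.
#' @param n_steps number of steps.
#' @param seed RNG seed (engine-internal generator; reproducible).
#' @param sample_every store a trajectory frame every this many steps
#'   (0 = none).
#' @param stress_every store stress/energy samples every this many steps
#'   (0 = none).
#' @param skin Verlet-list skin in nm (default 0.3).
#' @param thermostat logical; FALSE gives plain velocity-Verlet NVE.
#' @param max_disp optional per-half-step displacement cap in nm (0 = off);
#'   used by the relaxation stages to defuse close contacts, never for
#'   production dynamics.
#' @return list of validated settings.
#' @export
simulation_settings <- function(timestep_fs = 10, damping_ps = 5,
                                temperature = 298, n_steps = 1000,
                                seed = 1, sample_every = 0,
                                stress_every = 0, skin = 0.3,
                                thermostat = TRUE, max_disp = 0) {
  stopifnot(timestep_fs > 0, damping_ps > 0, temperature > 0, n_steps >= 0,
            skin > 0, max_disp >= 0)
  list(timestep_fs = timestep_fs, damping_ps = damping_ps,
       temperature = temperature, n_steps = as.integer(n_steps),
       seed = as.integer(seed), sample_every = as.integer(sample_every),
       stress_every = as.integer(stress_every), skin = skin,
       thermostat = isTRUE(thermostat), max_disp = max_disp)
}

# Maxwell-Boltzmann velocities (nm/ps)
init_velocities <- function(masses, T, seed) {
  set.seed(seed)
  n <- length(masses)
  matrix(rnorm(3 * n), n, 3) * sqrt(.kB * T / masses)
}

#' Run Langevin dynamics
#'
#' BAOAB-splitting Langevin integration in the NVT ensemble at fixed
#' volume, with per-stride potential/kinetic energy, instantaneous
#' temperature and virial stress output.  Fully reproducible under a fixed
#' seed.  With `thermostat = FALSE` the integrator reduces to velocity
#' Verlet (NVE).
#'
#' @param conf starting [configuration()]; if it carries velocities they
#'   are used, otherwise Maxwell-Boltzmann velocities are drawn.
#' @param model a [cg_model()].
#' @param settings a [simulation_settings()] list.
#' @return list with `trajectory` (a `cg_trajectory`), `stress` (a
#'   [stress_series()]), `energies` (data.frame t, potential, kinetic,
#'   temperature) and `final` (configuration with velocities).
#' @export
run_langevin <- function(conf, model, settings) {
  stopifnot(inherits(conf, "cg_configuration"))
  par <- engine_params(model, settings$temperature)
  if (par$maxcut + settings$skin > min(conf$box) / 2) {
    warning("interaction cutoff exceeds half the smallest box length; ",
            "minimum-image convention truncates periodic images")
  }
  masses <- bead_masses(model, conf$residue)
  vel <- conf$velocities
  if (is.null(vel)) {
    vel <- init_velocities(masses, settings$temperature, settings$seed)
  }
  if (settings$n_steps == 0) {
    return(list(trajectory = trajectory(list(conf$positions), 0, conf),
                stress = NULL, energies = NULL,
                final = configuration(conf$positions, conf$box, conf$chain,
                                      conf$residue, vel)))
  }
  out <- cpp_run_langevin(conf$positions, vel, conf$box,
                          bead_types(model, conf$residue), masses,
                          bond_list(conf$chain), par,
                          dt = settings$timestep_fs * 1e-3,
                          gamma = 1 / settings$damping_ps,
                          Tbath = settings$temperature,
                          nsteps = settings$n_steps, seed = settings$seed,
                          sample_every = settings$sample_every,
                          stress_every = settings$stress_every,
                          skin = settings$skin,
                          thermostat = settings$thermostat,
                          max_disp = settings$max_disp %||% 0)
  n <- nrow(conf$positions)
  frames <- NULL
  if (out$n_frames > 0) {
    frames <- lapply(seq_len(out$n_frames), function(k) {
      matrix(out$frames[((k - 1) * 3 * n + 1):(k * 3 * n)], n, 3)
    })
  }
  traj <- trajectory(frames, out$times[seq_len(out$n_frames)], conf)
  stress <- NULL
  energies <- NULL
  if (settings$stress_every > 0) {
    s <- out$stress
    stress <- stress_series(times = s[, 1],
                            sxy = s[, 2] * .BAR, sxz = s[, 3] * .BAR,
                            syz = s[, 4] * .BAR, sxx = s[, 5] * .BAR,
                            syy = s[, 6] * .BAR, szz = s[, 7] * .BAR,
                            V = prod(conf$box), T = settings$temperature,
                            units = "bar")
    energies <- data.frame(t = out$energies[, 1],
                           potential = out$energies[, 2],
                           kinetic = out$energies[, 3],
                           temperature = out$energies[, 4])
  }
  list(trajectory = traj, stress = stress, energies = energies,
       final = configuration(out$positions, conf$box, conf$chain,
                             conf$residue, out$velocities))
}

#' Instantaneous virial stress tensor
#'
#' Kinetic plus pairwise-virial contributions, sigma = (sum m v (x) v +
#' sum f (x) r) / V, symmetric by construction.
#'
#' @param conf a [configuration()].
#' @param velocities N x 3 velocities in nm/ps.
#' @param model a [cg_model()].
#' @param T temperature used to resolve the model (K).
#' @return 3 x 3 stress tensor in bar.
#' @export
virial_stress <- function(conf, velocities, model, T = 298) {
  par <- engine_params(model, T)
  S <- cpp_virial_stress(conf$positions, velocities, conf$box,
                         bead_types(model, conf$residue),
                         bead_masses(model, conf$residue),
                         bond_list(conf$chain), par)
  S * .BAR
}

#' Trajectory container
#'
#' @param frames list of N x 3 position matrices (nm).
#' @param times frame times in ps (strictly increasing).
#' @param conf the configuration supplying box, chain ids and residues.
#' @return object of class `cg_trajectory`.
#' @export
trajectory <- function(frames, times, conf) {
  if (length(frames) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(frames = frames, times = times, box = conf$box,
                 chain = conf$chain, residue = conf$residue),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames, %d beads, %.1f ps span\n",
              length(x$frames), length(x$chain),
              if (length(x$times) > 0) diff(range(x$times)) else 0))
  invisible(x)
}

#' Build a slab configuration for direct-coexistence simulation
#'
#' Places `n_chains` self-avoiding random-walk replicas of the sequence in
#' an elongated orthorhombic box (long axis = z), rejecting insertions with
#' any inter-bead separation below `min_ratio` sigma_ij.  Chain centres are
#' restricted to the central `slab_fraction` of the long axis so the start
#' is a dense slab surrounded by vacuum, the standard direct-coexistence
#' setup.
#'
#' @param model a [cg_model()].
#' @param sequence sequence string (one chain species).
#' @param n_chains number of replicas.
#' @param cross_section box cross-section in nm^2 (square; default 17 x 17).
#' @param length box length along z in nm (default 120).
#' @param seed RNG seed.
#' @param slab_fraction fraction of z available to chain centres.
#' @param min_ratio overlap rejection threshold in units of sigma_ij.
#' @param max_retries insertion attempts per chain.
#' @param relax logical; run a short small-timestep Langevin push-off to
#'   remove residual close contacts (recommended before production runs).
#' @param temperature push-off temperature in K.
#' @return a [configuration()]; its mean mass density is reported by
#'   [mass_density()].
#' @export
build_slab_configuration <- function(model, sequence, n_chains,
                                     cross_section = 17 * 17, length = 120,
                                     seed = 1, slab_fraction = 0.4,
                                     min_ratio = 0.7, max_retries = 1000,
                                     relax = FALSE, temperature = 298) {
  set.seed(seed)
  side <- sqrt(cross_section)
  box <- c(side, side, length)
  conf <- build_chains(model, sequence, n_chains, box,
                       z_range = c(length * (0.5 - slab_fraction / 2),
                                   length * (0.5 + slab_fraction / 2)),
                       min_ratio = min_ratio, max_retries = max_retries,
                       seed = seed)
  if (relax) conf <- soft_relax(conf, model, temperature, seed)
  conf
}

# staged small-timestep, strong-friction Langevin push-off that removes
# the residual close contacts left by random insertion
soft_relax <- function(conf, model, temperature, seed,
                       stages = c(0.5, 2, 5), steps = 600) {
  for (dt in stages) {
    st <- simulation_settings(timestep_fs = dt, damping_ps = 0.1,
                              temperature = temperature, n_steps = steps,
                              seed = seed, max_disp = 0.02)
    conf <- suppressWarnings(run_langevin(conf, model, st))$final
  }
  conf
}

build_chains <- function(model, sequence, n_chains, box, z_range,
                         min_ratio = 0.7, max_retries = 1000, seed = 1) {
  res1 <- strsplit(sequence, "")[[1]]
  n <- length(res1)
  sig1 <- model$residues$sigma[match(res1, model$alphabet)]
  if (anyNA(sig1)) stop("sequence contains residues absent from the model")
  r0 <- model$bond_r0 / 10
  pos <- cpp_insert_chains(n_chains, n, sig1, box, z_range[1], z_range[2],
                           r0, min_ratio, seed = seed,
                           bead_tries = 100, chain_tries = max_retries)
  configuration(pos, box, rep(seq_len(n_chains), each = n),
                rep(res1, n_chains))
}

#' Build a bulk (condensed-phase) configuration at a target density
#'
#' Chains are inserted in a dilute cubic box, then the box and the chain
#' centres of mass are isotropically rescaled in stages with short
#' Langevin relaxation runs in between, until the mass density is within
#' 1 percent of the target.  Rescaling centres of mass (not internal
#' coordinates) preserves bond lengths; the relaxation keeps all bonds
#' below 2 r0.
#'
#' @param model a [cg_model()].
#' @param sequence sequence string.
#' @param n_chains number of replicas.
#' @param target_density target mass density in g/cm^3 (> 0).
#' @param seed RNG seed.
#' @param temperature relaxation temperature in K.
#' @param stage_scale box-length factor per compression stage.
#' @param relax_steps Langevin steps between stages.
#' @param start_factor initial box length as multiple of the target length.
#' @param max_stages compression stage limit.
#' @return a [configuration()] in a cubic box at the target density.
#' @export
build_bulk_configuration <- function(model, sequence, n_chains,
                                     target_density, seed = 1,
                                     temperature = 298, stage_scale = 0.9,
                                     relax_steps = 200, start_factor = 2,
                                     max_stages = 60) {
  if (target_density <= 0) stop("target density must be positive")
  set.seed(seed)
  res1 <- strsplit(sequence, "")[[1]]
  chain_mass <- sum(bead_masses(model, res1))
  total_mass <- n_chains * chain_mass
  L_target <- (total_mass * .GCM3 / target_density)^(1 / 3)
  L <- L_target * start_factor
  conf <- build_chains(model, sequence, n_chains, rep(L, 3),
                       z_range = c(0, L), seed = seed)
  conf <- soft_relax(conf, model, temperature, seed)
  # strong-friction, reduced-timestep relaxation between compression
  # stages: COM rescaling creates fresh interchain contacts each stage
  settings <- simulation_settings(timestep_fs = 2, damping_ps = 0.2,
                                  temperature = temperature,
                                  n_steps = relax_steps, seed = seed,
                                  max_disp = 0.02)
  for (stage in seq_len(max_stages)) {
    run <- suppressWarnings(run_langevin(conf, model, settings))
    conf <- run$final
    if (L <= L_target * 1.0001) break
    Lnew <- max(L * stage_scale, L_target)
    conf <- rescale_com(conf, Lnew / L)
    L <- Lnew
    if (stage == max_stages) {
      stop("bulk compression did not converge; last density ",
           signif(mass_density(conf, model), 4), " g/cm^3")
    }
  }
  conf <- soft_relax(conf, model, temperature, seed,
                     stages = c(2, 5), steps = 1000)
  rho <- mass_density(conf, model)
  if (abs(rho - target_density) / target_density > 0.01) {
    stop("bulk compression did not converge; last density ",
         signif(rho, 4), " g/cm^3")
  }
  conf
}

# scale the box and chain centres of mass by `f`, keeping internal
# coordinates (hence bond lengths) fixed
rescale_com <- function(conf, f) {
  pos <- conf$positions
  box <- conf$box
  for (c in unique(conf$chain)) {
    idx <- which(conf$chain == c)
    p <- pos[idx, , drop = FALSE]
    # unwrap the chain around its first bead before computing the centre
    ref <- p[1, ]
    d <- sweep(p, 2, ref)
    d <- sweep(d, 2, box, function(x, L) x - L * round(x / L))
    p <- sweep(d, 2, ref, "+")
    com <- colMeans(p)
    pos[idx, ] <- sweep(p, 2, com * (f - 1), "+")
  }
  configuration(pos, box * f, conf$chain, conf$residue, conf$velocities)
}

#' Maximum bond length of a configuration
#'
#' @param conf a [configuration()].
#' @return longest bonded separation in nm (minimum image).
#' @export
max_bond_length <- function(conf) {
  b <- bond_list(conf$chain) + 1L
  d <- conf$positions[b[, 1], , drop = FALSE] -
       conf$positions[b[, 2], , drop = FALSE]
  d <- sweep(d, 2, conf$box, function(x, L) x - L * round(x / L))
  sqrt(max(rowSums(d^2)))
}
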