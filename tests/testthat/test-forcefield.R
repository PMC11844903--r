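# Pair potentials, model loading and the energy/force engine.

test_that("dielectric permittivity law matches an independent evaluation", {
  # independent evaluation: Horner form of the same empirical law
  horner <- function(T) {
    5321 / T + ((-8.292e-7 * T + 1.417e-3) * T - 0.9297) * T + 233.76
  }
  for (T in c(250, 273.15, 298.15, 350, 400)) {
    expect_equal(dielectric_of_temperature(T), horner(T), tolerance = 1e-14)
  }
  expect_equal(dielectric_of_temperature(298.15), 78.402, tolerance = 1e-4)
  # strictly decreasing over the liquid-water window
  grid <- dielectric_of_temperature(seq(250, 400, by = 1))
  expect_true(all(diff(grid) < 0))
  expect_error(dielectric_of_temperature(200), "window")
  expect_error(dielectric_of_temperature(500), "window")
})

test_that("Debye screening parameter reproduces physiological salt", {
  expect_equal(round(debye_kappa(150, 298, 80), 2), 1.26)
  expect_equal(debye_kappa(0, 298, 80), 0)
  # square-root scaling in the salt concentration
  expect_equal(debye_kappa(4 * 150, 298, 80),
               2 * debye_kappa(150, 298, 80), tolerance = 1e-12)
  expect_error(debye_kappa(-1, 298, 80), "non-negative")
})

test_that("harmonic bond energy has no 1/2 prefactor", {
  expect_equal(bond_energy(3.81, 9.6, 3.81), 0)
  expect_equal(bond_energy(4.81, 9.6, 3.81), 9.6)   # 1 A stretch
  expect_equal(bond_energy(4.81, 2.4, 3.81), 2.4)   # HPS-cation-pi constant
  expect_equal(bond_energy(4.81, 4.8, 3.81), 4.8)   # HPS-Urry constant
})

test_that("Ashbaugh-Hatch potential: limits and continuity", {
  eps <- 0.8368; sigma <- 0.6
  r <- seq(0.4, 2.5, by = 0.01)
  lj <- 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  # lambda = 1 reduces to plain Lennard-Jones everywhere
  expect_equal(ashbaugh_hatch_energy(r, eps, sigma, 1), lj,
               tolerance = 1e-14)
  # lambda = 0: tail switched off beyond the minimum
  expect_equal(ashbaugh_hatch_energy(seq(2^(1/6) * sigma, 3, by = 0.05),
                                     eps, sigma, 0),
               rep(0, length(seq(2^(1/6) * sigma, 3, by = 0.05))))
  # both branches give -lambda eps at the split point, for all lambda
  split <- 2^(1 / 6) * sigma
  for (lam in seq(0, 1, by = 0.1)) {
    below <- ashbaugh_hatch_energy(split - 1e-9, eps, sigma, lam)
    above <- ashbaugh_hatch_energy(split + 1e-9, eps, sigma, lam)
    expect_equal(below, -lam * eps, tolerance = 1e-6)
    expect_lt(abs(below - above), 1e-6)
    expect_equal(ashbaugh_hatch_energy(split, eps, sigma, lam),
                 -lam * eps, tolerance = 1e-12)
  }
})

test_that("Wang-Frenkel potential: zeros, depth and force at minimum", {
  eps <- 0.8; sigma <- 0.55
  for (nu in c(1, 2, 3)) {
    rc <- 3 * sigma
    expect_equal(wang_frenkel_energy(sigma, eps, sigma, nu), 0,
                 tolerance = 1e-14)
    expect_equal(wang_frenkel_energy(rc, eps, sigma, nu), 0)
    expect_equal(wang_frenkel_energy(rc + 0.1, eps, sigma, nu), 0)
    # numerical minimization: depth exactly -eps, gradient zero there
    opt <- optimize(function(r) wang_frenkel_energy(r, eps, sigma, nu),
                    interval = c(sigma, rc), tol = 1e-12)
    expect_equal(opt$objective, -eps, tolerance = 1e-8)
    h <- 1e-7
    grad <- (wang_frenkel_energy(opt$minimum + h, eps, sigma, nu) -
             wang_frenkel_energy(opt$minimum - h, eps, sigma, nu)) / (2 * h)
    expect_lt(abs(grad), 1e-4)
    # analytic minimum location agrees with the numerical one
    expect_equal(cgphase:::wang_frenkel_rmin(sigma, nu), opt$minimum,
                 tolerance = 1e-6)
  }
})

test_that("screened electrostatics: limits and hand-computed value", {
  r <- seq(0.3, 3, by = 0.1)
  expect_equal(debye_huckel_energy(r, 0, 1, 80, 1), rep(0, length(r)))
  # screening-off limit equals bare Coulomb
  expect_equal(debye_huckel_energy(r, 1, -1, 80, 0),
               138.935458 * (-1) / (80 * r), tolerance = 1e-14)
  # hand computation with the Coulomb constant
  expect_equal(debye_huckel_energy(1, 1, 1, 80, 1),
               138.935458 / 80 * exp(-1), tolerance = 1e-12)
})

test_that("Yukawa potential: scaling and monotonicity", {
  r <- seq(0.2, 4, by = 0.05)
  expect_equal(yukawa_energy(r, 0, 1.3), rep(0, length(r)))
  # functional scaling E(r2)/E(r1) = (r1/r2) exp(-kappa (r2 - r1))
  A <- 2.1; kap <- 1.26
  r1 <- 0.7; r2 <- 1.9
  expect_equal(yukawa_energy(r2, A, kap) / yukawa_energy(r1, A, kap),
               (r1 / r2) * exp(-kap * (r2 - r1)), tolerance = 1e-12)
  e <- yukawa_energy(r, A, kap)
  expect_true(all(e > 0) && all(diff(e) < 0))
})

test_that("cation-pi LJ term: zeros, depth and pair validation", {
  eps <- 3.35; sigma <- 0.64
  expect_equal(cation_pi_energy(sigma, eps, sigma), 0)
  opt <- optimize(function(r) cation_pi_energy(r, eps, sigma),
                  interval = c(0.5 * sigma, 3 * sigma), tol = 1e-12)
  expect_equal(opt$minimum, 2^(1 / 6) * sigma, tolerance = 1e-7)
  expect_equal(opt$objective, -eps, tolerance = 1e-9)
  expect_silent(cation_pi_energy(1, eps, sigma, pair = c("R", "Y")))
  expect_error(cation_pi_energy(1, eps, sigma, pair = c("G", "S")),
               "cation-pi")
  # only the HPS-cation-pi model carries the term
  expect_false(is.null(load_model("HPS-cation-pi")$eps_catpi))
  for (nm in c("HPS", "HPS-Urry", "CALVADOS2", "Mpipi", "Mpipi-Recharged")) {
    expect_null(load_model(nm)$eps_catpi)
  }
})

test_that("model registry: schemes, constants and validation errors", {
  hps <- load_model("HPS")
  expect_equal(hps$hydrophobic, "ashbaugh_hatch")
  expect_equal(hps$electrostatic, "debye_huckel_fixed")
  expect_equal(hps$kappa, 1.0)
  expect_equal(hps$bond_k, 9.6)
  expect_equal(hps$elec_cutoff, 3.5)
  expect_equal(unique(diag(hps$eps_hyd)), 0.8368)  # 0.2 kcal/mol in kJ/mol
  expect_equal(load_model("HPS-Urry")$elec_cutoff, 2.0)
  expect_equal(load_model("HPS-Urry")$bond_k, 4.8)
  expect_equal(load_model("HPS-cation-pi")$bond_k, 2.4)
  expect_equal(load_model("CALVADOS2")$elec_cutoff, 4.0)
  expect_equal(load_model("CALVADOS2")$electrostatic, "debye_huckel_salt_T")
  mp <- load_model("Mpipi")
  expect_equal(mp$hydrophobic, "wang_frenkel")
  expect_equal(mp$kappa, 1.26)
  mpr <- load_model("Mpipi-Recharged")
  expect_equal(mpr$hydrophobic, "wang_frenkel")
  expect_equal(mpr$electrostatic, "yukawa")
  expect_error(load_model("XYZ"), "unknown model")
  # incomplete table -> validation error naming the missing residues
  tmp <- tempfile()
  dir.create(tmp)
  file.copy(system.file("extdata", "params", package = "cgphase"), tmp,
            recursive = TRUE)
  pdir <- file.path(tmp, "params")
  rt <- read.csv(file.path(pdir, "hps_kr_residues.csv"), comment.char = "#")
  write.csv(rt[rt$res != "W", ], file.path(pdir, "hps_kr_residues.csv"),
            row.names = FALSE)
  expect_error(load_model("HPS", param_dir = pdir), "missing: W")
})

test_that("mixing rules hold exactly for the Lorentz-Berthelot models", {
  for (nm in c("HPS", "HPS-Urry", "CALVADOS2")) {
    m <- load_model(nm)
    lam <- m$residues$lambda
    sig <- m$residues$sigma
    expect_equal(m$lambda_hyd, outer(lam, lam, function(a, b) (a + b) / 2),
                 ignore_attr = TRUE)
    expect_equal(m$sigma_hyd, outer(sig, sig, function(a, b) (a + b) / 2),
                 ignore_attr = TRUE)
  }
})

test_that("pair energies are symmetric under i<->j for every model", {
  for (nm in c("HPS", "HPS-cation-pi", "HPS-Urry", "CALVADOS2", "Mpipi",
               "Mpipi-Recharged")) {
    m <- load_model(nm)
    rm <- cgphase:::resolve_model(m, 310)
    set.seed(7)
    for (k in 1:25) {
      i <- sample(20, 1); j <- sample(20, 1); r <- runif(1, 0.3, 3)
      expect_equal(cgphase:::pair_energy_resolved(rm, i, j, r),
                   cgphase:::pair_energy_resolved(rm, j, i, r),
                   tolerance = 1e-14)
    }
  }
})

test_that("pair energies vanish at and beyond their cutoffs", {
  for (nm in c("HPS", "Mpipi", "Mpipi-Recharged")) {
    m <- load_model(nm)
    rm <- cgphase:::resolve_model(m, 298)
    for (i in c(1, 5, 14)) {
      for (j in c(2, 14, 18)) {
        rcut <- max(rm$hcut[i, j], rm$ecut)
        expect_identical(cgphase:::pair_energy_resolved(rm, i, j, rcut), 0)
        expect_identical(cgphase:::pair_energy_resolved(rm, i, j,
                                                        rcut + 0.5), 0)
      }
    }
  }
})

test_that("engine energy and forces match the brute-force oracle", {
  for (nm in c("HPS", "HPS-cation-pi", "CALVADOS2", "Mpipi",
               "Mpipi-Recharged")) {
    m <- load_model(nm)
    conf <- random_configuration(m, 3, 10, c(4, 4, 4), seed = 42)
    ef <- total_energy_forces(m, conf, 300)
    bf <- brute_force_energy(m, conf, 300)
    expect_equal(ef$energy, bf$energy, tolerance = 1e-10)
    expect_equal(ef$e_bond, bf$e_bond, tolerance = 1e-10)
    # forces are the negative gradient (central differences, h = 1e-5 nm)
    Fn <- numeric_forces(m, conf, 300)
    expect_lt(max(abs(ef$forces - Fn)) / max(abs(Fn)), 1e-4)
  }
})

test_that("energy is invariant under rigid translation", {
  m <- load_model("Mpipi")
  conf <- random_configuration(m, 2, 12, c(5, 5, 5), seed = 9)
  e0 <- total_energy_forces(m, conf, 300)$energy
  shifted <- configuration(sweep(conf$positions, 2, c(1.37, -2.2, 0.61),
                                 "+"),
                           conf$box, conf$chain, conf$residue)
  expect_equal(total_energy_forces(m, shifted, 300)$energy, e0,
               tolerance = 1e-10)
})

test_that("unknown residue codes are rejected", {
  m <- load_model("HPS")
  conf <- configuration(matrix(runif(9), 3, 3) + 1, c(5, 5, 5),
                        c(1, 1, 1), c("A", "B", "G"))
  expect_error(total_energy_forces(m, conf, 300), "unknown residue")
})

test_that("interaction strength matrix is normalized, symmetric and ranks aromatics", {
  for (nm in c("HPS", "HPS-cation-pi", "HPS-Urry", "CALVADOS2", "Mpipi",
               "Mpipi-Recharged")) {
    M <- interaction_strength_matrix(load_model(nm), 298)
    expect_equal(max(M), 1)
    expect_equal(M, t(M), tolerance = 1e-12)
  }
  # hierarchical aromatic parametrizations rank W > Y > F
  for (nm in c("HPS-Urry", "CALVADOS2", "Mpipi", "Mpipi-Recharged")) {
    M <- interaction_strength_matrix(load_model(nm), 298)
    expect_true(M["W", "W"] > M["Y", "Y"])
    expect_true(M["Y", "Y"] > M["F", "F"])
  }
})

test_that("salt/T-dependent models resolve their screening from the laws", {
  m <- load_model("CALVADOS2")
  for (T in c(280, 300, 340)) {
    rm <- cgphase:::resolve_model(m, T)
    er <- dielectric_of_temperature(T)
    expect_equal(rm$eps_r, er)
    expect_equal(rm$kappa, debye_kappa(150, T, er))
  }
})
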