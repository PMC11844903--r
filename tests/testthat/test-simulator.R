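# System construction, Langevin dynamics, virial stress, interop formats.

test_that("slab construction: density arithmetic and determinism", {
  m <- load_model("HPS")
  wt <- a1lcd_variants()[["WT+NLS"]]
  # single chain: density is chain mass over box volume
  conf1 <- build_slab_configuration(m, wt, 1, cross_section = 100,
                                    length = 50, seed = 3)
  mass <- sum(cgphase:::bead_masses(m, strsplit(wt, "")[[1]]))
  expect_equal(mass_density(conf1, m), mass / 5000 * 1.66054e-3,
               tolerance = 1e-12)
  # same seed gives a bitwise-identical configuration
  c1 <- build_slab_configuration(m, wt, 5, cross_section = 64, length = 40,
                                 seed = 11)
  c2 <- build_slab_configuration(m, wt, 5, cross_section = 64, length = 40,
                                 seed = 11)
  expect_identical(c1$positions, c2$positions)
  # no inter-bead separation below the insertion threshold
  rm <- cgphase:::resolve_model(m, 298)
  idx <- match(c1$residue, m$alphabet)
  pos <- c1$positions
  worst <- Inf
  for (i in seq_len(nrow(pos) - 1)) {
    d <- sweep(pos[(i + 1):nrow(pos), , drop = FALSE], 2, pos[i, ])
    d <- sweep(d, 2, c1$box, function(x, L) x - L * round(x / L))
    r <- sqrt(rowSums(d^2))
    sij <- (rm$hsig[idx[i], idx[i]] / 2 +
            diag(rm$hsig)[idx[(i + 1):nrow(pos)]] / 2)
    bonded <- c1$chain[(i + 1):nrow(pos)] == c1$chain[i] &
      seq(i + 1, nrow(pos)) == i + 1
    worst <- min(worst, (r / sij)[!bonded])
  }
  expect_gte(worst, 0.7 - 1e-9)
})

test_that("direct-coexistence slab at production scale has the expected mean density", {
  m <- load_model("HPS")
  wt <- a1lcd_variants()[["WT+NLS"]]
  conf <- build_slab_configuration(m, wt, 200, seed = 1)
  expect_equal(dim(conf$positions), c(200L * nchar(wt), 3L))
  rho <- mass_density(conf, m)
  expect_gt(rho, 0.07)   # ~0.1 g/cm^3 for ~12 kDa chains in 17x17x120 nm
  expect_lt(rho, 0.16)
})

test_that("bulk construction reaches the target density with intact bonds", {
  tm <- toy_model()
  conf <- build_bulk_configuration(tm, toy_sequence(20), 5, 0.25, seed = 2,
                                   temperature = 300, stage_scale = 0.9,
                                   relax_steps = 200)
  expect_equal(length(unique(conf$box)), 1)   # cubic
  expect_lt(abs(mass_density(conf, tm) - 0.25) / 0.25, 0.01)
  expect_lt(max_bond_length(conf), 2 * tm$bond_r0 / 10)
  expect_error(build_bulk_configuration(tm, toy_sequence(20), 5, 0),
               "positive")
})

test_that("zero steps returns the configuration unchanged; runs are deterministic", {
  tm <- toy_model()
  conf <- build_slab_configuration(tm, toy_sequence(10), 4,
                                   cross_section = 25, length = 15,
                                   seed = 2, relax = TRUE,
                                   temperature = 250)
  st0 <- simulation_settings(temperature = 250, n_steps = 0, seed = 1)
  r0 <- suppressWarnings(run_langevin(conf, tm, st0))
  expect_identical(r0$final$positions, conf$positions)
  st <- simulation_settings(temperature = 250, n_steps = 1500, seed = 3,
                            sample_every = 500)
  r1 <- suppressWarnings(run_langevin(conf, tm, st))
  r2 <- suppressWarnings(run_langevin(conf, tm, st))
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  expect_identical(r1$final$velocities, r2$final$velocities)
})

test_that("trajectories are invariant to the Verlet skin choice", {
  tm <- toy_model()
  conf <- build_slab_configuration(tm, toy_sequence(10), 4,
                                   cross_section = 25, length = 15,
                                   seed = 2, relax = TRUE,
                                   temperature = 250)
  st1 <- simulation_settings(temperature = 250, n_steps = 2000, seed = 3,
                             sample_every = 500, skin = 0.3)
  st2 <- simulation_settings(temperature = 250, n_steps = 2000, seed = 3,
                             sample_every = 500, skin = 0.6)
  r1 <- suppressWarnings(run_langevin(conf, tm, st1))
  r2 <- suppressWarnings(run_langevin(conf, tm, st2))
  expect_equal(r1$trajectory$frames[[4]], r2$trajectory$frames[[4]],
               tolerance = 1e-10)
})

test_that("velocity-Verlet (thermostat off) conserves energy on a bound cluster", {
  tm <- toy_model()
  set.seed(1)
  conf <- cgphase:::build_chains(tm, toy_sequence(8), 1, c(20, 20, 20),
                                 z_range = c(8, 12), seed = 4)
  # cold collapsed chain: all pairs stay far from the cutoffs, so the
  # truncated potentials act as smooth ones and drift is integration-only
  warm <- simulation_settings(timestep_fs = 2, temperature = 20,
                              n_steps = 4000, seed = 5)
  w <- run_langevin(conf, tm, warm)$final
  nve <- simulation_settings(timestep_fs = 1, temperature = 20,
                             n_steps = 10000, seed = 5, stress_every = 10,
                             thermostat = FALSE)
  r <- run_langevin(w, tm, nve)
  etot <- r$energies$potential + r$energies$kinetic
  drift <- (max(etot) - min(etot)) / abs(mean(etot))
  expect_lt(drift, 1e-4)
})

test_that("virial stress: ideal gas, analytic pair, exact symmetry", {
  tm <- toy_model()
  # non-interacting beads (far apart): mean pressure = rho kB T
  n <- 64
  L <- 50
  g <- as.matrix(expand.grid(x = (0:3) + 0.5, y = (0:3) + 0.5,
                             z = (0:3) + 0.5)) * (L / 4)
  conf <- configuration(g, c(L, L, L), seq_len(n), rep("X", n))
  Tset <- 300
  set.seed(8)
  P <- replicate(40, {
    vel <- matrix(rnorm(3 * n), n, 3) * sqrt(0.0083144621 * Tset / 100)
    S <- virial_stress(conf, vel, tm, Tset)
    mean(diag(S))
  })
  pid <- n / L^3 * 0.0083144621 * Tset * 16.6054   # bar
  expect_lt(abs(mean(P) - pid) / pid, 0.05)
  # single interacting pair: virial term equals f (x) r by hand
  pos <- rbind(c(2, 2, 2), c(2, 2, 2.45))
  c2 <- configuration(pos, c(8, 8, 8), c(1, 2), c("S", "S"))
  vel0 <- matrix(0, 2, 3)
  S <- virial_stress(c2, vel0, tm, Tset) / 16.6054   # internal units
  ef <- total_energy_forces(tm, c2, Tset)
  f1 <- ef$forces[1, ]
  rvec <- c(0, 0, -0.45)
  expect_equal(S[3, 3], f1[3] * rvec[3] / 8^3, tolerance = 1e-12)
  expect_equal(S[1, 1], 0)
  # symmetry is exact
  set.seed(9)
  vel <- matrix(rnorm(6), 2, 3)
  S2 <- virial_stress(c2, vel, tm, Tset)
  expect_identical(S2[1, 2], S2[2, 1])
  expect_identical(S2[1, 3], S2[3, 1])
})

test_that("thermostatted runs equilibrate to the bath temperature", {
  tm <- toy_model()
  conf <- build_bulk_configuration(tm, toy_sequence(20), 8, 0.25, seed = 4,
                                   temperature = 300, stage_scale = 0.9,
                                   relax_steps = 200)
  st <- simulation_settings(temperature = 300, n_steps = 30000, seed = 6,
                            stress_every = 20)
  r <- suppressWarnings(run_langevin(conf, tm, st))
  Tk <- mean(r$energies$temperature[r$energies$t > 100])
  expect_lt(abs(Tk - 300) / 300, 0.02)
})

test_that("LAMMPS dump and columnar trajectory formats round-trip", {
  tm <- toy_model()
  conf <- build_slab_configuration(tm, toy_sequence(6), 3,
                                   cross_section = 16, length = 12,
                                   seed = 5)
  st <- simulation_settings(temperature = 250, n_steps = 300, seed = 2,
                            sample_every = 100)
  tr <- suppressWarnings(run_langevin(conf, tm, st))$trajectory
  f1 <- tempfile(fileext = ".dump")
  write_lammps_dump(tr, tm, f1)
  back <- read_lammps_dump(f1, alphabet = tm$alphabet)
  expect_equal(length(back$frames), length(tr$frames))
  expect_equal(back$frames[[2]], unname(tr$frames[[2]]), tolerance = 1e-5)
  expect_equal(back$residue, tr$residue)
  f2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f2)
  back2 <- read_trajectory_csv(f2)
  expect_equal(back2$frames[[3]], unname(tr$frames[[3]]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back2$times, tr$times)
  # LAMMPS data file is written with the right counts
  f3 <- tempfile(fileext = ".data")
  write_lammps_data(conf, tm, f3)
  lines <- readLines(f3)
  expect_true(any(grepl("^18 atoms$", lines)))
  expect_true(any(grepl("^15 bonds$", lines)))
})

test_that("stress series CSV round-trips with metadata", {
  s <- synthetic_stress_series(data.frame(G = 1, tau = 0.5), dt = 0.1,
                               length = 500, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_stress_csv(s, f)
  back <- read_stress_csv(f)
  expect_equal(back$sxy, s$sxy, tolerance = 1e-6)
  expect_equal(back$V, s$V)
  expect_equal(back$T, s$T)
  expect_equal(back$units, s$units)
})
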