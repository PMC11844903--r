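#' Synthetic coexistence data from the critical laws
#'
#' Inverts the law of critical exponents, (rho_l - rho_v)^alpha =
#' s1 (1 - T/Tc), and the law of rectilinear diameters, (rho_l + rho_v)/2
#' = rho_c + s2 (Tc - T), to generate exact coexistence points, with
#' optional multiplicative Gaussian noise.  Round-tripping through
#' [fit_critical_point()] recovers the inputs exactly at zero noise.
#'
#' @param T_c critical temperature (K).
#' @param rho_c critical density (g/cm^3).
#' @param s1,s2 law parameters.
#' @param temperatures subcritical temperatures (all < T_c).
#' @param noise_fraction sd of the multiplicative Gaussian noise (0 = exact).
#' @param seed RNG seed.
#' @param alpha critical exponent (default 3.06).
#' @return data.frame (T, rho_l, rho_v) with the generator parameters and
#'   seed attached as the attribute `synthetic_spec`.
#' @export
synthetic_coexistence_dataset <- function(T_c, rho_c, s1, s2, temperatures,
                                          noise_fraction = 0, seed = 1,
                                          alpha = 3.06) {
  if (any(temperatures >= T_c)) {
    stop("all temperatures must lie below T_c")
  }
  gap <- (s1 * (1 - temperatures / T_c))^(1 / alpha)
  mid <- rho_c + s2 * (T_c - temperatures)
  rho_l <- mid + gap / 2
  rho_v <- mid - gap / 2
  if (any(rho_v < 0)) {
    stop("parameters give negative vapour densities; adjust s1/s2/rho_c")
  }
  if (noise_fraction > 0) {
    set.seed(seed)
    rho_l <- rho_l * (1 + noise_fraction * rnorm(length(rho_l)))
    rho_v <- rho_v * (1 + noise_fraction * rnorm(length(rho_v)))
  }
  out <- data.frame(T = temperatures, rho_l = rho_l, rho_v = rho_v)
  attr(out, "synthetic_spec") <- list(generator = "coexistence",
                                      T_c = T_c, rho_c = rho_c, s1 = s1,
                                      s2 = s2, alpha = alpha,
                                      noise_fraction = noise_fraction,
                                      seed = seed)
  out
}

#' Synthetic stress series with a known Maxwell spectrum
#'
#' Superposes independent Ornstein-Uhlenbeck processes, the simplest
#' stationary processes with exponential autocorrelation, so that the
#' Green-Kubo relaxation modulus of the series is exactly
#' G(t) = sum_i G_i exp(-t/tau_i) and the viscosity is sum_i G_i tau_i.
#' The three off-diagonal components carry variance matched to the target;
#' the three normal components carry twice that variance so the
#' normal-stress differences satisfy the isotropic consistency relation
#' <N N> = 4 <sxy sxy> assumed by the six-component estimator.
#'
#' @param modes data.frame with columns `G` (MPa) and `tau` (ps).
#' @param dt sampling interval in ps (must be well below min tau).
#' @param length number of samples.
#' @param noise sd of additional white measurement noise, in units of the
#'   stationary stress sd (0 = none).
#' @param seed RNG seed.
#' @param V volume in nm^3.
#' @param T temperature in K.
#' @return a [stress_series()] (units bar) with the generator parameters
#'   attached as attribute `synthetic_spec`; the exact target viscosity in
#'   mPa s is in `synthetic_spec$eta`.
#' @export
synthetic_stress_series <- function(modes, dt, length, noise = 0, seed = 1,
                                    V = 1000, T = 300) {
  stopifnot(is.data.frame(modes), all(c("G", "tau") %in% names(modes)),
            all(modes$tau > 0), all(modes$G >= 0), length > 1)
  if (any(modes$G > 0) && dt >= min(modes$tau[modes$G > 0])) {
    stop("dt must be smaller than the shortest relaxation time")
  }
  set.seed(seed)
  # stationary variance per mode, in bar^2, from the GK prefactor
  v_int <- (modes$G / (.BAR / 10)) * (.kB * T / V)   # internal units^2
  v_bar <- v_int * .BAR^2
  ou_sum <- function(vars) {
    x <- numeric(length)
    total <- rep(0, length)
    for (i in seq_along(vars)) {
      if (vars[i] == 0) next
      a <- exp(-dt / modes$tau[i])
      b <- sqrt(vars[i] * (1 - a^2))
      xi <- rnorm(length)
      x <- numeric(length)
      x[1] <- rnorm(1, sd = sqrt(vars[i]))
      for (k in 2:length) x[k] <- a * x[k - 1] + b * xi[k]
      total <- total + x
    }
    if (noise > 0) total <- total + rnorm(length, sd = noise *
                                            sqrt(max(sum(vars), 1e-300)))
    total
  }
  s <- stress_series(times = (0:(length - 1)) * dt,
                     sxy = ou_sum(v_bar), sxz = ou_sum(v_bar),
                     syz = ou_sum(v_bar),
                     sxx = ou_sum(2 * v_bar), syy = ou_sum(2 * v_bar),
                     szz = ou_sum(2 * v_bar),
                     V = V, T = T, units = "bar")
  attr(s, "synthetic_spec") <- list(generator = "stress", modes = modes,
                                    dt = dt, length = length, noise = noise,
                                    seed = seed, V = V, T = T,
                                    eta = sum(modes$G * modes$tau) * 1e-3)
  s
}

#' Synthetic two-phase slab configuration
#'
#' Places non-interacting single-bead particles (toy residue "X") with a
#' z-dependent number density following a double-tanh profile between the
#' target vapour and liquid plateaus, the idealized direct-coexistence
#' slab.  The bead count equals the integral of the density over the box
#' (rounded to the nearest bead).
#'
#' @param rho_l,rho_v plateau mass densities in g/cm^3 (rho_l > rho_v >= 0).
#' @param box (Lx, Ly, Lz) in nm; the interface normal is z.
#' @param interface_width tanh width in nm (0 gives a sharp step).
#' @param seed RNG seed.
#' @param bead_mass bead mass in g/mol (default 100, the toy-model bead).
#' @return a [configuration()] (one bead per chain) with the generator
#'   parameters attached as attribute `synthetic_spec`.
#' @export
synthetic_two_phase_frame <- function(rho_l, rho_v, box = c(10, 10, 60),
                                      interface_width = 1, seed = 1,
                                      bead_mass = 100) {
  if (rho_l <= rho_v) stop("rho_l must exceed rho_v")
  set.seed(seed)
  L <- box[3]
  z1 <- L / 4
  z2 <- 3 * L / 4
  nd <- function(rho) rho / .GCM3 / bead_mass  # g/cm^3 -> beads/nm^3
  dens <- function(z) {
    if (interface_width <= 1e-9) {
      ifelse(z > z1 & z < z2, nd(rho_l), nd(rho_v))
    } else {
      nd(rho_v) + (nd(rho_l) - nd(rho_v)) / 2 *
        (tanh((z - z1) / interface_width) -
         tanh((z - z2) / interface_width))
    }
  }
  if (interface_width <= 1e-9) {
    # exact step profile: split the bead budget between the two regions
    Nl <- nd(rho_l) * box[1] * box[2] * (z2 - z1)
    Nv <- nd(rho_v) * box[1] * box[2] * (L - (z2 - z1))
    N <- round(Nl + Nv)
    if (N < 1) {
      stop("box too small to hold a single bead at these densities")
    }
    nl <- round(Nl)
    zl <- runif(nl, z1, z2)
    zv <- runif(N - nl, 0, L - (z2 - z1))
    zv <- ifelse(zv < z1, zv, zv + (z2 - z1))
    z <- c(zl, zv)
  } else {
    zg <- seq(0, L, length.out = 4097)
    dz <- zg[2] - zg[1]
    dvals <- dens(zg)
    total <- sum((dvals[-1] + dvals[-length(dvals)]) / 2 * dz) *
      box[1] * box[2]
    N <- round(total)
    if (N < 1) {
      stop("box too small to hold a single bead at these densities")
    }
    cdf <- cumsum(c(0, (dvals[-1] + dvals[-length(dvals)]) / 2 * dz))
    cdf <- cdf / cdf[length(cdf)]
    keep <- !duplicated(cdf)
    z <- stats::approx(cdf[keep], zg[keep], xout = runif(N))$y
  }
  pos <- cbind(runif(N) * box[1], runif(N) * box[2], z)
  conf <- configuration(pos, box, seq_len(N), rep("X", N))
  attr(conf, "synthetic_spec") <- list(generator = "two_phase",
                                       rho_l = rho_l, rho_v = rho_v,
                                       box = box,
                                       interface_width = interface_width,
                                       seed = seed, bead_mass = bead_mass,
                                       n_beads = N)
  conf
}

#' Wrap a single configuration as a one-frame trajectory
#'
#' @param conf a [configuration()].
#' @return a `cg_trajectory` with one frame at t = 0.
#' @export
as_trajectory <- function(conf) trajectory(list(conf$positions), 0, conf)

#' Three-letter toy model for fast desk-scale tests
#'
#' A minimal Ashbaugh-Hatch + Debye-Hueckel model over the alphabet
#' {S (sticker), X (spacer), C (charged)} with hand-set parameters chosen
#' so that poly(S-X) chains phase-separate at low temperature within
#' minutes of desk compute: the sticker-sticker well (lambda = 1,
#' eps = 4 kJ/mol) is much deeper than spacer-spacer (lambda = 0.3).
#'
#' @return a [cg_model()] over the toy alphabet; passes the same
#'   validation as the packaged models.
#' @export
toy_model <- function() {
  res <- data.frame(res = c("S", "X", "C"),
                    q = c(0, 0, 1),
                    lambda = c(1.0, 0.3, 0.2),
                    sigma = c(0.45, 0.40, 0.45),
                    mass = c(100, 100, 100))
  mix <- function(v) outer(v, v, function(a, b) (a + b) / 2)
  cg_model(name = "toy", residues = res,
           hydrophobic = "ashbaugh_hatch",
           eps_hyd = matrix(4.0, 3, 3),
           sigma_hyd = mix(res$sigma), lambda_hyd = mix(res$lambda),
           electrostatic = "debye_huckel_fixed", kappa = 1.0, eps_r = 80,
           bond_k = 9.6, bond_r0 = 3.81, elec_cutoff = 2.5,
           hyd_cutoff_factor = 3)
}

#' Alternating sticker-spacer toy sequence
#'
#' @param n chain length (default 20).
#' @return "SXSX..." string over the toy alphabet.
#' @export
toy_sequence <- function(n = 20) {
  paste(rep_len(c("S", "X"), n), collapse = "")
}
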