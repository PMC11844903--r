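#' Stress time series container
#'
#' Holds the six independent components of the pressure tensor sampled at
#' uniform intervals, plus the system volume and temperature needed by the
#' Green-Kubo prefactor.
#'
#' @param times sample times in ps (uniformly spaced).
#' @param sxy,sxz,syz off-diagonal stress components.
#' @param sxx,syy,szz normal stress components.
#' @param V system volume in nm^3.
#' @param T temperature in K.
#' @param units stress units, "bar" (default) or "kJ/mol/nm3".
#' @return object of class `stress_series`.
#' @export
stress_series <- function(times, sxy, sxz, syz, sxx, syy, szz, V, T,
                          units = c("bar", "kJ/mol/nm3")) {
  units <- match.arg(units)
  n <- length(times)
  stopifnot(n >= 2, V > 0, T > 0,
            length(sxy) == n, length(sxz) == n, length(syz) == n,
            length(sxx) == n, length(syy) == n, length(szz) == n)
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1]) {
    stop("stress series must be uniformly spaced in time")
  }
  structure(list(times = times, sxy = sxy, sxz = sxz, syz = syz,
                 sxx = sxx, syy = syy, szz = szz, V = V, T = T,
                 units = units, dt = dt[1]),
            class = "stress_series")
}

#' Read/write a stress series as CSV
#'
#' Columns: t, sxy, sxz, syz, sxx, syy, szz; volume, temperature and units
#' are carried in commented header lines.
#'
#' @param stress a [stress_series()].
#' @param path file path.
#' @return `read_stress_csv` returns a [stress_series()].
#' @export
write_stress_csv <- function(stress, path) {
  con <- file(path, "w")
  writeLines(sprintf("# V_nm3 %.10g", stress$V), con)
  writeLines(sprintf("# T_K %.10g", stress$T), con)
  writeLines(sprintf("# units %s", stress$units), con)
  write.csv(data.frame(t = stress$times, sxy = stress$sxy,
                       sxz = stress$sxz, syz = stress$syz,
                       sxx = stress$sxx, syy = stress$syy,
                       szz = stress$szz),
            con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_stress_csv
#' @export
read_stress_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  V <- as.numeric(sub("# V_nm3 ", "", hdr[1]))
  T <- as.numeric(sub("# T_K ", "", hdr[2]))
  units <- sub("# units ", "", hdr[3])
  d <- read.csv(path, comment.char = "#")
  stress_series(d$t, d$sxy, d$sxz, d$syz, d$sxx, d$syy, d$szz,
                V = V, T = T, units = units)
}

# raw (not mean-subtracted) autocorrelation <x(t0+k) x(t0)> averaged over
# all time origins, computed with FFT zero padding
acf_raw <- function(x, max_k) {
  n <- length(x)
  m <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, m - n)))
  s <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
  s[seq_len(max_k + 1)] / (n - 0:max_k)
}

#' Shear stress relaxation modulus from stress fluctuations
#'
#' Green-Kubo estimator.  The six-component form averages the
#' autocorrelations of the three off-diagonal stress components together
#' with the three normal stress differences N_ab = s_aa - s_bb weighted by
#' 1/6, under the prefactor V / (5 kB T):
#' G(t) = V/(5 kB T) [ <sxy sxy> + <sxz sxz> + <syz syz>
#'        + (1/6)(<Nxy Nxy> + <Nxz Nxz> + <Nyz Nyz>) ].
#' The single-component form uses V/(kB T) <sxy(t) sxy(0)> alone.
#' Autocorrelations are multiple-time-origin averages over the full series.
#'
#' @param stress a [stress_series()].
#' @param max_lag maximum lag time in ps (must be below the series span).
#' @param estimator "six_component" (default) or "single".
#' @return object of class `relaxation_modulus`: lag times `t` (ps) and
#'   `G` in MPa.
#' @export
relaxation_modulus <- function(stress, max_lag,
                               estimator = c("six_component", "single")) {
  stopifnot(inherits(stress, "stress_series"))
  estimator <- match.arg(estimator)
  span <- stress$times[length(stress$times)] - stress$times[1]
  if (max_lag >= span) stop("max_lag must be below the series time span")
  ks <- floor(max_lag / stress$dt)
  to_int <- if (stress$units == "bar") 1 / .BAR else 1
  pref <- stress$V / (.kB * stress$T) * to_int^2   # internal units
  if (estimator == "single") {
    C <- acf_raw(stress$sxy, ks)
    G <- pref * C
  } else {
    C <- acf_raw(stress$sxy, ks) + acf_raw(stress$sxz, ks) +
         acf_raw(stress$syz, ks)
    Nxy <- stress$sxx - stress$syy
    Nxz <- stress$sxx - stress$szz
    Nyz <- stress$syy - stress$szz
    CN <- acf_raw(Nxy, ks) + acf_raw(Nxz, ks) + acf_raw(Nyz, ks)
    G <- pref / 5 * (C + CN / 6)
  }
  structure(list(t = (0:ks) * stress$dt, G = G * .BAR / 10,  # -> MPa
                 estimator = estimator),
            class = "relaxation_modulus")
}

#' Construct a relaxation modulus from explicit values
#'
#' @param t lag times in ps.
#' @param G modulus values in MPa.
#' @return object of class `relaxation_modulus`.
#' @export
relaxation_modulus_from_values <- function(t, G) {
  stopifnot(length(t) == length(G), !is.unsorted(t))
  structure(list(t = t, G = G, estimator = "external"),
            class = "relaxation_modulus")
}

#' Choose the numeric/analytic split time t0
#'
#' Returns the earliest lag after which the (smoothed) relaxation modulus
#' is strictly positive and decays monotonically over a sliding window of
#' one decade in time, i.e. the point where intramolecular oscillations
#' have died out and the Maxwell-mode fit becomes meaningful.
#'
#' @param G a `relaxation_modulus`.
#' @param window_decades monotonicity window length in decades (default 1).
#' @param smooth half-width (points) of the running-mean smoother.
#' @param rise_tol allowed relative rise between consecutive smoothed
#'   points within the window (guards against estimator noise).
#' @return t0 in ps.
#' @export
choose_t0 <- function(G, window_decades = 1, smooth = 2, rise_tol = 0.05) {
  stopifnot(inherits(G, "relaxation_modulus"))
  g <- G$G
  t <- G$t
  n <- length(g)
  if (smooth > 0) {
    k <- 2 * smooth + 1
    gs <- stats::filter(g, rep(1 / k, k), sides = 2)
    gs[is.na(gs)] <- g[is.na(gs)]
    g <- as.numeric(gs)
  }
  for (i in seq_len(n - 1)) {
    t_end <- max(t[i] * 10^window_decades, t[i] + (t[2] - t[1]))
    idx <- which(t >= t[i] & t <= t_end)
    if (length(idx) < 2) idx <- i:min(i + 1, n)
    seg <- g[idx]
    if (all(seg > 0) &&
        all(diff(seg) <= rise_tol * pmax(seg[-length(seg)], 1e-300))) {
      return(t[i])
    }
  }
  stop("no lag found after which G(t) is positive and decays ",
       "monotonically; sample a longer stress series")
}

#' Fit Maxwell modes to the relaxation modulus tail
#'
#' Non-negative least squares for the amplitudes {G_i} on a fixed set of
#' relaxation times {tau_i} equidistant in logarithmic time spanning
#' [t0, t_max], so the tail is represented as sum_i G_i exp(-t/tau_i).
#'
#' @param G a `relaxation_modulus`.
#' @param t0 split time in ps (within the lag range).
#' @param M number of modes; default 4 per decade of [t0, t_max].
#' @return object of class `maxwell_spectrum`: `t0`, `tau` (ps, strictly
#'   increasing, log-equidistant), `G_i` (MPa, >= 0), fit residuals.
#' @export
fit_maxwell_modes <- function(G, t0, M = NULL) {
  stopifnot(inherits(G, "relaxation_modulus"))
  t_max <- max(G$t)
  if (t0 < 0 || t0 >= t_max) stop("t0 must lie within the lag range")
  lo <- max(t0, G$t[2])          # tau grid cannot start at 0
  decades <- log10(t_max / lo)
  if (is.null(M)) M <- max(1L, ceiling(4 * decades))
  if (M < 1) stop("need at least one Maxwell mode")
  tau <- if (M == 1) sqrt(lo * t_max) else 10^seq(log10(lo), log10(t_max),
                                                  length.out = M)
  idx <- which(G$t >= t0)
  A <- exp(-outer(G$t[idx], tau, "/"))
  cnd <- tryCatch(kappa(crossprod(A), exact = FALSE), error = function(e) Inf)
  if (!is.finite(cnd) || cnd > 1e12) {
    warning("ill-conditioned Maxwell-mode fit (condition estimate ",
            format(cnd, digits = 3), ")")
  }
  fit <- pracma::lsqnonneg(A, G$G[idx])
  structure(list(t0 = t0, tau = tau, G_i = fit$x,
                 residuals = A %*% fit$x - G$G[idx], M = M),
            class = "maxwell_spectrum")
}

#' @export
print.maxwell_spectrum <- function(x, ...) {
  cat(sprintf("maxwell_spectrum: %d modes, t0 = %.3g ps\n", x$M, x$t0))
  on <- x$G_i > 0
  if (any(on)) {
    print(data.frame(tau_ps = x$tau[on], G_MPa = x$G_i[on]),
          row.names = FALSE)
  }
  invisible(x)
}

#' Viscosity from the hybrid numeric + Maxwell-mode scheme
#'
#' eta = integral of G over [0, t0] by the trapezoidal rule, plus the
#' analytic tail sum_i G_i tau_i of the fitted Maxwell modes.
#'
#' @param G a `relaxation_modulus` (MPa vs ps).
#' @param spectrum a `maxwell_spectrum` fitted to the same modulus.
#' @return viscosity in mPa s (1 MPa ps = 1e-3 mPa s).
#' @seealso [viscosity_numeric()] for the purely numeric integral.
#' @export
viscosity <- function(G, spectrum) {
  stopifnot(inherits(G, "relaxation_modulus"),
            inherits(spectrum, "maxwell_spectrum"))
  idx <- which(G$t <= spectrum$t0)
  eta_short <- if (length(idx) >= 2) {
    pracma::trapz(G$t[idx], G$G[idx])
  } else 0
  eta <- (eta_short + sum(spectrum$G_i * spectrum$tau)) * 1e-3
  if (eta < 0) {
    stop("negative viscosity; the Maxwell-mode fit is unreliable")
  }
  eta
}

#' Purely numeric Green-Kubo viscosity
#'
#' Trapezoidal integral of G(t) over the full sampled lag range; the
#' cross-check for the hybrid estimate.
#'
#' @param G a `relaxation_modulus`.
#' @return viscosity in mPa s.
#' @export
viscosity_numeric <- function(G) {
  stopifnot(inherits(G, "relaxation_modulus"))
  pracma::trapz(G$t, G$G) * 1e-3
}
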