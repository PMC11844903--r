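#' Mass density profile along the long axis
#'
#' Bins bead mass along the chosen axis.  By default each frame is first
#' recentred on the condensate's periodic (circular-mean) centre of mass so
#' slab drift does not smear the plateaus, then profiles are averaged over
#' frames.
#'
#' @param traj a `cg_trajectory`.
#' @param model model supplying residue masses.
#' @param n_bins number of bins (>= 4).
#' @param axis profile axis, "x", "y" or "z" (default the elongated z).
#' @param recenter recentre each frame on the mass centre (default TRUE).
#' @return object of class `density_profile`: list with bin centres `z`
#'   (nm), mean `density` (g/cm^3), the per-frame profile matrix and the
#'   frame count.  The bin integral times the cross-section recovers the
#'   total mass.
#' @export
density_profile <- function(traj, model, n_bins = 100, axis = "z",
                            recenter = TRUE) {
  stopifnot(inherits(traj, "cg_trajectory"), length(traj$frames) >= 1)
  if (n_bins < 4) stop("n_bins must be at least 4")
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  L <- traj$box[ax]
  cross <- prod(traj$box[-ax])
  masses <- bead_masses(model, traj$residue)
  edges <- seq(0, L, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  vbin <- cross * L / n_bins
  prof <- matrix(0, length(traj$frames), n_bins)
  for (k in seq_along(traj$frames)) {
    zz <- traj$frames[[k]][, ax]
    if (recenter) {
      # circular mean of the mass distribution, shifted to L/2
      th <- 2 * pi * zz / L
      mu <- atan2(sum(masses * sin(th)), sum(masses * cos(th)))
      zc <- (mu / (2 * pi)) * L
      zz <- (zz - zc + L / 2) %% L
    }
    bin <- pmin(pmax(ceiling(zz / L * n_bins), 1L), n_bins)
    prof[k, ] <- tapply(masses, factor(bin, levels = seq_len(n_bins)),
                        sum, default = 0) / vbin * .GCM3
  }
  structure(list(z = centers, density = colMeans(prof),
                 per_frame = prof, n_frames = length(traj$frames),
                 box = traj$box, axis = axis),
            class = "density_profile")
}

tanh_profile <- function(z, rho_v, drho, z1, z2, w) {
  rho_v + drho / 2 * (tanh((z - z1) / w) - tanh((z - z2) / w))
}

#' Coexistence densities from a slab density profile
#'
#' Default method fits the averaged profile with a double hyperbolic-
#' tangent interface shape, `rho(z) = rho_v + (rho_l - rho_v)/2 *
#' (tanh((z - z1)/w) - tanh((z - z2)/w))`, and reads the plateau densities
#' from the fit.  The alternative `"plateau"` method averages the central
#' condensate region and the far vapour region directly.  Profiles without
#' a distinguishable interface yield a single-phase signal rather than a
#' density pair.
#'
#' @param profile a [density_profile()].
#' @param method "tanh" (default) or "plateau".
#' @param n_boot bootstrap resamples (over frames) for the uncertainties;
#'   0 disables.
#' @param flat_tol declare single phase when the profile contrast
#'   (max - min)/mean falls below this value.
#' @return list with `rho_l`, `rho_v` (g/cm^3), their uncertainties
#'   `se_l`, `se_v`, `single_phase` flag and the fit details.
#' @export
coexistence_densities <- function(profile, method = c("tanh", "plateau"),
                                  n_boot = 30, flat_tol = 0.25) {
  stopifnot(inherits(profile, "density_profile"))
  method <- match.arg(method)
  rho <- profile$density
  z <- profile$z
  contrast <- (max(rho) - min(rho)) / max(mean(rho), 1e-12)
  if (contrast < flat_tol) {
    return(list(rho_l = NA_real_, rho_v = NA_real_, se_l = NA_real_,
                se_v = NA_real_, single_phase = TRUE, method = method))
  }
  est <- function(rho) {
    if (method == "plateau") {
      thr <- (max(rho) + min(rho)) / 2
      dense <- rho >= thr
      list(rho_l = mean(rho[dense]), rho_v = mean(rho[!dense]))
    } else {
      L <- max(z)
      dense <- rho >= (max(rho) + min(rho)) / 2
      width <- sum(dense) / length(rho) * L
      start <- list(rho_v = max(min(rho), 1e-6), drho = max(rho) - min(rho),
                    z1 = L / 2 - width / 2, z2 = L / 2 + width / 2,
                    w = L / 50)
      fit <- minpack.lm::nlsLM(
        rho ~ tanh_profile(z, rho_v, drho, z1, z2, w),
        data = data.frame(z = z, rho = rho), start = start,
        lower = c(0, 0, 0, 0, 1e-3), upper = c(max(rho), 2 * max(rho), L, L, L),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- coef(fit)
      list(rho_l = unname(cf["rho_v"] + cf["drho"]),
           rho_v = unname(cf["rho_v"]), fit = fit)
    }
  }
  main <- est(rho)
  if (!is.finite(main$rho_l) ||
      (main$rho_l - main$rho_v) < flat_tol * mean(rho)) {
    return(list(rho_l = NA_real_, rho_v = NA_real_, se_l = NA_real_,
                se_v = NA_real_, single_phase = TRUE, method = method))
  }
  se_l <- se_v <- NA_real_
  if (n_boot > 0 && profile$n_frames > 1) {
    bs <- replicate(n_boot, {
      idx <- sample.int(profile$n_frames, replace = TRUE)
      m <- tryCatch(est(colMeans(profile$per_frame[idx, , drop = FALSE])),
                    error = function(e) list(rho_l = NA, rho_v = NA))
      c(m$rho_l, m$rho_v)
    })
    se_l <- sd(bs[1, ], na.rm = TRUE)
    se_v <- sd(bs[2, ], na.rm = TRUE)
  }
  list(rho_l = main$rho_l, rho_v = main$rho_v, se_l = se_l, se_v = se_v,
       single_phase = FALSE, method = method, fit = main$fit)
}

# joint fit of the scaling law and rectilinear-diameter law at fixed Tc:
# (rho_l - rho_v)^alpha = s1 (1 - T/Tc)   [exponent on the density gap]
# (rho_l + rho_v)/2     = rho_c + s2 (Tc - T)
# Both inner problems are linear, so Tc can be profiled exactly.
critfit_inner <- function(Tc, T, gap_a, mid) {
  x1 <- 1 - T / Tc
  s1 <- sum(x1 * gap_a) / sum(x1 * x1)
  r1 <- gap_a - s1 * x1
  x2 <- Tc - T
  f2 <- lm.fit(cbind(1, x2), mid)
  list(s1 = s1, rho_c = unname(f2$coefficients[1]),
       s2 = unname(f2$coefficients[2]),
       rss = sum(r1^2) + sum(f2$residuals^2))
}

#' Fit the critical point from coexistence data
#'
#' Joint nonlinear least squares of the law of critical exponents,
#' (rho_l - rho_v)^alpha = s1 (1 - T/Tc) with the 3D-Ising exponent alpha
#' fixed at 3.06, and the law of rectilinear diameters, (rho_l + rho_v)/2
#' = rho_c + s2 (Tc - T), equally weighted.  Given Tc both laws are linear
#' in the remaining parameters, so Tc is profiled by one-dimensional
#' optimization.  The Tc uncertainty is estimated from refits restricted to
#' the last two, three and four temperatures (the points closest to the
#' critical region).
#'
#' @param points data.frame with columns `T` (K), `rho_l`, `rho_v`
#'   (g/cm^3); at least 3 subcritical state points.
#' @param alpha critical exponent (default 3.06).
#' @return object of class `critical_point`: list with `Tc`, `rho_c`,
#'   `s1`, `s2`, `alpha`, `dTc` (half-range of the subset refits) and the
#'   subset estimates.
#' @export
fit_critical_point <- function(points, alpha = 3.06) {
  stopifnot(is.data.frame(points),
            all(c("T", "rho_l", "rho_v") %in% names(points)))
  points <- points[order(points$T), ]
  n <- nrow(points)
  if (n < 3) stop("need at least 3 coexistence points")
  if (any(points$rho_l <= points$rho_v)) {
    stop("rho_l must exceed rho_v for every point")
  }
  gap <- points$rho_l - points$rho_v
  if (any(diff(gap) > 0)) {
    warning("density gap is not monotonically decreasing with T")
  }
  fit_once <- function(pts) {
    gap_a <- (pts$rho_l - pts$rho_v)^alpha
    mid <- (pts$rho_l + pts$rho_v) / 2
    Tmax <- max(pts$T)
    obj <- function(Tc) critfit_inner(Tc, pts$T, gap_a, mid)$rss
    # bracket: Tc just above the highest simulated temperature up to 3x
    opt <- optimize(obj, interval = c(Tmax * (1 + 1e-6), Tmax * 3),
                    tol = .Machine$double.eps^0.5 * Tmax)
    # polish with Brent around the optimum for tight recovery
    opt2 <- optimize(obj, interval = c(opt$minimum * 0.999,
                                       opt$minimum * 1.001),
                     tol = .Machine$double.eps^0.6 * Tmax)
    Tc <- if (opt2$objective < opt$objective) opt2$minimum else opt$minimum
    c(list(Tc = Tc), critfit_inner(Tc, pts$T, gap_a, mid))
  }
  full <- fit_once(points)
  subsets <- list()
  for (k in 2:4) {
    if (n >= k) {
      subsets[[paste0("last", k)]] <-
        fit_once(points[(n - k + 1):n, , drop = FALSE])$Tc
    }
  }
  sub <- unlist(subsets)
  dTc <- if (length(sub) > 1) (max(sub) - min(sub)) / 2 else 0
  structure(list(Tc = full$Tc, rho_c = full$rho_c, s1 = full$s1,
                 s2 = full$s2, alpha = alpha, dTc = dTc,
                 subset_Tc = sub, n_points = n, rss = full$rss),
            class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("critical point: Tc = %.2f +/- %.2f K, rho_c = %.4f g/cm^3\n",
              x$Tc, x$dTc, x$rho_c))
  cat(sprintf("  s1 = %.4g, s2 = %.4g (alpha = %.2f, %d points)\n",
              x$s1, x$s2, x$alpha, x$n_points))
  invisible(x)
}
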