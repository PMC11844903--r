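# Green-Kubo relaxation modulus, t0 selection, Maxwell modes, viscosity.

test_that("constant stress gives the degenerate constant modulus", {
  n <- 400
  c0 <- 30   # bar
  s <- stress_series((0:(n - 1)) * 0.1, sxy = rep(c0, n), sxz = rep(0, n),
                     syz = rep(0, n), sxx = rep(0, n), syy = rep(0, n),
                     szz = rep(0, n), V = 500, T = 300)
  G <- relaxation_modulus(s, max_lag = 10)
  # analytic: V/(5 kBT) * [c0^2 + (1/6)(2 c0^... )]; with only sxy set,
  # N-differences vanish, so G = V/(5kBT) c0^2 (constant at all lags)
  conv <- 16.6054
  expected <- 500 / (5 * 0.0083144621 * 300) * (c0 / conv)^2 * conv / 10
  expect_equal(G$G, rep(expected, length(G$G)), tolerance = 1e-10)
  expect_error(relaxation_modulus(s, max_lag = 1000), "below the series")
})

test_that("white-noise stress decorrelates beyond lag zero", {
  set.seed(5)
  n <- 20000
  mk <- function() rnorm(n)
  s <- stress_series((0:(n - 1)) * 0.1, mk(), mk(), mk(), mk(), mk(),
                     mk(), V = 500, T = 300)
  G <- relaxation_modulus(s, max_lag = 50)
  # i.i.d. noise: G(t>0) consistent with zero at the estimator noise
  # level (at most a few percent of lags beyond 3 sd)
  sd0 <- sd(G$G[-1])
  expect_lt(mean(abs(G$G[-1]) > 3 * sd0), 0.05)
  expect_lt(max(abs(G$G[-1])), 6 * sd0)
  expect_gt(G$G[1], 10 * sd0)
})

test_that("six-component and single-component estimators agree", {
  modes <- data.frame(G = 2, tau = 1)
  s <- synthetic_stress_series(modes, dt = 0.02, length = 100000,
                               seed = 11)
  G6 <- relaxation_modulus(s, max_lag = 10)
  G1 <- relaxation_modulus(s, max_lag = 10, estimator = "single")
  # both estimate the same target; agreement within estimator noise
  target <- 2 * exp(-G6$t / 1)
  expect_lt(mean(abs(G6$G - target)[G6$t < 3]), 0.1)
  expect_lt(mean(abs(G1$G - target)[G1$t < 3]), 0.25)
  expect_lt(mean(abs(G6$G - G1$G)[G6$t < 3]), 0.3)
})

test_that("t0 selection handles monotone, oscillatory and hopeless moduli", {
  t <- seq(0, 20, by = 0.05)
  mono <- relaxation_modulus_from_values(t, 3 * exp(-t / 2))
  expect_equal(choose_t0(mono), 0)
  # one negative excursion at small lag: t0 moves past it
  osc <- 3 * exp(-t / 2) - 4 * exp(-t / 0.3)
  Gosc <- relaxation_modulus_from_values(t, osc)
  t0 <- choose_t0(Gosc, smooth = 0)
  expect_gt(t0, 0.1)       # the excursion is negative up to t ~ 0.1
  expect_true(all(osc[t >= t0] > 0))
  allneg <- relaxation_modulus_from_values(t, -1 - 0 * t)
  expect_error(choose_t0(allneg), "longer")
})

test_that("Maxwell-mode fit recovers a representable single mode", {
  t <- seq(0, 100, by = 0.01)
  G0 <- 2.5
  G <- relaxation_modulus_from_values(t, G0 * exp(-t / 1))
  # log-equidistant grid 1e-2..1e2 with 5 modes contains tau = 1 exactly
  sp <- fit_maxwell_modes(G, t0 = 0.01, M = 5)
  expect_equal(sp$tau, 10^seq(-2, 2, length.out = 5))
  on <- which(sp$G_i > 1e-6)
  expect_equal(sp$tau[on], 1)
  expect_lt(abs(sp$G_i[on] - G0) / G0, 1e-4)
  expect_error(fit_maxwell_modes(G, t0 = 0.01, M = 0), "at least one")
  expect_error(fit_maxwell_modes(G, t0 = 1e5), "within the lag range")
})

test_that("three-mode fits leave negligible residuals on exact data", {
  t <- seq(0, 1000, by = 0.1)
  Gv <- 2 * exp(-t / 1) + 1 * exp(-t / 10) + 0.3 * exp(-t / 100)
  G <- relaxation_modulus_from_values(t, Gv)
  sp <- fit_maxwell_modes(G, t0 = 0.1, M = 9)  # grid 1e-1..1e3 hits taus
  expect_lt(max(abs(sp$residuals)), 1e-8)
})

test_that("viscosity: closed forms and hybrid-vs-numeric consistency", {
  # single exponential with t0 = 0: eta = G0 tau exactly
  t <- seq(0, 100, by = 0.01)
  G0 <- 2.5
  G <- relaxation_modulus_from_values(t, G0 * exp(-t / 1))
  sp <- fit_maxwell_modes(G, t0 = 0.01, M = 5)
  sp$t0 <- 0
  expect_equal(viscosity(G, sp), G0 * 1 * 1e-3, tolerance = 1e-6)
  # zero modulus integrates to zero
  Gz <- relaxation_modulus_from_values(t, 0 * t)
  expect_equal(viscosity_numeric(Gz), 0)
  # hybrid equals the full numeric integral on dense multimode data
  t2 <- seq(0, 2000, by = 0.05)
  Gv <- 2 * exp(-t2 / 1) + 1 * exp(-t2 / 10) + 0.3 * exp(-t2 / 100)
  G2 <- relaxation_modulus_from_values(t2, Gv)
  t0 <- choose_t0(G2)
  sp2 <- fit_maxwell_modes(G2, t0 = max(t0, 0.05))
  eta_h <- viscosity(G2, sp2)
  eta_n <- viscosity_numeric(G2)
  expect_lt(abs(eta_h - eta_n) / eta_n, 0.01)
})

test_that("scaling stress by c scales G by c^2 and eta by c^2", {
  modes <- data.frame(G = c(1.5, 0.5), tau = c(0.5, 5))
  s <- synthetic_stress_series(modes, dt = 0.02, length = 50000, seed = 3)
  s2 <- s
  for (comp in c("sxy", "sxz", "syz", "sxx", "syy", "szz")) {
    s2[[comp]] <- 3 * s[[comp]]
  }
  G1 <- relaxation_modulus(s, max_lag = 20)
  G2 <- relaxation_modulus(s2, max_lag = 20)
  expect_equal(G2$G, 9 * G1$G, tolerance = 1e-10)
  sp1 <- fit_maxwell_modes(G1, t0 = 0.02)
  sp2 <- fit_maxwell_modes(G2, t0 = 0.02)
  expect_equal(viscosity(G2, sp2), 9 * viscosity(G1, sp1),
               tolerance = 1e-6)
})

test_that("generated Maxwell stress recovers the known viscosity", {
  modes <- data.frame(G = 2, tau = 1)
  s <- synthetic_stress_series(modes, dt = 0.02, length = 200000,
                               seed = 11)
  G <- relaxation_modulus(s, max_lag = 20)
  sp <- fit_maxwell_modes(G, t0 = max(choose_t0(G), 0.02))
  eta <- viscosity(G, sp)
  expect_lt(abs(eta - 2e-3) / 2e-3, 0.1)
  # two well-separated modes: fitted times bracket the truth
  modes2 <- data.frame(G = c(2, 0.5), tau = c(0.5, 20))
  s2 <- synthetic_stress_series(modes2, dt = 0.02, length = 400000,
                                seed = 21)
  G2 <- relaxation_modulus(s2, max_lag = 200)
  sp2 <- fit_maxwell_modes(G2, t0 = 0.02)
  on <- sp2$G_i > 0.05 * max(sp2$G_i)
  expect_true(any(sp2$tau[on] > 0.5 / 1.5 & sp2$tau[on] < 0.5 * 1.5))
  expect_true(any(sp2$tau[on] > 20 / 1.5 & sp2$tau[on] < 20 * 1.5))
})

test_that("unit audit: bar input yields mPa s through the documented chain", {
  # deterministic sanity: a constant G of 1 MPa over 1 ps integrates to
  # 1 MPa ps = 1e-3 mPa s
  t <- seq(0, 1, by = 0.001)
  G <- relaxation_modulus_from_values(t, rep(1, length(t)))
  expect_equal(viscosity_numeric(G), 1e-3, tolerance = 1e-12)
  # and the estimator's prefactor converts bar^2 stress correctly:
  # G(0) = V/(5 kBT) * 3 var(sxy) for centred isotropic white input
  set.seed(2)
  n <- 200000
  x <- rnorm(n, sd = 10)
  s <- stress_series((0:(n - 1)) * 0.1, x, rnorm(n, sd = 10),
                     rnorm(n, sd = 10), rep(0, n), rep(0, n), rep(0, n),
                     V = 800, T = 310)
  G0 <- relaxation_modulus(s, max_lag = 1)$G[1]
  conv <- 16.6054
  expected <- 800 / (5 * 0.0083144621 * 310) * 3 * (10 / conv)^2 *
    conv / 10
  expect_lt(abs(G0 - expected) / expected, 0.02)
})
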