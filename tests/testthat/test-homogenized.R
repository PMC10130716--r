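# Homogenized Robin-boundary model.

test_that("the effective permeability formula behaves as derived", {
  expect_equal(homogenized_permeability(100, pi / 100, 1), 206.98,
               tolerance = 1e-4)
  # log argument 4/e makes kappa = N D / 2 exactly
  expect_equal(homogenized_permeability(20, 4 / (exp(1) * 20), 2), 20)
  # perfectly absorbing limit as the covering saturates
  expect_gt(homogenized_permeability(100, 3.9999 / 100, 1), 1e5)
  expect_error(homogenized_permeability(100, 0.05, 1), "regime")
})

test_that("Robin flux modes match direct Bessel evaluation and their limits", {
  # kappa -> infinity, m = 0, alpha = 1, R = 2: K0(2)/K0(1)
  mod_inf <- homogenized_model(Inf, R = 2, D = 1)
  expect_equal(Re(robin_flux_mode(0, 1 + 0i, mod_inf)),
               besselK(2, 0) / besselK(1, 0), tolerance = 1e-10)
  expect_equal(Re(robin_flux_mode(0, 1 + 0i, mod_inf)), 0.27052,
               tolerance = 1e-4)
  # immediate capture: R -> 1 with kappa -> infinity gives chi_m -> 1
  mod_close <- homogenized_model(Inf, R = 1 + 1e-9, D = 1)
  expect_equal(Re(robin_flux_mode(0:3, 0.7 + 0i, mod_close)), rep(1, 4),
               tolerance = 1e-6)
  # certain eventual capture: chi_0 climbs to 1 as alpha -> 0 at finite
  # kappa (logarithmically, as for all two-dimensional recurrence limits)
  mod <- homogenized_model(10, R = 3, D = 1)
  chi0 <- Re(vapply(c(1e-3, 1e-6, 1e-12), function(a) {
    robin_flux_mode(0, complex(real = a), mod)
  }, complex(1)))
  expect_true(all(diff(chi0) > 0))
  expect_gt(chi0[3], 0.9)
  expect_true(all(chi0 < 1))
})

test_that("the half-covered cell has captured about 60 percent of particles at t = 1000", {
  kap <- homogenized_permeability(100, pi / 100, 1)
  mod <- homogenized_model(kap, R = 5, D = 1)
  # the transition-time figure quoted as "approximately 60%" is the capture
  # CDF at t = 1e3; the surviving fraction is its complement
  expect_lt(abs(homog_capture_cdf(1e3, mod) - 0.60), 0.03)
  expect_equal(homog_survival(1e3, mod) + homog_capture_cdf(1e3, mod), 1)
  # survival is a proper decreasing tail
  ts <- 10^seq(1, 6, by = 1)
  sv <- homog_survival(ts, mod)
  expect_true(all(diff(sv) < 0))
  expect_lt(sv[length(sv)], 0.25)
  expect_true(all(sv > 0 & sv < 1))
})

test_that("angular flux density integrates to the total flux mode", {
  kap <- 206.98
  mod <- homogenized_model(kap, R = 2, D = 1)
  tt <- 0.5
  th <- seq(-pi, pi, length.out = 2001)
  J <- homogenized_flux_density(th, tt, mod)
  M0 <- talbot_invert(function(s) {
    vapply(seq_along(s), function(j) {
      robin_flux_mode(0, sqrt(s[j] / mod$D), mod)
    }, complex(1))
  }, tt)
  expect_equal(trapz(th, J), M0, tolerance = 1e-6)
  expect_true(all(J > -1e-10))
  # flux concentrates towards the source direction
  expect_gt(J[1001], max(J[c(1, 2001)]))
})

test_that("mode ratio decays to zero as the flux becomes radially symmetric", {
  kap <- homogenized_permeability(100, pi / 100, 1)
  mod <- homogenized_model(kap, R = 5, D = 1)
  ts <- 10^seq(2, 4, by = 0.5)
  mr <- mode_ratio(ts, mod)
  expect_true(all(diff(abs(mr)) < 0))   # monotone decay on these scales
  expect_lt(abs(mr[length(mr)]), 0.05)
  # fully directional limit: source at the membrane, short time
  mod_close <- homogenized_model(1e4, R = 1.001, D = 1)
  expect_gt(mode_ratio(1e-5, mod_close), 0.95)
})

test_that("short-time moments match the inverse transform and Gaussian limit", {
  mod <- homogenized_model(206.98, R = 2, D = 1, theta0 = 0)
  ts <- 10^seq(-4, -2, by = 0.5)
  m <- short_time_moments(ts, mod)
  M0_num <- vapply(ts, function(tt) {
    talbot_invert(function(s) {
      vapply(seq_along(s), function(j) {
        robin_flux_mode(0, sqrt(s[j] / mod$D), mod)
      }, complex(1))
    }, tt)
  }, numeric(1))
  expect_equal(m$M0, M0_num, tolerance = 0.05)
  expect_equal(m$variance, 2 * mod$D * ts / mod$R)
  expect_equal(m$kurtosis, rep(3, length(ts)))
  # numerical angular variance of the full mode series approaches 2Dt/R
  tt <- 1e-3
  th <- seq(-0.5, 0.5, length.out = 4001)
  J <- homogenized_flux_density(th, tt, mod)
  v_num <- trapz(th, th^2 * J) / trapz(th, J)
  expect_equal(v_num, 2 * mod$D * tt / mod$R, tolerance = 0.02)
  # Gaussian approximation: correct normalization, shrinking total-variation
  # distance as t -> 0+
  tv <- vapply(c(0.2, 0.1, 0.05, 0.02), function(tt) {
    th <- seq(-pi, pi, length.out = 4001)
    J <- homogenized_flux_density(th, tt, mod)
    G <- suppressWarnings(gaussian_flux_approx(th, tt, mod))
    trapz(th, abs(J - G)) / trapz(th, abs(J))
  }, numeric(1))
  expect_true(all(diff(tv) < 0))
  expect_lt(tv[4], 0.02)
  g <- gaussian_flux_approx(seq(-pi, pi, length.out = 4001), 1e-3, mod)
  expect_equal(trapz(seq(-pi, pi, length.out = 4001), g),
               short_time_moments(1e-3, mod)$M0, tolerance = 1e-6)
})

test_that("discrete receptor fluxes converge to the Robin modes as N grows", {
  # uniform coverings at fixed eps*N (half coverage), source at R = 2
  s0 <- 1 + 0i
  src <- source_spec(2, theta0 = 0.3, D = 1)
  for (q in 0:2) {
    err <- numeric(0)
    psi <- numeric(0)
    for (N in c(16, 32, 64, 128)) {
      cfg <- uniform_config(N, pi / N)          # eps*N = pi throughout
      kap <- homogenized_permeability(N, pi / N, 1)
      chi_q <- robin_flux_mode(q, sqrt(s0),
                               homogenized_model(kap, R = 2, D = 1))
      ff <- discrete_fourier_flux(cfg, src, s0, q)
      err <- c(err, Mod(ff$chi_bar - chi_q))
      psi <- c(psi, Mod(ff$psi_bar))
    }
    expect_true(all(diff(err) < 0))
    expect_lt(err[4], 0.02)
    expect_lt(psi[4], 1e-6)             # sine parts vanish
  }
})
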