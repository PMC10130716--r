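# Green's functions: special-function layer, then PDE-level verification of
# the closed forms against independent finite-difference oracles.

test_that("complex scaled Bessel K0/K1 agrees with base besselK on the real axis", {
  xs <- c(1e-3, 0.1, 0.5, 2, 5, 9, 11, 13, 20, 80, 500)
  got <- besselk01(complex(real = xs))
  expect_equal(Re(got[, 1]), besselK(xs, 0, expon.scaled = TRUE),
               tolerance = 1e-10)
  expect_equal(Re(got[, 2]), besselK(xs, 1, expon.scaled = TRUE),
               tolerance = 1e-10)
  expect_true(all(abs(Im(got)) < 1e-12))
})

test_that("complex Bessel K is conjugate-symmetric and consistent across regime boundaries", {
  zs <- complex(real = c(0.4, 2, 4, 11.9, 12.1, 3, 0.3),
                imaginary = c(0.8, 9, 10, 1, 1, 11.3, 9))
  k <- besselk01(zs)
  kc <- besselk01(Conj(zs))
  expect_equal(kc, Conj(k), tolerance = 1e-12)
  # K0' = -K1: finite-difference check along a complex direction
  h <- 1e-6
  for (z in c(1.5 + 2i, 8 + 4i, 14 + 3i)) {
    k0 <- function(w) unname(besselk01(w)[1, 1]) * exp(-w)   # unscaled
    deriv <- (k0(z + h) - k0(z - h)) / (2 * h)
    expect_equal(deriv, unname(-besselk01(z)[1, 2]) * exp(-z),
                 tolerance = 1e-7)
  }
})

test_that("Laplace surface Green's function satisfies its defining properties", {
  xi <- c(0, 1)
  # candidate closed-form value
  expect_equal(laplace_surface_green(c(2, 0), xi),
               (-log(5) / 2 + log(2) / 2) / pi, tolerance = 1e-12)
  expect_equal(laplace_surface_green(c(2, 0), xi), -0.14583, tolerance = 1e-4)
  # harmonic: five-point Laplacian residual at interior points of the domain
  h <- 1e-3
  for (x in list(c(1.7, 0.4), c(2.5, -1.2))) {
    lap <- (laplace_surface_green(c(x[1] + h, x[2]), xi) +
            laplace_surface_green(c(x[1] - h, x[2]), xi) +
            laplace_surface_green(c(x[1], x[2] + h), xi) +
            laplace_surface_green(c(x[1], x[2] - h), xi) -
            4 * laplace_surface_green(x, xi)) / h^2
    expect_lt(abs(lap), 1e-6)
  }
  # reflecting: radial derivative vanishes on the boundary away from xi
  # (second-order one-sided difference at r = 1)
  for (th in c(0, -2, 2.5)) {
    u <- c(cos(th), sin(th))
    gp <- (-3 * laplace_surface_green(u, xi) +
             4 * laplace_surface_green((1 + h) * u, xi) -
             laplace_surface_green((1 + 2 * h) * u, xi)) / (2 * h)
    expect_lt(abs(gp), 1e-5)
  }
  # unit flux: integral of the radial derivative over a circle r = 3 is -1
  th <- seq(-pi, pi, length.out = 2001)[-1]
  gp <- (laplace_surface_green(cbind((3 + h) * cos(th), (3 + h) * sin(th)), xi) -
         laplace_surface_green(cbind((3 - h) * cos(th), (3 - h) * sin(th)), xi)) /
    (2 * h)
  expect_equal(sum(gp) * (2 * pi / 2000) * 3, -1, tolerance = 1e-6)
  # regular part finite: G + log|x-xi|/pi approaches R_s = 0
  d <- 10^(-(3:6))
  vals <- vapply(d, function(dd) {
    x <- (1 + dd) * xi
    laplace_surface_green(x, xi) + log(dd) / pi
  }, numeric(1))
  expect_lt(abs(vals[4]), 1e-3)
  expect_error(laplace_surface_green(c(0, 1), xi), "singular")
  expect_error(laplace_surface_green(c(0.5, 0), xi), "outside")
})

test_that("gauge freedom of the surface Green's function is exposed and documented", {
  expect_equal(laplace_regular_part(c(1, 0)), 0)
  expect_equal(laplace_regular_part(c(0, 1), gauge = 2.5), 2.5)
  expect_equal(laplace_surface_green(c(2, 0), c(0, 1), gauge = 3) -
                 laplace_surface_green(c(2, 0), c(0, 1)), 3)
})

test_that("Helmholtz surface Green's function matches the finite-difference PDE oracle", {
  s <- 1; D <- 1
  mmax <- 600
  g <- vapply(0:mmax, function(m) {
    fd_helmholtz_mode(m, s, D, gp1 = -(2 - (m == 0)) / (2 * pi * D))
  }, numeric(1))
  m <- seq_len(mmax)
  for (dth in c(pi, pi / 2)) {
    rh_fd <- g[1] + sum((g[-1] - 1 / (pi * D * m)) * cos(m * dth))
    expect_equal(Re(helmholtz_regular_part(dth, 0, s, D)), rh_fd,
                 tolerance = 1e-4)
    expect_lt(abs(Im(helmholtz_regular_part(dth, 0, s, D))), 1e-12)
  }
  # full G_h = log part + regular part at delta-theta = pi
  expect_equal(Re(helmholtz_surface_green(pi, 0, s, D)),
               g[1] + sum((g[-1] - 1 / (pi * D * m)) * cos(m * pi)) -
                 log(2 * abs(sin(pi / 2))) / (pi * D),
               tolerance = 1e-4)
})

test_that("Helmholtz surface Green's function is symmetric and self-consistently truncated", {
  s <- 2 + 3i
  expect_equal(helmholtz_surface_green(0.7, -0.4, s, 1),
               helmholtz_surface_green(-0.4, 0.7, s, 1), tolerance = 1e-12)
  # doubling the truncation cap changes nothing beyond tolerance
  a <- helmholtz_regular_part(1.1, 0, s, 1, tol = 1e-12, mmax = 1e5)
  b <- helmholtz_regular_part(1.1, 0, s, 1, tol = 1e-13, mmax = 2e5)
  expect_equal(a, b, tolerance = 1e-10)
  expect_error(helmholtz_surface_green(0.5, 0.5, s, 1), "singular")
})

test_that("Helmholtz bulk Green's function matches the PDE oracle and decays in R", {
  s <- 1; D <- 1
  gb <- vapply(0:60, function(m) {
    fd_helmholtz_mode(m, s, D, R_src = 2, w = (2 - (m == 0)) / (2 * pi),
                      drho_max = 2e-4)
  }, numeric(1))
  expect_lt(abs(Re(helmholtz_bulk_green(0, 2, 0, s, D)) - sum(gb)), 1e-4)
  # rotation invariance: depends only on theta - theta0
  expect_equal(helmholtz_bulk_green(0.3, 2, 0.3, s, D),
               helmholtz_bulk_green(1.5, 2, 1.5, s, D), tolerance = 1e-12)
  # vanishes as the source recedes
  vals <- Mod(vapply(c(2, 5, 10, 20), function(R) {
    helmholtz_bulk_green(0, R, 0, s, D)
  }, complex(1)))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[4], 1e-8)
  expect_error(helmholtz_bulk_green(0, 0.8, 0, s, D), "R > 1")
})
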