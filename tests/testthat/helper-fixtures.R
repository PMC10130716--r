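# shared fixtures and small numerical helpers for the suite

fixture_three <- function(eps = 0.1) three_receptor_config(eps)
fixture_source <- function() source_spec(R = 2, theta0 = 0, D = 1)

# Finite-difference solve of one angular Fourier mode of the exterior
# modified Helmholtz problem on a logarithmic radial grid (rho = log r, where
# the mode equation becomes g'' - (m^2 + (s/D) e^{2 rho}) g = rhs, uniformly
# resolvable in m).  A prescribed derivative g'(1) = gp1 models a surface
# point flux (ghost point, second order); a ring source of weight w at
# R_src models a bulk point source; decay is imposed at the far edge.
# Completely independent of the Bessel-function route: the brute-force PDE
# oracle.  Returns g(1).
fd_helmholtz_mode <- function(m, s, D = 1, gp1 = 0, R_src = NA, w = 0,
                              drho_max = 5e-4) {
  a2 <- s / D
  rho_max <- min(log(30), max(1.0, 45 / max(m, 1)))
  drho <- min(drho_max, 0.05 / max(m, 1))
  n <- ceiling(rho_max / drho)
  rho <- seq(0, by = drho, length.out = n)
  coef <- m^2 + a2 * exp(2 * rho)
  main <- c(-2 / drho^2 - coef[1],
            rep(-2 / drho^2, n - 2) - coef[2:(n - 1)], 1)
  lower <- c(rep(1 / drho^2, n - 2), 0)
  upper <- c(2 / drho^2, rep(1 / drho^2, n - 2))
  rhs <- numeric(n)
  rhs[1] <- 2 * gp1 / drho
  if (!is.na(R_src)) {
    i <- which.min(abs(rho - log(R_src)))
    rhs[i] <- rhs[i] - (w / D) / drho
  }
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(lower, main, upper))
  as.numeric(Matrix::solve(A, rhs))[1]
}

# trapezoid rule on a possibly non-uniform grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
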