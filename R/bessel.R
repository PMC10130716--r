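# Modified Bessel functions K0, K1 of complex argument, exponentially scaled.
#
# All Laplace-domain quantities in this package reduce to ratios of modified
# Bessel functions K_m evaluated at alpha = sqrt(s/D) on a Talbot contour, so
# the argument is complex with Re(z) > 0.  Higher orders are never computed
# directly: they follow from the stable forward recurrence on the ratios
# K_{m+1}/K_m (see src/series.cpp), which needs only K0 and K1 here.
#
# Three evaluation regimes:
#   |z| >= 12                asymptotic expansion (error below ~1e-12),
#   |z| + Re(z) <= 14        ascending power series (cancellation bounded by
#                            exp(|z| + Re z) * eps <= ~3e-10),
#   otherwise                Gauss-Legendre quadrature of the integral
#                            representation K_nu(z) = int_0^inf
#                            exp(-z cosh t) cosh(nu t) dt, transformed with
#                            u = sinh t so the oscillation is near-linear.
# In the remaining quadrature region Re(z) > 2, which keeps both the
# integrand decay and the oscillation count well resolved.

.EULER_GAMMA <- 0.57721566490153286061

.bk01_asym <- function(z) {
  pref <- sqrt(pi / (2 * z))
  out <- c(0 + 0i, 0 + 0i)
  for (i in 1:2) {
    mu <- 4 * (i - 1)^2
    term <- 1 + 0i
    acc <- term
    prev <- Inf
    for (k in 1:40) {
      term <- term * (mu - (2 * k - 1)^2) / (8 * k * z)
      if (Mod(term) > prev) break
      acc <- acc + term
      prev <- Mod(term)
      if (Mod(term) < 1e-17 * Mod(acc)) break
    }
    out[i] <- pref * acc
  }
  out
}

.bk01_series <- function(z) {
  z2 <- z * z / 4
  lg <- log(z / 2)
  ti <- 1 + 0i                       # (z^2/4)^k / (k!)^2
  I0 <- ti
  K0s <- 0 + 0i
  tk1 <- 1 + 0i                      # (z^2/4)^k / (k! (k+1)!)
  I1s <- tk1
  K1s <- (-2 * .EULER_GAMMA + 1) * tk1   # psi(1) + psi(2)
  H <- 0
  for (k in 1:60) {
    ti <- ti * z2 / (k * k)
    H <- H + 1 / k
    I0 <- I0 + ti
    K0s <- K0s + ti * H
    tk1 <- tk1 * z2 / (k * (k + 1))
    I1s <- I1s + tk1
    K1s <- K1s + tk1 * (-2 * .EULER_GAMMA + 2 * H + 1 / (k + 1))
    if (k > 4 && Mod(ti) < 1e-18 * (Mod(K0s) + 1e-300)) break
  }
  K0 <- -(lg + .EULER_GAMMA) * I0 + K0s
  I1 <- (z / 2) * I1s
  K1 <- 1 / z + lg * I1 - (z / 4) * K1s
  c(K0, K1) * exp(z)
}

.gl_env <- new.env(parent = emptyenv())

.gl12 <- function() {
  if (is.null(.gl_env$g12)) {
    .gl_env$g12 <- pracma::gaussLegendre(12, 0, 1)
  }
  .gl_env$g12
}

.bk01_quad <- function(z) {
  x <- Re(z)
  y <- abs(Im(z))
  U <- sqrt((1 + 40 / x)^2 - 1)
  npan <- min(3000, max(8, ceiling(U * y / (2 * pi) * 4), ceiling(U * x / 8)))
  g <- .gl12()
  edges <- seq(0, U, length.out = npan + 1)
  w <- diff(edges)
  u <- as.vector(outer(g$x, w) + rep(edges[-length(edges)], each = 12))
  wq <- as.vector(outer(g$w, w))
  sq <- sqrt(1 + u * u)
  e <- exp(-z * sq + z)              # scaled integrand
  c(sum(wq * e / sq), sum(wq * e))
}

#' Scaled modified Bessel functions K0, K1 for complex argument
#'
#' Evaluates \eqn{e^z K_0(z)} and \eqn{e^z K_1(z)} for complex \code{z} with
#' \code{Re(z) > 0} (or purely imaginary \code{z}).  These seed the stable
#' ratio recurrences used by all Laplace-domain Green's function series.
#'
#' @param z complex vector, \code{Re(z) >= 0}, \code{z != 0}.
#' @return a complex matrix with columns \code{K0} and \code{K1} (scaled by
#'   \eqn{e^z}).
#' @export
besselk01 <- function(z) {
  z <- as.complex(z)
  if (any(!is.finite(z)) || any(Re(z) < 0) || any(z == 0)) {
    stop("besselk01 requires finite z with Re(z) >= 0, z != 0")
  }
  out <- matrix(0 + 0i, nrow = length(z), ncol = 2,
                dimnames = list(NULL, c("K0", "K1")))
  for (i in seq_along(z)) {
    zi <- z[i]
    az <- Mod(zi)
    out[i, ] <- if (az >= 12) {
      .bk01_asym(zi)
    } else if (az + Re(zi) <= 14) {
      .bk01_series(zi)
    } else {
      .bk01_quad(zi)
    }
  }
  out
}
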