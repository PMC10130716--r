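# Green's functions with reflecting (Neumann) boundary on the exterior of the
# unit disc: the Laplace surface Green's function used by the static splitting
# solver, and the modified-Helmholtz (Laplace-transform-domain) surface and
# bulk Green's functions used by the dynamic flux solver.

#' Laplace surface Green's function on the disc exterior
#'
#' Green's function for the Laplacian outside the unit disc with a unit point
#' flux injected at the boundary point \code{xi} and reflecting boundary
#' elsewhere:
#' \deqn{G_s(x;\xi) = -\frac{1}{\pi}\log|x-\xi| + \frac{1}{2\pi}\log|x| + C,}
#' taken in the gauge \code{C = 0}.  The Green's function is defined only up
#' to an additive constant; the static splitting solver is invariant under
#' that constant because its strengths satisfy \eqn{\sum_j \nu_j A_{jk} = 0}.
#'
#' @param x evaluation point(s): length-2 vector or 2-column matrix, outside
#'   the open unit disc.
#' @param xi boundary point (length-2 vector with \code{|xi| = 1}).
#' @param gauge additive constant \code{C} (default 0).
#' @return numeric vector of values.
#' @export
laplace_surface_green <- function(x, xi, gauge = 0) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  if (abs(sqrt(sum(xi^2)) - 1) > 1e-10) stop("xi must lie on the unit circle")
  r2 <- x[, 1]^2 + x[, 2]^2
  if (any(r2 < 1 - 1e-12)) stop("evaluation points must lie outside the unit disc")
  d2 <- (x[, 1] - xi[1])^2 + (x[, 2] - xi[2])^2
  if (any(d2 == 0)) stop("singular evaluation: x coincides with xi")
  -log(d2) / (2 * pi) + log(r2) / (4 * pi) + gauge
}

#' Regular part of the Laplace surface Green's function
#'
#' The finite remainder \eqn{R_s(\xi) = \lim_{x\to\xi}[G_s + \log|x-\xi|/\pi]}.
#' On the unit circle this equals the gauge constant.
#'
#' @param xi boundary point (unused beyond validation; the disc is rotation
#'   invariant).
#' @param gauge additive constant \code{C} (default 0).
#' @return the regular part.
#' @export
laplace_regular_part <- function(xi = c(1, 0), gauge = 0) {
  if (abs(sqrt(sum(xi^2)) - 1) > 1e-10) stop("xi must lie on the unit circle")
  gauge
}

.alpha_of <- function(s, D) {
  a <- sqrt(as.complex(s) / D)       # principal branch: Re(alpha) >= 0
  if (any(Re(a) < 0)) a[Re(a) < 0] <- -a[Re(a) < 0]
  a
}

# shared series evaluation: regular part of the Helmholtz surface Green's
# function at angular separations dtheta
.rh_values <- function(dtheta, s, D, tol = 1e-12, mmax = 2e6) {
  alpha <- .alpha_of(s, D)
  k <- besselk01(alpha)
  out <- rh_series_sum(alpha, k[1, 1], k[1, 2], as.numeric(dtheta),
                       as.integer(mmax), tol)
  if (out$m_used >= mmax) {
    warning("Helmholtz surface series truncated at mmax = ", mmax,
            " before reaching tol = ", tol)
  }
  (-out$c0 / 2 - out$sums) / (pi * D)
}

#' Regular part of the Helmholtz surface Green's function
#'
#' Evaluates \eqn{R_h} in
#' \eqn{G_h(x;\xi,s) = -\log|x-\xi|/(\pi D) + R_h}
#' for boundary points at angular separation \code{theta - thetap}, via the
#' Fourier--Bessel series in \eqn{K_m(\alpha)}, \eqn{K_m'(\alpha)} with
#' \eqn{\alpha = \sqrt{s/D}}.  The series is truncated adaptively: terms decay
#' like \eqn{|\alpha|^2/(2m^3)}.
#'
#' @param theta,thetap boundary angles (radians); \code{theta} may be a vector.
#' @param s complex Laplace variable, off the negative real axis.
#' @param D diffusivity.
#' @param tol series tail tolerance.
#' @param mmax truncation cap.
#' @return complex vector of \eqn{R_h} values.
#' @export
helmholtz_regular_part <- function(theta, thetap = 0, s, D = 1,
                                   tol = 1e-12, mmax = 2e6) {
  .rh_values(theta - thetap, s, D, tol, mmax)
}

#' Helmholtz surface Green's function on the disc exterior
#'
#' Green's function of \eqn{D\Delta G - sG = 0} outside the unit disc with a
#' unit point flux at the boundary angle \code{thetap}, evaluated at boundary
#' angle(s) \code{theta}.  Symmetric in its two angles.
#'
#' @inheritParams helmholtz_regular_part
#' @return complex vector of values.
#' @export
helmholtz_surface_green <- function(theta, thetap, s, D = 1,
                                    tol = 1e-12, mmax = 2e6) {
  dth <- theta - thetap
  chord <- 2 * abs(sin(dth / 2))
  if (any(chord == 0)) stop("singular evaluation: theta coincides with thetap")
  -log(chord) / (pi * D) + .rh_values(dth, s, D, tol, mmax)
}

#' Helmholtz bulk-to-surface Green's function on the disc exterior
#'
#' Green's function of the modified Helmholtz operator with a unit source at
#' the bulk point \eqn{(R, \theta_0)} (polar), evaluated at boundary angle(s)
#' \code{theta}:
#' \deqn{G_h = -\frac{K_0(\alpha R)}{2\pi D\,\alpha K_0'(\alpha)}
#'   - \frac{1}{\pi D}\sum_{m\ge1}\frac{K_m(\alpha R)}{\alpha K_m'(\alpha)}
#'   \cos m(\theta-\theta_0).}
#' Terms decay geometrically like \eqn{R^{-m}}.
#'
#' @param theta boundary angle(s), radians.
#' @param R source radius, \code{> 1}.
#' @param theta0 source angle, radians.
#' @inheritParams helmholtz_regular_part
#' @return complex vector of values.
#' @export
helmholtz_bulk_green <- function(theta, R, theta0 = 0, s, D = 1,
                                 tol = 1e-12, mmax = 1e5) {
  if (R <= 1) stop("bulk source must lie outside the cell: R > 1")
  alpha <- .alpha_of(s, D)
  ka <- besselk01(alpha)
  kaR <- besselk01(alpha * R)
  p0 <- exp(-alpha * (R - 1)) * kaR[1, 1] / ka[1, 1]
  out <- bulk_series_sum(alpha, R, ka[1, 1], ka[1, 2], kaR[1, 1], kaR[1, 2],
                         p0, as.numeric(theta - theta0), as.integer(mmax), tol)
  -(out$T0 / 2 + out$sums) / (pi * D)
}
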