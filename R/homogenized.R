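# Homogenized Robin-boundary model: many small equally spaced receptors are
# replaced by a uniform partially absorbing (Robin) condition
# D dp/dn = kappa p on the unit circle.  All fluxes follow from the mode
# functions chi_m(alpha) = K_m(alpha R) / (K_m(alpha) - D kappa^-1 alpha
# K_m'(alpha)), inverted on the Talbot contour.

#' Effective Robin permeability of a patchy receptor covering
#'
#' For \code{N} equally spaced receptors of common angular extent \code{eps}
#' on the unit circle, the homogenization limit replaces the mixed boundary
#' condition with a uniform Robin condition of permeability
#' \deqn{\kappa = -\frac{N D}{2 \log(\varepsilon N / 4)}.}
#' Valid while the receptors occupy less than the whole boundary in the
#' capacitance sense, \eqn{\varepsilon N < 4}.
#'
#' @param N number of receptors.
#' @param eps per-receptor angular extent (radians).
#' @param D diffusivity.
#' @return the permeability \eqn{\kappa > 0} (length/time).
#' @export
homogenized_permeability <- function(N, eps, D = 1) {
  if (eps <= 0 || eps * N >= 4) {
    stop("homogenization regime requires 0 < eps*N < 4")
  }
  -N * D / (2 * log(eps * N / 4))
}

#' Homogenized Robin-surface model
#'
#' @param kappa boundary permeability (length/time), \code{> 0};
#'   \code{Inf} gives the perfectly absorbing circle.
#' @param R source distance, \code{> 1}.
#' @param D diffusivity.
#' @param theta0 source angle.
#' @param n_nodes Talbot nodes for inversions.
#' @param mode_tol relative tolerance used when truncating the angular mode
#'   series.
#' @return an object of class \code{homogenized_model}.
#' @export
homogenized_model <- function(kappa, R, D = 1, theta0 = 0, n_nodes = 64,
                              mode_tol = 1e-10) {
  if (!(kappa > 0)) stop("kappa must be positive")
  if (R <= 1) stop("source must lie outside the cell: R > 1")
  if (D <= 0) stop("D must be positive")
  structure(list(kappa = kappa, R = R, D = D, theta0 = theta0,
                 Dk_inv = if (is.infinite(kappa)) 0 else D / kappa,
                 n_nodes = n_nodes, mode_tol = mode_tol),
            class = "homogenized_model")
}

#' @export
print.homogenized_model <- function(x, ...) {
  cat(sprintf("homogenized_model: kappa = %g, R = %g, D = %g\n",
              x$kappa, x$R, x$D))
  invisible(x)
}

.chi_modes <- function(alpha, model, mmodes) {
  ka <- besselk01(alpha)
  kaR <- besselk01(alpha * model$R)
  p0 <- exp(-alpha * (model$R - 1)) * kaR[1, 1] / ka[1, 1]
  chi_mode_vector(alpha, model$R, ka[1, 1], ka[1, 2], kaR[1, 1], kaR[1, 2],
                  p0, model$Dk_inv, as.integer(mmodes))
}

#' Robin-surface flux modes
#'
#' The Laplace-domain angular modes of the surface flux,
#' \deqn{\chi_m(\alpha) = \frac{K_m(\alpha R)}{K_m(\alpha) -
#'   D\kappa^{-1}\alpha K_m'(\alpha)},}
#' evaluated with scaled Bessel ratios so large \eqn{|\alpha R|} neither
#' overflows nor underflows.  \eqn{\chi_0(\alpha)} is the transform of the
#' total absorption rate; \eqn{\chi_0(\alpha)/s} that of the capture
#' fraction.
#'
#' @param m mode order(s), non-negative integers.
#' @param alpha complex scaled Laplace parameter \eqn{\sqrt{s/D}},
#'   \code{Re(alpha) > 0}.
#' @param model a \code{\link{homogenized_model}}.
#' @return complex vector \eqn{\chi_m(\alpha)}, one entry per \code{m}.
#' @export
robin_flux_mode <- function(m, alpha, model) {
  stopifnot(all(m >= 0), all(m == round(m)))
  v <- .chi_modes(as.complex(alpha), model, max(m))
  v[m + 1]
}

# number of angular modes needed so chi_M/chi_0 < tol at the widest contour
.modes_needed <- function(model, t, cap = 4096) {
  ct <- talbot_contour(t, model$n_nodes)
  alpha <- .alpha_of(ct$s[which.max(Mod(ct$s))], model$D)
  mm <- 32
  repeat {
    v <- .chi_modes(alpha, model, mm)
    ref <- Mod(v[1]) + 1e-300
    idx <- which(Mod(v) / ref < model$mode_tol)
    if (length(idx) > 0) return(min(idx) - 1)
    if (mm >= cap) return(cap)
    mm <- min(cap, mm * 4)
  }
}

#' Capture fraction and survival of the homogenized model
#'
#' \code{homog_capture_cdf} inverts \eqn{\chi_0(\alpha)/s} on the Talbot
#' contour, giving the probability that the particle has been absorbed by
#' time \code{t}; \code{homog_survival} is its complement.
#'
#' @param t positive time(s).
#' @param model a \code{\link{homogenized_model}}.
#' @return numeric vector over \code{t}.
#' @export
homog_capture_cdf <- function(t, model) {
  vapply(t, function(tt) {
    talbot_invert(function(s) {
      a <- .alpha_of(s, model$D)
      vapply(seq_along(s), function(j) .chi_modes(a[j], model, 0)[1],
             complex(1)) / s
    }, tt, n_nodes = model$n_nodes)
  }, numeric(1))
}

#' @rdname homog_capture_cdf
#' @export
homog_survival <- function(t, model) 1 - homog_capture_cdf(t, model)

#' Angular flux density of the homogenized model
#'
#' Inverts the mode series
#' \deqn{\hat J(\theta,s) = \frac{\chi_0(\alpha)}{2\pi} +
#'   \frac{1}{\pi}\sum_{m\ge1}\chi_m(\alpha)\cos m(\theta-\theta_0)}
#' term by term on the Talbot contour.  The truncation order is chosen so
#' the dropped modes are below \code{mode_tol} relative to \eqn{\chi_0} at
#' the widest contour node.
#'
#' @param theta boundary angle(s).
#' @param t a single positive time.
#' @param model a \code{\link{homogenized_model}}.
#' @return numeric vector \eqn{J(\theta, t)} over \code{theta}.
#' @export
homogenized_flux_density <- function(theta, t, model) {
  stopifnot(length(t) == 1, t > 0)
  mm <- .modes_needed(model, t)
  ct <- talbot_contour(t, model$n_nodes)
  acc <- numeric(length(theta))
  cosmat <- cos(outer(theta - model$theta0, seq_len(mm), function(a, m) m * a))
  for (j in seq_along(ct$s)) {
    a <- .alpha_of(ct$s[j], model$D)
    chi <- .chi_modes(a, model, mm)
    w <- exp(ct$s[j] * t) * ct$ds[j]
    series <- chi[1] / 2 + if (mm > 0) drop(cosmat %*% chi[-1]) else 0
    acc <- acc + Im(w * series)
  }
  acc * (2 / model$n_nodes) / pi
}

#' Directional-information mode ratio
#'
#' The ratio \eqn{L^{-1}[\chi_1](t) / L^{-1}[\chi_0](t)} of the first two
#' angular flux modes.  Its magnitude measures how much directional
#' information about the source is still carried by the arriving flux; it
#' decays to zero as the surviving density becomes radially symmetric.
#'
#' @param t positive time(s).
#' @param model a \code{\link{homogenized_model}}.
#' @return numeric vector of ratios (\code{NA} where the denominator is
#'   below 1e-14).
#' @export
mode_ratio <- function(t, model) {
  vapply(t, function(tt) {
    v <- talbot_invert(function(s) {
      a <- .alpha_of(s, model$D)
      t(vapply(seq_along(s), function(j) .chi_modes(a[j], model, 1),
               complex(2)))
    }, tt, n_nodes = model$n_nodes)
    if (abs(v[1]) < 1e-14) NA_real_ else v[2] / v[1]
  }, numeric(1))
}

#' Short-time moments and Gaussian flux approximation
#'
#' In the short-time regime (diffusion length below the cell radius but
#' above the receptor scale) the arriving flux is concentrated near the
#' boundary point closest to the source and is asymptotically Gaussian in
#' angle:
#' \deqn{J(\theta,t) \sim \frac{M_0(t)}{\sqrt{2\pi\sigma^2}}
#'   e^{-(\theta-\theta_0)^2/2\sigma^2},\qquad \sigma^2 = 2Dt/R,}
#' with total flux
#' \deqn{M_0(t) = \frac{\kappa(R-1)}{\sqrt{\pi R D t}}\,
#'   \frac{e^{-(R-1)^2/4Dt}}{2\kappa t + (R-1)},}
#' a form that is uniform in the relative size of \eqn{\kappa t} and
#' \eqn{R-1}.  The kurtosis is 3 + O(Dt): the distribution is Gaussian to
#' leading order.
#'
#' @param t positive time(s); a warning is issued outside \code{Dt < 0.1}.
#' @param model a \code{\link{homogenized_model}} (finite \code{kappa}).
#' @return \code{short_time_moments}: a list with \code{M0},
#'   \code{variance}, \code{kurtosis}.
#' @export
short_time_moments <- function(t, model) {
  if (any(model$D * t > 0.1)) {
    warning("short-time asymptotics requested outside the regime D*t << 1")
  }
  k <- model$kappa
  R <- model$R
  D <- model$D
  M0 <- k * (R - 1) / sqrt(pi * R * D * t) * exp(-(R - 1)^2 / (4 * D * t)) /
    (2 * k * t + (R - 1))
  list(M0 = M0, variance = 2 * D * t / R, kurtosis = rep(3, length(t)))
}

#' @rdname short_time_moments
#' @param theta boundary angle(s) for the Gaussian density.
#' @return \code{gaussian_flux_approx}: \eqn{J(\theta,t)} under the Gaussian
#'   approximation (vector over \code{theta}; \code{t} scalar).
#' @export
gaussian_flux_approx <- function(theta, t, model) {
  stopifnot(length(t) == 1)
  m <- short_time_moments(t, model)
  m$M0 / sqrt(2 * pi * m$variance) *
    exp(-(theta - model$theta0)^2 / (2 * m$variance))
}

#' Discrete Fourier flux coefficients of a receptor configuration
#'
#' For a discrete receptor configuration the Laplace-domain surface flux is a
#' sum of point masses; its Fourier coefficients are
#' \deqn{\bar\chi_q(\alpha) - i\bar\psi_q(\alpha) = \pi D \sum_j \nu_j A_j(s)
#'   e^{-iq(\theta_j-\theta_0)}.}
#' As the number of equally spaced receptors grows at fixed total
#' capacitance, \eqn{\bar\chi_q \to \chi_q} of the homogenized model and the
#' sine parts \eqn{\bar\psi_q \to 0}: this is the diagnostic by which the
#' discrete-to-Robin convergence is measured.
#'
#' @param config receptor configuration.
#' @param source a \code{\link{source_spec}}.
#' @param s complex Laplace variable.
#' @param q mode order.
#' @param tol series tolerance.
#' @return list with complex \code{chi_bar} and \code{psi_bar}.
#' @export
discrete_fourier_flux <- function(config, source, s, q, tol = 1e-12) {
  A <- solve_strengths(s, config, source, tol = tol)
  ph <- q * (config$angles - source$theta0)
  base <- pi * source$D * config$nu * A
  list(chi_bar = sum(base * cos(ph)), psi_bar = sum(base * sin(ph)))
}
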