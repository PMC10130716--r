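# Reference solver for the static mixed boundary-value problem, independent
# of the matched-asymptotic machinery: the splitting probability is
# represented as a constant plus single-layer potentials of the Neumann
# surface Green's function supported on the receptor arcs,
#
#   phi(x) = phi_bar + sum_j int_{arc_j} sigma_j(xi) G_s(x; xi) ds,
#
# which is exterior-harmonic and satisfies the reflecting condition off the
# arcs exactly.  The flux density sigma_j has inverse-square-root endpoint
# singularities, so it is expanded as sigma_j(u) = sum_n c_jn T_n(u) /
# sqrt(1 - u^2) in the scaled arc coordinate u in [-1, 1].  Only the
# Dirichlet condition on the arcs is collocated (overdetermined, solved in
# least squares); the self-arc logarithmic kernel integrates in closed form
# through the identity
#   int_-1^1 T_n(u) log|v-u| / sqrt(1-u^2) du = -pi log 2        (n = 0)
#                                             = -pi T_n(v) / n   (n >= 1),
# and all regular kernels use Gauss-Chebyshev quadrature, giving spectral
# accuracy in the basis order.

# V_{jn}(x(v)) on the same arc j: closed form + smooth remainder
.self_block <- function(ej, n_basis, v, uq, wq) {
  # returns matrix |v| x n_basis of basis-function boundary values on arc j
  Tn_v <- cos(outer(acos(v), 0:(n_basis - 1)))
  # singular part: -(1/pi) * (e/2) * closed-form Chebyshev-log integrals
  sing <- matrix(0, length(v), n_basis)
  sing[, 1] <- -pi * log(2)
  for (n in seq_len(n_basis - 1)) sing[, n + 1] <- -pi * Tn_v[, n + 1] / n
  # smooth remainder S(u, v) = log( |2 sin(d/2)| / |d| ), d = (e/2)(v - u),
  # plus the constant log(e/2); S -> 0 as d -> 0
  dd <- (ej / 2) * outer(v, uq, "-")
  Sm <- ifelse(abs(dd) < 1e-12, 0, log(abs(2 * sin(dd / 2)) / abs(dd)))
  Tn_u <- cos(outer(acos(uq), 0:(n_basis - 1)))
  smooth <- (Sm %*% (wq * Tn_u))
  smooth[, 1] <- smooth[, 1] + pi * log(ej / 2)
  -(ej / 2) / pi * (sing + smooth)
}

# V_{jn} evaluated at boundary angles th (radians) away from arc j
.cross_block <- function(aj, ej, n_basis, th, uq, wq) {
  thu <- aj + (ej / 2) * uq
  chord <- 2 * abs(sin(outer(th, thu, "-") / 2))
  K <- -log(chord) / pi
  Tn_u <- cos(outer(acos(uq), 0:(n_basis - 1)))
  (ej / 2) * (K %*% (wq * Tn_u))
}

#' Spectral reference solution of the static splitting problem
#'
#' Solves the exterior mixed boundary-value problem for the splitting
#' probabilities by least-squares collocation of a singularity-adapted
#' harmonic expansion: single-layer potentials of the reflecting-boundary
#' Green's function with Chebyshev-weighted densities on each receptor arc
#' (capturing the inverse-square-root flux singularities at arc endpoints
#' exactly), plus a free constant.  The reflecting condition holds by
#' construction; the absorbing conditions \eqn{\phi_k = \delta_{jk}} are
#' imposed at Chebyshev collocation points on the arcs, clustered towards
#' the endpoints, and solved in least squares with a shared QR factorization
#' for all \code{N} targets.  Boundedness at infinity is enforced through
#' the zero-total-charge constraint on the densities.
#'
#' @param config receptor configuration.
#' @param n_basis Chebyshev basis order per arc (convergence is spectral).
#' @param n_quad Gauss--Chebyshev quadrature nodes per arc.
#' @param oversample collocation points per basis function on each arc.
#' @param resid_tol root-mean-square residual above which an accuracy
#'   warning is raised.
#' @return a list of class \code{spectral_solution}: \code{coef} (density
#'   coefficients, one column per target), \code{phi_bar} (far-field
#'   values), \code{residual_rms}, and the configuration.
#' @export
spectral_splitting <- function(config, n_basis = 32, n_quad = 96,
                               oversample = 2, resid_tol = 1e-8) {
  stopifnot(n_basis >= 4, n_quad >= 2 * n_basis)
  N <- config$N
  a <- config$angles
  e <- config$extents
  uq <- cos((2 * seq_len(n_quad) - 1) * pi / (2 * n_quad))
  wq <- rep(pi / n_quad, n_quad)
  n_col <- ceiling(oversample * n_basis)
  v <- cos((2 * seq_len(n_col) - 1) * pi / (2 * n_col))
  p <- N * n_basis + 1
  rows <- N * n_col + 1
  Amat <- matrix(0, rows, p)
  for (i in seq_len(N)) {
    ri <- (i - 1) * n_col + seq_len(n_col)
    th_i <- a[i] + (e[i] / 2) * v
    for (j in seq_len(N)) {
      cj <- (j - 1) * n_basis + seq_len(n_basis)
      Amat[ri, cj] <- if (i == j) {
        .self_block(e[j], n_basis, v, uq, wq)
      } else {
        .cross_block(a[j], e[j], n_basis, th_i, uq, wq)
      }
    }
    Amat[ri, p] <- 1                        # the constant phi_bar
  }
  # boundedness at infinity: total charge sum_j int sigma_j = 0, i.e. the
  # n = 0 coefficients (each integrating to pi * e_j / 2) must cancel
  Amat[rows, (seq_len(N) - 1) * n_basis + 1] <- pi * e / 2
  rhs <- matrix(0, rows, N)
  for (k in seq_len(N)) rhs[(k - 1) * n_col + seq_len(n_col), k] <- 1
  qrA <- qr(Amat, LAPACK = TRUE)
  coef <- qr.coef(qrA, rhs)
  coef[is.na(coef)] <- 0
  res <- Amat[-rows, , drop = FALSE] %*% coef - rhs[-rows, , drop = FALSE]
  resid <- sqrt(mean(res^2))
  if (resid > resid_tol) {
    warning(sprintf("spectral fit residual %.2e above tolerance; %s",
                    resid, "increase n_basis"))
  }
  structure(list(coef = coef[seq_len(p - 1), , drop = FALSE],
                 phi_bar = coef[p, ],
                 n_basis = n_basis, n_quad = n_quad,
                 residual_rms = resid, config = config),
            class = "spectral_solution")
}

#' Evaluate a spectral splitting solution at exterior points
#'
#' @param solution a \code{\link{spectral_splitting}} result.
#' @param x exterior point(s): length-2 vector or 2-column matrix.
#' @return an \code{N}-vector (or \code{P x N} matrix) of splitting
#'   probabilities.
#' @export
spectral_phi <- function(solution, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  r2 <- x[, 1]^2 + x[, 2]^2
  if (any(r2 < 1 - 1e-12)) stop("x must lie outside the unit disc")
  cfg <- solution$config
  nb <- solution$n_basis
  nq <- solution$n_quad
  uq <- cos((2 * seq_len(nq) - 1) * pi / (2 * nq))
  wq <- rep(pi / nq, nq)
  Tn_u <- cos(outer(acos(uq), 0:(nb - 1)))
  P <- nrow(x)
  B <- matrix(0, P, nrow(solution$coef))
  for (j in seq_len(cfg$N)) {
    thu <- cfg$angles[j] + (cfg$extents[j] / 2) * uq
    xi1 <- cos(thu); xi2 <- sin(thu)
    d2 <- outer(x[, 1], xi1, "-")^2 + outer(x[, 2], xi2, "-")^2
    G <- -log(d2) / (2 * pi) + log(r2) / (4 * pi)
    B[, (j - 1) * nb + seq_len(nb)] <-
      (cfg$extents[j] / 2) * (G %*% (wq * Tn_u))
  }
  out <- B %*% solution$coef +
    matrix(solution$phi_bar, P, cfg$N, byrow = TRUE)
  if (nrow(out) == 1) drop(out) else out
}
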