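# Static splitting probabilities by the sums-of-logs asymptotic solution:
# each receptor is replaced by a point absorber of logarithmic capacitance
# nu_k and the interaction between absorbers is resolved exactly through the
# surface Green's function, giving accuracy beyond any truncated expansion in
# 1/|log eps|.

#' Solve the sums-of-logs linear system for static splitting
#'
#' For each target receptor \code{k}, solves the \eqn{(N+1)\times(N+1)} system
#' \deqn{\begin{bmatrix} I + \pi\,\mathcal{G}_s V & -e \\ \nu^T & 0
#'   \end{bmatrix}\begin{bmatrix}A_k\\ \bar\phi_k\end{bmatrix}
#'   = -\begin{bmatrix}e_k\\ 0\end{bmatrix}}
#' where \eqn{[\mathcal{G}_s]_{ij}} is the surface Green's function between
#' receptor centres (regular part on the diagonal) and \eqn{V =
#' \mathrm{diag}(\nu)}.  The matrix is target-independent, so one LU
#' factorization serves all \code{N} right-hand sides.
#'
#' @param config a \code{\link{build_config}} receptor configuration.
#' @param gauge additive constant of the surface Green's function; the
#'   returned probabilities are invariant to it (checked).
#' @return a list of class \code{static_solution}: \code{A} (the
#'   \eqn{N\times N} strength matrix, column \code{k} for target \code{k}),
#'   \code{phi_bar} (far-field splitting probabilities, summing to 1), and
#'   the configuration.
#' @export
solve_static <- function(config, gauge = 0) {
  N <- config$N
  nu <- config$nu
  xs <- cbind(cos(config$angles), sin(config$angles))
  Gs <- matrix(gauge, N, N)          # regular part R_s = gauge on the diagonal
  if (N > 1) {
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        d <- sqrt(sum((xs[i, ] - xs[j, ])^2))
        Gs[i, j] <- Gs[j, i] <- -log(d) / pi + gauge
      }
    }
  }
  M <- rbind(cbind(diag(N) + pi * Gs %*% diag(nu, N), -rep(1, N)),
             c(nu, 0))
  rhs <- rbind(-diag(N), rep(0, N))
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    stop("singular sums-of-logs system (receptor configuration is degenerate): ",
         conditionMessage(e))
  })
  kappa_cond <- rcond(M)
  if (kappa_cond < 1e-12) {
    warning(sprintf("sums-of-logs system poorly conditioned (rcond = %.2e)",
                    kappa_cond))
  }
  A <- sol[seq_len(N), , drop = FALSE]
  phi_bar <- sol[N + 1, ]
  structure(list(A = A, phi_bar = phi_bar, config = config, gauge = gauge),
            class = "static_solution")
}

#' Static splitting probabilities at an exterior point
#'
#' Evaluates \deqn{\phi^*_k(x) = -\pi\sum_j A_{jk}\nu_j G_s(x;x_j) +
#' \bar\phi_k} for every receptor \code{k}.  The result is a probability
#' vector: each component lies in \eqn{(0,1)} and they sum to 1.
#'
#' @param x exterior point(s): length-2 vector or 2-column matrix with
#'   \code{|x| > 1}, not inside any receptor arc.
#' @param solution a \code{\link{solve_static}} result.
#' @param config the receptor configuration (defaults to the one stored in
#'   \code{solution}).
#' @return an \code{N}-vector (or \code{P x N} matrix) of probabilities.
#' @export
splitting_probability <- function(x, solution, config = solution$config) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  r <- sqrt(x[, 1]^2 + x[, 2]^2)
  if (any(r <= 1 + 1e-12)) {
    th <- atan2(x[, 2], x[, 1])
    on_arc <- vapply(th, function(t) .arc_index(t, config) > 0, logical(1))
    if (any(on_arc & abs(r - 1) < 1e-9)) {
      stop("indeterminate point: x lies on a receptor arc")
    }
    if (any(r < 1 - 1e-12)) stop("x must lie outside the unit disc")
  }
  N <- config$N
  G <- vapply(seq_len(N), function(j) {
    laplace_surface_green(x, c(cos(config$angles[j]), sin(config$angles[j])),
                          gauge = solution$gauge)
  }, numeric(nrow(x)))
  if (nrow(x) == 1) G <- matrix(G, nrow = 1)
  phi <- -pi * G %*% (solution$A * config$nu) +
    matrix(solution$phi_bar, nrow(x), N, byrow = TRUE)
  if (nrow(phi) == 1) drop(phi) else phi
}

#' Leading-order splitting probabilities
#'
#' In the limit of vanishing receptor size every receptor is equally likely
#' to capture the particle regardless of the source position, so the
#' splitting probabilities degenerate to \code{1/N}.  Finite receptor size is
#' what makes two-dimensional source inference possible.
#'
#' @param N number of receptors.
#' @return the constant vector \code{rep(1/N, N)}.
#' @export
leading_order_splitting <- function(N) {
  stopifnot(N >= 1)
  rep(1 / N, N)
}
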