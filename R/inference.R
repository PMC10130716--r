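# Source-localization estimators built on the static and dynamic signal
# models: likelihood landscapes over candidate source positions,
# triangulation from splitting probabilities, batched polar averaging of
# receptor input, and extreme-value (Gumbel) first-arrival statistics.

#' Polar evaluation grid for likelihood landscapes
#'
#' Radii are log-spaced: landscapes are elongated in the radial direction
#' (direction is identified early, distance only once a large signal
#' fraction has arrived), so logarithmic radial gridding spends points where
#' the landscape varies.
#'
#' @param r_range radial range (both ends \code{> 1}).
#' @param n_r,n_theta grid resolution.
#' @return a list with \code{r}, \code{theta} and the full polar grid
#'   (\code{R}, \code{TH} matrices).
#' @export
landscape_grid <- function(r_range = c(1.05, 40), n_r = 64, n_theta = 256) {
  stopifnot(r_range[1] > 1, r_range[2] > r_range[1])
  r <- exp(seq(log(r_range[1]), log(r_range[2]), length.out = n_r))
  theta <- seq(-pi, pi, length.out = n_theta + 1)[-1]
  list(r = r, theta = theta,
       R = matrix(r, n_r, n_theta), TH = matrix(theta, n_r, n_theta,
                                                byrow = TRUE))
}

#' Signal-model providers for landscape evaluation
#'
#' A provider maps candidate source positions to the probability vector
#' \eqn{q_k} the receptors would report if the source were there:
#' \code{q_provider_static} uses the splitting probabilities (the
#' \eqn{t = \infty} signal); \code{q_provider_dynamic} uses the cumulative
#' fractional fluxes \eqn{q_k(x;t)} at finite \code{t}.  Both return a
#' function \code{f(r, theta)} taking equal-length polar coordinate vectors
#' and returning a \code{length(r) x N} matrix.
#'
#' The dynamic provider factors the receptor-interaction matrix once per
#' Talbot node (it does not depend on the candidate source), so scanning a
#' grid of candidate positions costs one bulk-Green's evaluation and one
#' back-substitution per node and point.
#'
#' @param config receptor configuration.
#' @param t observation time (dynamic provider).
#' @param D diffusivity assumed for the candidate sources.
#' @param n_nodes Talbot nodes.
#' @param tol series tolerance.
#' @return a provider function.
#' @export
q_provider_static <- function(config) {
  sol <- solve_static(config)
  function(r, theta) {
    x <- cbind(r * cos(theta), r * sin(theta))
    p <- splitting_probability(x, sol)
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    p
  }
}

#' @rdname q_provider_static
#' @export
q_provider_dynamic <- function(config, t, D = 1, n_nodes = 64, tol = 1e-10) {
  N <- config$N
  ct <- talbot_contour(t, n_nodes)
  pre <- lapply(seq_along(ct$s), function(j) {
    s <- ct$s[j]
    Gh <- .gh_matrix(config, s, D, tol)
    Minv <- solve(diag(N) + pi * D * Gh %*% diag(config$nu, N))
    alpha <- .alpha_of(s, D)
    list(s = s, w = exp(s * t) * ct$ds[j], Minv = Minv, alpha = alpha,
         k = besselk01(alpha))
  })
  function(r, theta) {
    P <- length(r)
    acc <- matrix(0, P, N)
    for (nd in pre) {
      g0 <- matrix(0 + 0i, N, P)
      for (p in seq_len(P)) {
        R <- r[p]
        kaR <- besselk01(nd$alpha * R)
        p0 <- exp(-nd$alpha * (R - 1)) * kaR[1, 1] / nd$k[1, 1]
        bs <- bulk_series_sum(nd$alpha, R, nd$k[1, 1], nd$k[1, 2],
                              kaR[1, 1], kaR[1, 2], p0,
                              config$angles - theta[p], as.integer(1e5), tol)
        g0[, p] <- -(bs$T0 / 2 + bs$sums) / (pi * D)
      }
      A <- nd$Minv %*% g0
      Jhat <- pi * D * config$nu * A
      acc <- acc + t(Im((Jhat / nd$s) * nd$w))
    }
    cum <- acc * (2 / n_nodes)
    cum[cum < 0] <- 0
    tot <- rowSums(cum)
    q <- matrix(1 / N, P, N)
    ok <- tot > 1e-14
    q[ok, ] <- cum[ok, , drop = FALSE] / tot[ok]
    q
  }
}

.landscape_eval <- function(weights, q_provider, grid) {
  P <- length(grid$R)
  q <- q_provider(as.vector(grid$R), as.vector(grid$TH))
  lq <- suppressWarnings(log(q))    # q <= 0 handled by exclusion below
  bad <- !is.finite(lq) & rep(weights > 0, each = P)
  L <- -as.vector(lq %*% weights)
  L[rowSums(matrix(bad, nrow = P)) > 0] <- Inf
  matrix(L, nrow = length(grid$r))
}

.refine_minimum <- function(L, grid, objective) {
  idx <- arrayInd(which.min(L), dim(L))
  r0 <- grid$r[idx[1]]
  th0 <- grid$theta[idx[2]]
  opt <- stats::optim(c(log(r0 - 1), th0),
                      function(p) objective(1 + exp(p[1]), p[2]),
                      method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  r_hat <- 1 + exp(opt$par[1])
  th_hat <- .wrap_angle(opt$par[2])
  list(x_hat = c(r_hat * cos(th_hat), r_hat * sin(th_hat)),
       r_hat = r_hat, theta_hat = th_hat, value = opt$value)
}

#' Maximum-likelihood source landscape
#'
#' The negative multinomial log-likelihood of the observed receptor counts
#' under the signal model,
#' \deqn{L(x;t) = -\sum_k c_k \log q_k(x;t),}
#' evaluated over a polar grid of candidate source positions and minimized
#' (grid search plus derivative-free local refinement).  Grid points where
#' some \eqn{q_k = 0} while \eqn{c_k > 0} are excluded (set to \code{Inf})
#' and flagged.
#'
#' @param counts a \code{\link{count_table}}.
#' @param q_provider from \code{\link{q_provider_static}} or
#'   \code{\link{q_provider_dynamic}}.
#' @param grid a \code{\link{landscape_grid}}.
#' @return a list of class \code{landscape}: \code{L} (matrix over the
#'   grid), \code{grid}, \code{x_hat}, \code{r_hat}, \code{theta_hat}.
#' @export
mle_landscape <- function(counts, q_provider, grid = landscape_grid()) {
  w <- counts$counts
  if (sum(w) <= 0) stop("counts must contain at least one arrival")
  L <- .landscape_eval(w, q_provider, grid)
  obj <- function(r, th) {
    q <- q_provider(r, th)
    v <- -sum(w * log(pmax(q, 1e-300)))
    if (!is.finite(v)) 1e300 else v
  }
  ref <- .refine_minimum(L, grid, obj)
  structure(c(list(L = L, grid = grid, excluded = any(!is.finite(L))), ref),
            class = "landscape")
}

#' Exact (noise-free) source landscape
#'
#' The cross-entropy landscape
#' \deqn{L^*(x;x_0,t) = -\sum_k q_k(x_0;t)\log q_k(x;t),}
#' in which the finite counts are replaced by the exact relative signal from
#' the true source \eqn{x_0}.  By Gibbs' inequality its minimum is at
#' \eqn{x = x_0}; the sublevel contours within (0.125, 0.25, 0.5, 1.0)
#' percent of the minimum summarize how sharply the data identify the
#' source.
#'
#' @param source the true source (\code{\link{source_spec}}).
#' @param q_provider signal-model provider.
#' @param grid a \code{\link{landscape_grid}}.
#' @param levels contour levels as fractions above the minimum.
#' @return a list of class \code{landscape} with \code{L}, \code{grid},
#'   \code{x_hat}, and \code{contour_levels} (absolute \code{L*} values).
#' @export
exact_landscape <- function(source, q_provider,
                            grid = landscape_grid(),
                            levels = c(0.00125, 0.0025, 0.005, 0.01)) {
  q0 <- drop(q_provider(source$R, source$theta0))
  L <- .landscape_eval(q0, q_provider, grid)
  obj <- function(r, th) {
    q <- q_provider(r, th)
    v <- -sum(q0 * log(pmax(q, 1e-300)))
    if (!is.finite(v)) 1e300 else v
  }
  ref <- .refine_minimum(L, grid, obj)
  lv <- ref$value * (1 + levels)
  structure(c(list(L = L, grid = grid, contour_levels = lv,
                   level_fractions = levels), ref),
            class = "landscape")
}

#' Triangulate the source from long-time counts
#'
#' Uses the overdetermined system that equates observed splitting fractions
#' \eqn{c_k/M} to the asymptotic splitting probabilities
#' \eqn{\phi^*_k(x_0)}: the residual
#' \deqn{r_k(x_0) = \bar\phi_k - c_k/M - \pi\sum_j A_{jk}\nu_j G_s(x_0;x_j)}
#' is minimized in least squares over a polar parameter search.  At least
#' three receptors are required for identifiability on the circle.
#'
#' @param counts a \code{\link{count_table}} of eventual (\code{t = Inf})
#'   counts.
#' @param config receptor configuration.
#' @param solution optional precomputed \code{\link{solve_static}} result.
#' @param grid polar search grid.
#' @return list with \code{x_hat}, \code{r_hat}, \code{theta_hat},
#'   \code{residual}.
#' @export
triangulate_source <- function(counts, config, solution = NULL,
                               grid = landscape_grid()) {
  if (config$N < 3) {
    stop("source triangulation requires at least N = 3 receptors")
  }
  if (is.null(solution)) solution <- solve_static(config)
  target <- counts$counts / counts$M
  X <- cbind(as.vector(grid$R) * cos(as.vector(grid$TH)),
             as.vector(grid$R) * sin(as.vector(grid$TH)))
  phi <- splitting_probability(X, solution, config)
  res2 <- rowSums(sweep(phi, 2, target)^2)
  Lr <- matrix(res2, nrow = length(grid$r))
  resid2 <- function(r, th) {
    x <- c(r * cos(th), r * sin(th))
    sum((splitting_probability(x, solution, config) - target)^2)
  }
  ref <- .refine_minimum(Lr, grid, resid2)
  list(x_hat = ref$x_hat, r_hat = ref$r_hat, theta_hat = ref$theta_hat,
       residual = sqrt(ref$value))
}

#' Batched polar average of receptor arrivals
#'
#' Sorts arrivals by time and, for each consecutive batch of \code{M_s}
#' arrivals, reports the count-weighted circular mean of the receptor
#' angles: the direction \eqn{\theta_{pa}} a cell could form by simply
#' averaging which receptors fired.  The circular mean (via summed unit
#' vectors) is used rather than the arithmetic mean of angles, which is
#' ill-defined across the \eqn{\pm\pi} cut; for sources near angle 0 the two
#' coincide.
#'
#' @param table an arrival table (\code{\link{simulate_arrivals}}).
#' @param M_s batch size.
#' @param config optional receptor configuration; by default the recorded
#'   arrival angles are averaged, with a configuration the receptor centre
#'   angles are used (as a cell reading only receptor identities would).
#' @return data.frame with one row per batch: \code{t_mid} (median arrival
#'   time in the batch), \code{theta_pa}, \code{n} and a \code{partial} flag
#'   on a final incomplete batch.
#' @export
polar_average <- function(table, M_s, config = NULL) {
  stopifnot(M_s >= 1)
  tab <- table[!table$censored & !is.na(table$receptor_id), ]
  tab <- tab[order(tab$time), ]
  ang <- if (is.null(config)) tab$angle else config$angles[tab$receptor_id]
  n <- nrow(tab)
  if (n == 0) stop("no uncensored arrivals to average")
  batch <- (seq_len(n) - 1) %/% M_s
  out <- do.call(rbind, lapply(split(seq_len(n), batch), function(ix) {
    data.frame(t_mid = stats::median(tab$time[ix]),
               theta_pa = atan2(mean(sin(ang[ix])), mean(cos(ang[ix]))),
               n = length(ix))
  }))
  out$partial <- out$n < M_s
  rownames(out) <- NULL
  out
}

#' Kolmogorov-Smirnov uniformity p-value for angles
#'
#' One-sample KS test of angular samples against the uniform distribution on
#' \eqn{(-\pi, \pi]}, with the asymptotic p-value.  Used to date the time at
#' which the polar average loses directional information.
#'
#' @param samples angles (radians; wrapped automatically).
#' @return the p-value.
#' @export
ks_uniformity_pvalue <- function(samples) {
  samples <- .wrap_angle(samples)
  if (length(samples) < 5) stop("need at least 5 samples")
  suppressWarnings(
    stats::ks.test(samples, stats::punif, -pi, pi)$p.value
  )
}

# --- extreme-value first-arrival statistics --------------------------------

#' Gumbel parameters of the fastest of M arrivals
#'
#' If the single-particle arrival-time distribution has the short-time form
#' \eqn{1 - P(t) \sim A t^q e^{-B/t}} as \eqn{t \to 0^+}, then the minimum of
#' \code{M} independent arrival times converges (after centring and scaling)
#' to a Gumbel law with
#' \deqn{b_M = \frac{B}{q W_M},\qquad a_M = \frac{b_M}{q(1 + W_M)},\qquad
#'   W_M = W_*\!\left[\tfrac{B}{q}(AM)^{1/q}\right],}
#' where \eqn{W_*} is the principal Lambert-W branch.
#'
#' @param A,B,q short-time constants (\code{A != 0}, \code{B > 0}).
#' @param M number of independent particles, \code{>= 2}.
#' @return an object of class \code{gumbel_params} with \code{a_M},
#'   \code{b_M}, \code{W_M}, \code{A}, \code{B}, \code{q}, \code{M}.
#' @export
gumbel_arrival_params <- function(A, B, q, M) {
  stopifnot(M >= 2, B > 0, A != 0)
  z <- (B / q) * (A * M)^(1 / q)
  if (!is.finite(z) || z <= 0) stop("invalid Lambert-W argument; check A, B, q, M")
  W <- pracma::lambertWp(z)
  b <- B / (q * W)
  a <- b / (q * (1 + W))
  structure(list(a_M = a, b_M = b, W_M = W, A = A, B = B, q = q, M = M),
            class = "gumbel_params")
}

#' @export
print.gumbel_params <- function(x, ...) {
  cat(sprintf("gumbel_params: q = %g, a_M = %.4g, b_M = %.4g (W_M = %.4g)\n",
              x$q, x$a_M, x$b_M, x$W_M))
  invisible(x)
}

#' Extreme-arrival parameters for the homogenized Robin cell
#'
#' The Robin surface gives the short-time law with exponent \eqn{q = 3/2}
#' and constants
#' \deqn{A = \frac{4\kappa}{(R-1)^2}\sqrt{\frac{D}{\pi R}},\qquad
#'   B = \frac{(R-1)^2}{4D},}
#' obtained by integrating the short-time total flux \eqn{M_0(t)}.
#'
#' @param M number of particles.
#' @param R source distance.
#' @param kappa Robin permeability.
#' @param D diffusivity.
#' @return a \code{\link{gumbel_arrival_params}} object (with \code{R},
#'   \code{D}, \code{kappa} attached).
#' @export
extreme_params <- function(M, R, kappa, D = 1) {
  stopifnot(R > 1, kappa > 0, D > 0)
  A <- 4 * kappa * sqrt(D / (pi * R)) / (R - 1)^2
  B <- (R - 1)^2 / (4 * D)
  p <- gumbel_arrival_params(A, B, q = 3 / 2, M = M)
  p$R <- R; p$D <- D; p$kappa <- kappa
  p
}

#' Extreme-arrival parameters for a perfectly absorbing cell
#'
#' The all-absorbing circle has first-passage tail
#' \eqn{1 - P(t) = \mathrm{erfc}((R-1)/\sqrt{4Dt})/\sqrt{R} \sim
#' A t^{1/2} e^{-B/t}} with \eqn{q = 1/2},
#' \eqn{A = 2\sqrt{D/\pi}/((R-1)\sqrt{R})} and the same
#' \eqn{B = (R-1)^2/4D}.
#'
#' @inheritParams extreme_params
#' @return a \code{\link{gumbel_arrival_params}} object.
#' @export
absorbing_extreme_params <- function(M, R, D = 1) {
  stopifnot(R > 1, D > 0)
  A <- 2 * sqrt(D / pi) / ((R - 1) * sqrt(R))
  B <- (R - 1)^2 / (4 * D)
  p <- gumbel_arrival_params(A, B, q = 1 / 2, M = M)
  p$R <- R; p$D <- D; p$kappa <- Inf
  p
}

#' Mean and variance of the extreme arrival time
#'
#' For the Gumbel minimum law, \eqn{E[t_a] = b_M - \gamma_e a_M} (with
#' \eqn{\gamma_e} the Euler--Mascheroni constant) and
#' \eqn{\mathrm{Var}[t_a] = \pi^2 a_M^2/6}.  \code{mean_large_M} is the
#' equivalent closed form \eqn{b_M(1 - 2\gamma_e/(3(1+W_M)))} written in
#' terms of \eqn{W_M} (exponent 3/2 case).
#'
#' @param params a \code{\link{gumbel_arrival_params}} object.
#' @return list with \code{mean}, \code{variance}, \code{mean_large_M}.
#' @export
extreme_mean <- function(params) {
  g <- .EULER_GAMMA
  list(mean = params$b_M - g * params$a_M,
       variance = pi^2 * params$a_M^2 / 6,
       mean_large_M = params$b_M * (1 - g / (params$q * (1 + params$W_M))))
}

#' Variance of the first-arrival angle
#'
#' Conditioned on arriving at the Gumbel mode time \eqn{b_M}, the arrival
#' angle is normally distributed about the source direction with variance
#' \eqn{2 D b_M / R}.  For the Robin cell (\eqn{q = 3/2}) this equals
#' \eqn{g(R)/W_M} with \eqn{g(R) = (R-1)^2/(3R)}: the variance shrinks only
#' logarithmically in the particle number, so even a single first arrival
#' carries usable directional information when the source is not too
#' distant.
#'
#' @param params a \code{\link{gumbel_arrival_params}} from
#'   \code{\link{extreme_params}} or
#'   \code{\link{absorbing_extreme_params}} (needs \code{R}, \code{D}).
#' @return the angular variance \eqn{\sigma^2_{\theta_a}}.
#' @export
extreme_angle_variance <- function(params) {
  if (is.null(params$R)) stop("params must carry the source distance R")
  2 * params$D * params$b_M / params$R
}
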