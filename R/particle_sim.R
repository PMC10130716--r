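# R interface to the Monte Carlo simulators (src/sim.cpp).  All functions
# take an explicit seed and use R's RNG, so identical seeds give bit-identical
# output.

#' Time-free splitting-probability simulation
#'
#' Samples, for each of \code{M} independent particles started at the source,
#' the receptor at which it is eventually absorbed.  The boundary hitting
#' angle from any exterior point follows the exact harmonic measure of the
#' unit circle (the Poisson kernel, a wrapped Cauchy distribution with
#' concentration \code{1/r}), so no time stepping is involved: a particle
#' that lands on the reflecting portion of the boundary is re-injected at
#' radius \code{1 + delta} at the landing angle and redrawn.  Counts converge
#' to the splitting probabilities as \code{delta} decreases; the default was
#' fixed by a convergence study against the static solver.
#'
#' @param M number of particles.
#' @param config receptor configuration.
#' @param source a \code{\link{source_spec}} (only the geometry is used:
#'   splitting probabilities are diffusivity-free).
#' @param seed RNG seed.
#' @param delta re-injection offset after a reflecting hit.
#' @param max_hops per-particle hop cap; particles exceeding it are reported
#'   as censored, never silently dropped.
#' @return a list with \code{counts} (per-receptor), \code{table} (a
#'   data.frame of uncensored arrivals: \code{angle}, \code{receptor_id}),
#'   \code{censored}, \code{mean_hops}, \code{M}, \code{seed}.
#' @export
simulate_splitting <- function(M, config, source, seed = 1, delta = 1e-3,
                               max_hops = 1e6) {
  set.seed(seed)
  out <- sim_splitting(as.integer(M), config$angles, config$extents / 2,
                       source$R, source$theta0, delta, as.integer(max_hops))
  keep <- !is.na(out$receptor_id)
  list(counts = out$counts,
       table = data.frame(angle = out$angle[keep],
                          receptor_id = out$receptor_id[keep]),
       censored = out$censored, mean_hops = out$mean_hops, M = M, seed = seed)
}

#' Time-resolved arrival simulation
#'
#' Adaptive Euler--Maruyama propagation of Brownian particles outside the
#' reflecting unit disc with absorbing receptor arcs.  The step size keeps
#' three standard deviations of the increment inside the distance to the
#' boundary (\eqn{\sqrt{2Dh} \le d/3}) with a floor \code{h_min} at the
#' wall; boundary crossings are located exactly on the straight step segment,
#' and crossings outside a receptor are reflected specularly about the local
#' tangent.  Particles not absorbed by \code{t_max} are returned censored.
#'
#' @param M number of particles.
#' @param config receptor configuration.
#' @param source a \code{\link{source_spec}}.
#' @param t_max censoring horizon.
#' @param seed RNG seed.
#' @param h_min step-size floor near the boundary (time units).
#' @param step_frac step standard deviation as a fraction of the distance to
#'   the boundary (the default 1/6 was fixed by a convergence study against
#'   the deterministic capture fractions).
#' @return an arrival table of class \code{arrival_table}: a data.frame with
#'   columns \code{time}, \code{angle}, \code{receptor_id}, \code{censored};
#'   attributes \code{M}, \code{seed}, \code{t_max}.
#' @export
simulate_arrivals <- function(M, config, source, t_max, seed = 1,
                              h_min = 1e-6, step_frac = 1 / 6) {
  stopifnot(t_max > 0)
  set.seed(seed)
  out <- sim_arrivals(as.integer(M), config$angles, config$extents / 2,
                      source$R, source$theta0, source$D, t_max, h_min,
                      step_frac)
  df <- data.frame(time = out$time, angle = out$angle,
                   receptor_id = out$receptor_id, censored = out$censored)
  attr(df, "M") <- M
  attr(df, "seed") <- seed
  attr(df, "t_max") <- t_max
  class(df) <- c("arrival_table", "data.frame")
  df
}

#' First-arrival statistics for an all-absorbing cell
#'
#' Repeats \code{n_rep} times: release \code{M} particles at distance
#' \code{R} from a perfectly absorbing unit circle and record the time and
#' angle of the first arrival.  Used to validate the extreme-value (Gumbel)
#' asymptotics; the running minimum caps the propagation horizon of the
#' remaining particles, so the cost is dominated by early arrivals.
#'
#' @param M particles per replicate.
#' @param R source distance.
#' @param D diffusivity.
#' @param n_rep number of replicates.
#' @param t_max horizon; replicates with no arrival are returned as
#'   \code{NA}.
#' @param seed RNG seed.
#' @param h_min step-size floor.
#' @param step_frac step standard deviation relative to boundary distance.
#' @return data.frame with columns \code{t_first}, \code{theta_first}.
#' @export
simulate_first_arrival <- function(M, R, D = 1, n_rep = 1, t_max = Inf,
                                   seed = 1, h_min = 1e-6, step_frac = 1 / 6) {
  if (is.infinite(t_max)) t_max <- 1e6
  set.seed(seed)
  out <- sim_first_arrival(as.integer(n_rep), as.integer(M), R, D, t_max,
                           h_min, step_frac)
  data.frame(t_first = out$t_first, theta_first = out$theta_first)
}

#' Receptor counts at an observation time
#'
#' Counts uncensored arrivals with \code{time <= t} per receptor.  Tables
#' from \code{\link{simulate_splitting}} are time-free: any \code{t} returns
#' the full (eventual) counts.
#'
#' @param table an arrival table (from \code{\link{simulate_arrivals}}) or a
#'   \code{\link{simulate_splitting}} result.
#' @param t observation time (may be \code{Inf}).
#' @param N number of receptors (inferred from the table if absent).
#' @return a \code{\link{count_table}}.
#' @export
empirical_counts <- function(table, t = Inf, N = NULL) {
  if (is.list(table) && !is.data.frame(table) && !is.null(table$counts)) {
    # splitting-mode result: time-free
    return(count_table(table$counts, t = Inf, M = table$M))
  }
  if (is.null(N)) N <- max(table$receptor_id, na.rm = TRUE)
  keep <- !table$censored & !is.na(table$receptor_id) & table$time <= t
  counts <- tabulate(table$receptor_id[keep], nbins = N)
  count_table(counts, t = t, M = attr(table, "M"))
}
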