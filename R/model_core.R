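#' Logarithmic capacitance of a small absorbing arc
#'
#' A receptor occupying an arc of arclength \code{extent} on the unit circle
#' acts, in the small-receptor limit, as a point absorber of strength
#' \deqn{\nu = -1/\log(\mathrm{extent}/4).}
#' The strength grows monotonically with the arc length and equals 1 exactly
#' when the extent is \eqn{4/e}.
#'
#' @param extent arclength(s) of the absorbing arc, in \code{(0, 4)} (the cell
#'   radius is fixed at 1, so arclengths are dimensionless).
#' @return the capacitance \eqn{\nu > 0}, vectorized over \code{extent}.
#' @export
receptor_capacitance <- function(extent) {
  if (any(!is.finite(extent)) || any(extent <= 0) || any(extent >= 4)) {
    stop("invalid receptor geometry: arc extent must lie in (0, 4)")
  }
  -1 / log(extent / 4)
}

.wrap_angle <- function(theta) {
  # map to (-pi, pi]
  w <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  w[w <= -pi] <- pi
  w
}

#' Receptor configuration on the unit circle
#'
#' Builds a validated set of \code{N} non-overlapping absorbing arcs.
#' Receptor \code{k} occupies the closed arc of half-width \code{extents[k]/2}
#' about \code{angles[k]}; a boundary point falling on a shared endpoint is
#' assigned to the lower-index receptor.
#'
#' @param angles arc centres, radians (any values; normalized to \code{(-pi, pi]}).
#' @param extents arclengths of the arcs, each in \code{(0, 4)}, summing to
#'   less than \code{2*pi}.
#' @return an object of class \code{receptor_config} with fields \code{N},
#'   \code{angles}, \code{extents}, \code{nu} and \code{cell_radius = 1}.
#' @export
build_config <- function(angles, extents) {
  if (length(angles) != length(extents) || length(angles) < 1) {
    stop("angles and extents must be non-empty vectors of equal length")
  }
  angles <- .wrap_angle(as.numeric(angles))
  extents <- as.numeric(extents)
  nu <- receptor_capacitance(extents)
  if (sum(extents) >= 2 * pi) {
    stop("invalid receptor geometry: arcs cover the whole circle")
  }
  # overlap check on the circle: sort by centre, compare neighbouring arcs
  o <- order(angles)
  a <- angles[o]; e <- extents[o]
  n <- length(a)
  if (n > 1) {
    gap <- c(diff(a), a[1] + 2 * pi - a[n])
    need <- (e + c(e[-1], e[1])) / 2
    if (any(gap < need)) stop("invalid receptor geometry: overlapping arcs")
  }
  structure(
    list(N = n, angles = angles, extents = extents, nu = nu, cell_radius = 1),
    class = "receptor_config"
  )
}

#' @export
print.receptor_config <- function(x, ...) {
  cat(sprintf("receptor_config: N = %d arcs on the unit circle\n", x$N))
  cat(sprintf("  total coverage %.1f%% of the boundary\n",
              100 * sum(x$extents) / (2 * pi)))
  invisible(x)
}

#' Three-receptor benchmark configuration
#'
#' The asymmetric three-receptor layout used throughout the package's
#' validation examples: centres at angles \code{pi/4, pi, 3*pi/2} with
#' arclengths \code{eps * c(pi/3, pi/3, 2*pi/3)}.
#'
#' @param eps receptor size parameter (default 0.1).
#' @return a \code{receptor_config}.
#' @export
three_receptor_config <- function(eps = 0.1) {
  build_config(angles = c(pi / 4, pi, 3 * pi / 2),
               extents = eps * c(pi / 3, pi / 3, 2 * pi / 3))
}

#' Uniformly spaced receptor configuration
#'
#' \code{N} equally spaced receptors at angles \code{2*pi*k/N} with common
#' arclength \code{eps * lc}.
#'
#' @param N number of receptors.
#' @param eps receptor size parameter.
#' @param lc common arc-length multiplier (default 1).
#' @return a \code{receptor_config}.
#' @export
uniform_config <- function(N, eps, lc = 1) {
  build_config(angles = 2 * pi * seq_len(N) / N, extents = rep(eps * lc, N))
}

#' Diffusive source specification
#'
#' @param R radial distance of the source from the cell centre (must exceed
#'   the cell radius 1).
#' @param theta0 polar angle of the source, radians.
#' @param D diffusivity of the signalling molecule (length^2/time, with the
#'   cell radius as the length unit).
#' @return a list with fields \code{R}, \code{theta0}, \code{D} and the
#'   Cartesian position \code{x0}.
#' @export
source_spec <- function(R, theta0 = 0, D = 1) {
  if (!is.finite(R) || R <= 1) stop("source must lie outside the cell: R > 1")
  if (!is.finite(D) || D <= 0) stop("diffusivity D must be positive")
  theta0 <- .wrap_angle(theta0)
  list(R = R, theta0 = theta0, D = D,
       x0 = c(R * cos(theta0), R * sin(theta0)))
}

#' Receptor count table
#'
#' Per-receptor arrival counts at an observation time.
#'
#' @param counts non-negative integer vector, one entry per receptor.
#' @param t observation time (use \code{Inf} for the fully absorbed record).
#' @param M total number of particles released; defaults to \code{sum(counts)}.
#' @return a list with fields \code{counts}, \code{t}, \code{M}.
#' @export
count_table <- function(counts, t = Inf, M = sum(counts)) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) > M) stop("sum of counts exceeds the number of particles M")
  list(counts = counts, t = t, M = M)
}

.arc_index <- function(theta, config) {
  # receptor containing boundary angle theta (closed arcs, ties to lower
  # index), or 0 if on the reflecting portion
  th <- .wrap_angle(theta)
  for (k in seq_len(config$N)) {
    d <- abs(.wrap_angle(th - config$angles[k]))
    if (d <= config$extents[k] / 2 + 1e-15) return(k)
  }
  0L
}

# --- structured config file (YAML) -----------------------------------------

#' Read a run configuration file
#'
#' The file is YAML with blocks \code{receptors} (\code{angles},
#' \code{extents}), \code{source} (\code{R}, \code{theta0}, \code{D}) and
#' optional \code{solver} / \code{simulate} / \code{inference} blocks carrying
#' numerical settings. Unknown top-level keys are rejected.
#'
#' @param path file path.
#' @return a list with \code{config} (a \code{receptor_config}),
#'   \code{source} (or \code{NULL}) and the remaining setting blocks.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("receptors", "source", "solver", "simulate", "inference")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  if (is.null(raw$receptors)) stop("configuration must contain a 'receptors' block")
  cfg <- build_config(raw$receptors$angles, raw$receptors$extents)
  src <- NULL
  if (!is.null(raw$source)) {
    src <- source_spec(raw$source$R,
                       if (is.null(raw$source$theta0)) 0 else raw$source$theta0,
                       if (is.null(raw$source$D)) 1 else raw$source$D)
  }
  list(config = cfg, source = src,
       solver = raw$solver, simulate = raw$simulate, inference = raw$inference)
}

#' Write a run configuration file
#'
#' @param config a \code{receptor_config}.
#' @param source optional source specification from \code{\link{source_spec}}.
#' @param path output file path.
#' @param solver,simulate,inference optional setting blocks echoed verbatim.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path, source = NULL, solver = NULL,
                             simulate = NULL, inference = NULL) {
  out <- list(receptors = list(angles = config$angles, extents = config$extents))
  if (!is.null(source)) {
    out$source <- list(R = source$R, theta0 = source$theta0, D = source$D)
  }
  if (!is.null(solver)) out$solver <- solver
  if (!is.null(simulate)) out$simulate <- simulate
  if (!is.null(inference)) out$inference <- inference
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Read a receptor count table from delimited text
#'
#' Expects a header \code{receptor_id,count}.
#'
#' @param path file path.
#' @param t observation time attached to the table (default \code{Inf}).
#' @param M total particles released (default \code{sum(count)}).
#' @return a \code{\link{count_table}}.
#' @export
read_count_table <- function(path, t = Inf, M = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("receptor_id", "count") %in% names(df))) {
    stop("count table must have columns 'receptor_id' and 'count'")
  }
  df <- df[order(df$receptor_id), ]
  count_table(df$count, t = t, M = if (is.null(M)) sum(df$count) else M)
}

#' Write a receptor count table as delimited text
#'
#' @param counts a \code{\link{count_table}} or plain count vector.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_count_table <- function(counts, path) {
  if (is.list(counts)) counts <- counts$counts
  utils::write.csv(
    data.frame(receptor_id = seq_along(counts), count = counts),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
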