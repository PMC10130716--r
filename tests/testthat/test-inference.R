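# Source-localization estimators.

test_that("exact landscape obeys Gibbs' inequality with its minimum at the source", {
  cfg <- fixture_three(0.1)
  qp <- q_provider_static(cfg)
  src <- fixture_source()
  grid <- landscape_grid(n_r = 24, n_theta = 64)
  ls <- exact_landscape(src, qp, grid)
  q0 <- drop(qp(src$R, src$theta0))
  self_entropy <- -sum(q0 * log(q0))
  expect_true(all(ls$L >= self_entropy - 1e-10))
  expect_gte(ls$value, self_entropy - 1e-8)
  # refined minimizer lands on the source
  expect_lt(abs(ls$r_hat - 2), 0.05)
  expect_lt(abs(ls$theta_hat - 0), 0.05)
  # sublevel contours exist at the documented fractions
  expect_equal(ls$contour_levels, ls$value * (1 + c(0.00125, 0.0025, 0.005, 0.01)))
})

test_that("noise-free counts recover the source exactly", {
  cfg <- fixture_three(0.1)
  qp <- q_provider_static(cfg)
  q0 <- drop(qp(2, 0))
  counts <- count_table(round(1e6 * q0), M = 1e6)
  ls <- mle_landscape(counts, qp, landscape_grid(n_r = 24, n_theta = 64))
  expect_lt(sqrt(sum((ls$x_hat - c(2, 0))^2)), 0.05)
})

test_that("uniform counts on a symmetric cell give a rotationally symmetric landscape", {
  cfg <- uniform_config(6, 0.2)
  qp <- q_provider_static(cfg)
  counts <- count_table(rep(100, 6))
  grid <- landscape_grid(r_range = c(1.3, 40), n_r = 10, n_theta = 48)
  ls <- mle_landscape(counts, qp, grid)
  expect_true(all(is.finite(ls$L)))
  # exact invariance under rotation by the receptor spacing 2*pi/6
  # (48 angular grid points = 8 columns per spacing)
  shifted <- ls$L[, c(9:48, 1:8)]
  expect_equal(shifted, ls$L, tolerance = 1e-10)
  # in the far field the receptor discreteness washes out entirely
  spread <- diff(range(ls$L[10, ])) / abs(mean(ls$L[10, ]))
  expect_lt(spread, 1e-6)
})

test_that("long-time estimates cluster around the true source over repeated draws", {
  cfg <- fixture_three(0.1)
  src <- fixture_source()
  qp <- q_provider_static(cfg)
  grid <- landscape_grid(r_range = c(1.05, 30), n_r = 32, n_theta = 96)
  xh <- t(vapply(1:20, function(i) {
    sm <- simulate_splitting(1e4, cfg, src, seed = 100 + i)
    ls <- mle_landscape(count_table(sm$counts), qp, grid)
    ls$x_hat
  }, numeric(2)))
  ang <- atan2(xh[, 2], xh[, 1])
  rr <- sqrt(rowSums(xh^2))
  expect_lt(abs(median(ang)), 0.3)
  expect_true(median(rr) > 1.2 && median(rr) < 4)
  # the cloud surrounds the source direction
  expect_gt(mean(abs(ang) < 0.8), 0.7)
})

test_that("estimator scatter shrinks as the particle number grows", {
  cfg <- fixture_three(0.1)
  src <- fixture_source()
  qp <- q_provider_static(cfg)
  grid <- landscape_grid(r_range = c(1.05, 30), n_r = 32, n_theta = 96)
  med_err <- vapply(c(1e3, 1e5), function(M) {
    errs <- vapply(1:8, function(i) {
      sm <- simulate_splitting(M, cfg, src, seed = 300 + i)
      ls <- mle_landscape(count_table(sm$counts), qp, grid)
      sqrt(sum((ls$x_hat - c(2, 0))^2))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(med_err[2], med_err[1])
})

test_that("triangulation recovers the source from exact splitting fractions", {
  cfg <- fixture_three(0.1)
  sol <- solve_static(cfg)
  phi0 <- splitting_probability(c(2, 0), sol)
  counts <- count_table(round(1e7 * phi0), M = 1e7)
  tri <- triangulate_source(counts, cfg, sol)
  expect_lt(sqrt(sum((tri$x_hat - c(2, 0))^2)), 0.05)
  cfg2 <- build_config(c(0, pi), c(0.2, 0.2))
  expect_error(triangulate_source(count_table(c(5, 5)), cfg2), "N = 3")
})

test_that("polar averages report batchwise directions with circular safety", {
  tab <- data.frame(time = 1:6, angle = c(0.1, -0.1, 0.05, 3.1, -3.1, 3.14),
                    receptor_id = c(1, 1, 1, 2, 2, 2),
                    censored = rep(FALSE, 6))
  pa <- polar_average(tab, M_s = 3)
  # first batch: mean of small angles near zero
  expect_lt(abs(pa$theta_pa[1] - 0.0166), 1e-2)
  # second batch straddles the +-pi cut; the circular mean stays near pi
  expect_gt(abs(pa$theta_pa[2]), 3.0)
  expect_false(any(pa$partial))
  # all arrivals at one receptor: the receptor angle itself
  cfg <- build_config(c(0.7, -2), c(0.1, 0.1))
  tab1 <- data.frame(time = 1:5, angle = rep(0.7, 5),
                     receptor_id = rep(1, 5), censored = rep(FALSE, 5))
  expect_equal(polar_average(tab1, 5, config = cfg)$theta_pa, 0.7)
  # final partial batch flagged
  pa2 <- polar_average(tab, M_s = 4)
  expect_true(pa2$partial[2])
})

test_that("KS uniformity p-values are calibrated against a resampling oracle", {
  set.seed(11)
  # null calibration: roughly uniform p-values under uniform angles
  ps <- vapply(1:60, function(i) {
    ks_uniformity_pvalue(runif(200, -pi, pi))
  }, numeric(1))
  expect_gt(mean(ps > 0.5), 0.3)
  expect_lt(mean(ps < 0.05), 0.2)
  # point mass rejects
  expect_lt(ks_uniformity_pvalue(rep(0.3, 50) + rnorm(50, 0, 1e-3)), 1e-10)
  # asymptotic p close to a brute-force Monte Carlo p at n = 1001
  x <- runif(1001, -pi, pi)
  p_asym <- ks_uniformity_pvalue(x)
  dstat <- function(u) {
    u <- sort(u)
    n <- length(u)
    max(seq_len(n) / n - u, u - (seq_len(n) - 1) / n)
  }
  d0 <- dstat((x + pi) / (2 * pi))
  dnull <- vapply(1:10000, function(i) dstat(runif(1001)), numeric(1))
  p_mc <- mean(dnull >= d0)
  expect_lt(abs(p_asym - p_mc), 0.02)
})

test_that("Gumbel machinery matches its closed forms and monotonicities", {
  p <- absorbing_extreme_params(1e4, R = 2, D = 1)
  expect_equal(p$B, 0.25)               # (R-1)^2 / 4D
  expect_equal(p$q, 0.5)
  pr <- extreme_params(1e6, R = 5, kappa = 206.98, D = 1)
  expect_equal(pr$q, 1.5)
  expect_equal(pr$B, 4)
  expect_equal(pr$A, 4 * 206.98 * sqrt(1 / (5 * pi)) / 16, tolerance = 1e-12)
  # W_M increases and b_M decreases with the particle number
  Ms <- 10^(2:6)
  W <- vapply(Ms, function(M) extreme_params(M, 5, 206.98, 1)$W_M, numeric(1))
  b <- vapply(Ms, function(M) extreme_params(M, 5, 206.98, 1)$b_M, numeric(1))
  expect_true(all(diff(W) > 0))
  expect_true(all(diff(b) < 0))
  # Lambert-W consistency: W e^W equals its argument
  z <- (pr$B / pr$q) * (pr$A * 1e6)^(1 / pr$q)
  expect_equal(pr$W_M * exp(pr$W_M), z, tolerance = 1e-10)
  # the large-M mean expression coincides with mean = b - gamma*a
  em <- extreme_mean(pr)
  expect_equal(em$mean, em$mean_large_M, tolerance = 1e-12)
  expect_equal(em$variance, pi^2 * pr$a_M^2 / 6)
  # a_M -> 0 sends the mean to b_M
  expect_lt(abs(em$mean - pr$b_M), pr$a_M)
})

test_that("first-arrival angles are near-normal with the predicted variance", {
  M <- 1e4
  fa <- simulate_first_arrival(M, R = 2, D = 1, n_rep = 1000, t_max = 0.4,
                               seed = 8)
  th <- fa$theta_first[!is.na(fa$theta_first)]
  expect_gt(length(th), 990)
  p <- absorbing_extreme_params(M, 2, 1)
  s2 <- extreme_angle_variance(p)
  expect_lt(abs(var(th) / s2 - 1), 0.2)
  expect_lt(abs(mean(th)), 3 * sqrt(s2 / length(th)))
  kur <- mean((th - mean(th))^4) / stats::var(th)^2
  expect_gt(kur, 2.5)
  expect_lt(kur, 3.5)
  # variance decreasing in M; vanishing as the source touches the membrane
  s2s <- vapply(10^(3:6), function(M) {
    extreme_angle_variance(absorbing_extreme_params(M, 2, 1))
  }, numeric(1))
  expect_true(all(diff(s2s) < 0))
  g <- function(R) (R - 1)^2 / (3 * R)
  expect_equal(g(1), 0)
})
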