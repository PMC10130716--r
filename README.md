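# gradsense

Cells sense the direction of a chemical source from the noisy arrival of
diffusing molecules at membrane receptors. `gradsense` models this signal
for a circular cell in the plane: a reflecting unit disc whose boundary
carries `N` absorbing receptor arcs, with molecules released by a point
source outside the cell. The package computes where and *when* the signal
arrives — and what a cell (or an experimenter) could infer about the source
position from it.

## What it computes

**Static splitting probabilities.** The probability `φ_k(x)` that a molecule
released at `x` is first captured by receptor `k` solves an exterior mixed
Dirichlet–Neumann problem. In the small-receptor limit each arc of
arclength `εℓ_k` acts as a point absorber of logarithmic capacitance
`ν_k = −1/log(εℓ_k/4)`, and the "sums-of-logs" solution

    φ*_k(x) = −π Σ_j A_jk ν_j G_s(x; x_j) + φ̄_k

follows from an (N+1)×(N+1) linear system built on the reflecting-boundary
Green's function `G_s`. Accuracy is beyond any truncated expansion in
`1/|log ε|`; a spectrally accurate boundary-integral reference solver
(`spectral_splitting`) is included for validation.

**Dynamic receptor fluxes.** Laplace transforming the diffusion equation
gives a modified Helmholtz problem whose receptor strengths `A_k(s)` solve
`(I + πD G_h V) A = g_0`, with `G_h` the surface and bulk Green's functions
expressed through modified Bessel functions `K_m(α)`, `α = √(s/D)`. The
per-receptor flux transforms `Ĵ_k(s) = πD ν_k A_k(s)` are inverted
numerically on a Talbot contour (midpoint rule, ~1e-8 relative accuracy or
better on reference transforms), yielding fluxes `J_k(t)`, cumulative
fractional signals `q_k(t)`, and the capture fraction `C(t)`.

**Boundary homogenization.** For `N` equally spaced receptors the patchy
boundary is equivalent to a uniform partially absorbing (Robin) condition
`D ∂p/∂n = κp` with

    κ = −N D / (2 log(εN/4)),

valid for every dynamic angular mode, with flux modes
`χ_m(α) = K_m(αR) / (K_m(α) − Dκ⁻¹ α K_m'(α))` and short-time Gaussian
asymptotics (angular variance `2Dt/R`).

**Particle simulation.** A Monte Carlo simulator validates everything: a
time-free mode samples exact boundary-hit angles from the harmonic measure
(wrapped-Cauchy / Poisson kernel), and a time-resolved mode propagates
Brownian particles with adaptive steps, exact segment–circle crossing
detection, specular reflection, and a Brownian-bridge graze correction.

**Source inference.** Maximum-likelihood landscapes
`L(x;t) = −Σ_k c_k log q_k(x;t)` over candidate source positions, the exact
cross-entropy landscape, triangulation from splitting fractions, batched
polar averaging of receptor activity (with a Kolmogorov–Smirnov uniformity
diagnostic), and extreme-value (Gumbel) statistics of the fastest of `M`
arrivals, whose arrival angle estimates the source direction with variance
shrinking like `1/log M`.

## Worked example

Three receptors at angles `π/4, π, 3π/2` with arclengths
`0.1 × (π/3, π/3, 2π/3)`, source at `(2, 0)`, diffusivity 1:

```r
library(gradsense)
cfg <- three_receptor_config(eps = 0.1)
src <- source_spec(R = 2, theta0 = 0, D = 1)

## where does the signal eventually land?
sol <- solve_static(cfg)
round(splitting_probability(c(2, 0), sol), 4)
#> [1] 0.4143 0.2246 0.3610

## how fast does it arrive, and how is it distributed en route?
fs <- flux_time_series(cfg, src, times = c(1, 10, 1000))
round(fs$C, 4)          # fraction captured by t = 1, 10, 1000
#> [1] 0.0706 0.2845 0.5674
round(fs$q[, 3], 4)     # fractional signal per receptor at t = 1000
#> [1] 0.4804 0.1641 0.3555

## the simulator tells the same story
sim <- simulate_splitting(1e4, cfg, src, seed = 1)
sim$counts
#> [1] 4123 2250 3627
```

Receptor 1 (facing the source) receives 41% of all molecules eventually,
but early arrivals are far more lopsided: by `t = 1` receptor 2 (on the far
side) has seen essentially nothing, which is why short-time data carry the
directional information.

The homogenized model for a cell half-covered by 100 receptors:

```r
kappa <- homogenized_permeability(N = 100, eps = pi / 100, D = 1)
round(kappa, 2)
#> [1] 206.98
mod <- homogenized_model(kappa, R = 5, D = 1)
round(homog_capture_cdf(1000, mod), 3)   # capture fraction at the transition
#> [1] 0.595
```

and the fastest-arrival statistics for a million released molecules:

```r
p <- absorbing_extreme_params(M = 1e6, R = 5, D = 1)
signif(extreme_mean(p)$mean, 3)          # expected first-arrival time
#> [1] 0.339
signif(extreme_angle_variance(p), 3)     # variance of its arrival angle
#> [1] 0.142
```

A single first arrival already points to the source within ±0.38 rad (one
standard deviation) at distance 5.

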