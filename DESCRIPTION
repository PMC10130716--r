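Package: gradsense
Title: Diffusive Receptor Fluxes and Source Localization on a Circular Cell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the diffusive signal arriving at absorbing membrane
    receptors on a circular cell in the plane. Implements matched-asymptotic
    (sums-of-logs) splitting probabilities, dynamic per-receptor fluxes via
    Laplace-domain strengths inverted on a Talbot contour, a homogenized
    Robin-boundary model for dense receptor coverings with its short-time
    Gaussian asymptotics, a particle-based Monte Carlo simulator of the
    underlying diffusion, and source-localization estimators (maximum
    likelihood landscapes, triangulation, polar averaging, and extreme-value
    first-arrival statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
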