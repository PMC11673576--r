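# Analytic fixtures used across test files.

# Noise-free Volmer curve pi = kT/(A - a_exc) - cohesion, clipped at 0 and
# (optionally) at a collapse plateau.
volmer_curve <- function(a_exc = 33.1, cohesion = 7.5, kT = 407.3,
                         pi_collapse = Inf, area_max = 110, area_min = 40,
                         by = 0.1, ...) {
  A <- seq(area_max, area_min, by = -by)
  p <- pmin(pmax(kT / (A - a_exc) - cohesion, 0), pi_collapse)
  isotherm_curve(A, p, ...)
}

# Closed-form Volmer quantities on the unclipped branch
volmer_pressure <- function(A, a_exc = 33.1, cohesion = 7.5, kT = 407.3) {
  kT / (A - a_exc) - cohesion
}
volmer_area_at <- function(p, a_exc = 33.1, cohesion = 7.5, kT = 407.3) {
  a_exc + kT / (p + cohesion)
}
volmer_modulus <- function(A, a_exc = 33.1, kT = 407.3) {
  A * kT / (A - a_exc)^2
}

# Ideal 2D gas pi = c / A
ideal_gas_curve <- function(c0 = 400, area_max = 90, area_min = 40,
                            by = 0.1) {
  A <- seq(area_max, area_min, by = -by)
  isotherm_curve(A, c0 / A)
}

# Random planar point set whose min-max-normalised distances are exactly
# realisable in the plane (the set contains a coincident pair, so the
# smallest pairwise distance is 0 and the normalisation is a pure scaling).
planar_points_embeddable <- function(n = 8, seed = 1) {
  set.seed(seed)
  P <- matrix(stats::runif(2 * (n - 1)), n - 1, 2)
  rbind(P, P[1, ])
}
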