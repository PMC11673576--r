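# Seeded RNG isolation: run `expr` under a local seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Volmer-type isotherm model specification
#'
#' Parameters of the two-dimensional Volmer equation of state used to
#' emulate monolayer compression isotherms,
#' \deqn{\pi(A) = \frac{kT}{A - A_{exc}} - \Pi_{coh},}
#' clipped below at 0 (the balance reads ~0 before film lift-off) and above
#' at the collapse plateau.  A subphase additive at concentration `c` (in
#' micromolar) expands the excluded area, `A_exc(c) = a_exc0 * (1 +
#' alpha_expand * c)`, and softens the cohesion, `Pi_coh(c) = cohesion *
#' max(1 - beta_soften * c, 0.05)`, reproducing the qualitative signatures
#' of isotherm expansion and modulus reduction.
#'
#' @param model_id Membrane-model label.
#' @param a_exc0 Excluded (hard-core) area at zero additive, Angstrom^2.
#' @param cohesion Attractive pressure offset \eqn{\Pi_{coh}}, mN/m.
#' @param kT Thermal energy per area unit, mN/m Angstrom^2; 407.3
#'   corresponds to k_B T at 295 K expressed in these units.
#' @param pi_collapse Collapse plateau pressure, mN/m.
#' @param alpha_expand Fractional excluded-area increase per micromolar.
#' @param beta_soften Fractional cohesion reduction per micromolar.
#' @param noise_sd Gaussian pressure noise, mN/m.
#' @return An object of class `isotherm_model_spec`.
#' @export
isotherm_model_spec <- function(model_id = "CM1", a_exc0 = 33.1,
                                cohesion = 7.5, kT = 407.3,
                                pi_collapse = 52.7, alpha_expand = 0.01,
                                beta_soften = 0.005, noise_sd = 0.2) {
  stopifnot(a_exc0 > 0, kT > 0, pi_collapse > 0, alpha_expand >= 0,
            noise_sd >= 0, cohesion >= 0)
  structure(
    list(model_id = model_id, a_exc0 = a_exc0, cohesion = cohesion,
         kT = kT, pi_collapse = pi_collapse, alpha_expand = alpha_expand,
         beta_soften = beta_soften, noise_sd = noise_sd),
    class = "isotherm_model_spec"
  )
}

#' Default membrane-model specifications
#'
#' Named list of Volmer specifications for the four membrane models: CM1
#' and HM1 (saturated-lipid mixtures: stiffer films, collapse near 53
#' mN/m; the CM1 baseline is placed near A_30 ~ 44 Angstrom^2 and
#' C_S^-1 at 30 mN/m ~ 150 mN/m) and CM2 and HM2 (mixtures containing an
#' unsaturated lipid: softer, more expanded films collapsing near 42
#' mN/m).  These are toy equations of state with realistic magnitudes, not
#' fits to any measured system.
#'
#' @param alpha_expand,beta_soften,noise_sd Overrides applied to every
#'   model (defaults as in [isotherm_model_spec()]).
#' @return Named list of `isotherm_model_spec` objects.
#' @export
default_model_specs <- function(alpha_expand = 0.01, beta_soften = 0.005,
                                noise_sd = 0.2) {
  base <- list(
    CM1 = list(a_exc0 = 33.1, cohesion = 7.5, pi_collapse = 52.7),
    HM1 = list(a_exc0 = 32.8, cohesion = 10.6, pi_collapse = 53.8),
    CM2 = list(a_exc0 = 38.0, cohesion = 4.0, pi_collapse = 42.6),
    HM2 = list(a_exc0 = 37.0, cohesion = 4.5, pi_collapse = 42.8)
  )
  out <- lapply(names(base), function(id) {
    b <- base[[id]]
    isotherm_model_spec(model_id = id, a_exc0 = b$a_exc0,
                        cohesion = b$cohesion, pi_collapse = b$pi_collapse,
                        alpha_expand = alpha_expand,
                        beta_soften = beta_soften, noise_sd = noise_sd)
  })
  names(out) <- names(base)
  out
}

effective_spec <- function(spec, conc) {
  list(a_exc = spec$a_exc0 * (1 + spec$alpha_expand * conc),
       cohesion = spec$cohesion * max(1 - spec$beta_soften * conc, 0.05))
}

#' Generate a synthetic compression isotherm
#'
#' Evaluates the Volmer equation of state of `spec` at additive
#' concentration `conc` on a uniform area grid, clips at lift-off (pi = 0)
#' and collapse, and adds i.i.d. Gaussian pressure noise (floored at -0.45
#' mN/m, the sensor floor).  Bit-identical for a fixed `seed`.
#'
#' @param spec An [isotherm_model_spec()].
#' @param conc Additive concentration, micromolar.
#' @param area_max Largest area on the grid, Angstrom^2; the default
#'   spreads to 15 Angstrom^2 beyond the lift-off area (where the Volmer
#'   pressure reaches 0), so every curve starts on the zero-pressure
#'   baseline.
#' @param area_min Smallest area; default compresses 4 Angstrom^2 past the
#'   collapse point to produce a plateau.
#' @param by Area grid spacing, Angstrom^2 (default 0.25).
#' @param seed Integer RNG seed (default 1).
#' @param replicate Replicate index recorded in the metadata.
#' @return An [isotherm_curve()].
#' @export
generate_isotherm <- function(spec, conc = 0, area_max = NULL,
                              area_min = NULL, by = 0.25, seed = 1L,
                              replicate = 1L) {
  stopifnot(inherits(spec, "isotherm_model_spec"))
  eff <- effective_spec(spec, conc)
  a_col <- eff$a_exc + spec$kT / (spec$pi_collapse + eff$cohesion)
  if (is.null(area_max)) {
    a_lift <- eff$a_exc + spec$kT / max(eff$cohesion, 1)
    area_max <- a_lift + 15
  }
  if (is.null(area_min)) area_min <- max(a_col - 4, eff$a_exc + 1)
  if (area_min <= eff$a_exc) {
    stop("area grid enters the excluded area", call. = FALSE)
  }
  A <- seq(area_max, area_min, by = -abs(by))
  p <- spec$kT / (A - eff$a_exc) - eff$cohesion
  p <- pmin(pmax(p, 0), spec$pi_collapse)
  if (spec$noise_sd > 0) {
    p <- p + with_seed(seed, stats::rnorm(length(p), sd = spec$noise_sd))
    p <- pmax(p, -0.45)
  }
  isotherm_curve(A, p, model_id = spec$model_id, scx4_conc = conc,
                 replicate = replicate)
}

#' Generate a labelled collection of isotherms
#'
#' Replicated synthetic isotherms for every (membrane model, additive
#' concentration) condition, mirroring a 4-model x 4-concentration x
#' replicate experimental design.  Per-curve seeds are derived
#' deterministically from the master seed, so two calls with the same
#' arguments are bit-identical.
#'
#' @param specs Named list of [isotherm_model_spec()] objects (default
#'   [default_model_specs()]).
#' @param concs Additive concentrations, micromolar (default
#'   `c(0, 1, 10, 30)`).
#' @param replicates Replicates per condition (default 3).
#' @param seed Master seed (default 1).
#' @param effect_scale Multiplier applied to every spec's `alpha_expand`
#'   and `beta_soften`, for sweeping the additive effect size (default 1).
#' @return Named list of `isotherm_curve` objects with attributes `labels`
#'   (condition label `model_conc` per curve) and `conditions`.
#' @export
generate_condition_set <- function(specs = default_model_specs(),
                                   concs = c(0, 1, 10, 30),
                                   replicates = 3, seed = 1L,
                                   effect_scale = 1) {
  stopifnot(length(specs) >= 1, replicates >= 1, effect_scale >= 0)
  curves <- list()
  labels <- character(0)
  counter <- 0L
  for (id in names(specs)) {
    spec <- specs[[id]]
    spec$alpha_expand <- spec$alpha_expand * effect_scale
    spec$beta_soften <- spec$beta_soften * effect_scale
    for (conc in concs) {
      for (r in seq_len(replicates)) {
        counter <- counter + 1L
        crv <- generate_isotherm(
          spec, conc = conc,
          seed = (as.integer(seed) * 1000L + counter) %% 2147483647L,
          replicate = r)
        nm <- sprintf("%s_c%g_r%d", id, conc, r)
        curves[[nm]] <- crv
        labels <- c(labels, sprintf("%s_%g", id, conc))
      }
    }
  }
  structure(curves, labels = labels,
            conditions = unique(labels))
}

#' Generate a toy particle configuration
#'
#' Places particles in an orthorhombic box with a prescribed z profile:
#' `"uniform"` fills the whole box, `"step"` fills only `z < midpoint`, and
#' `"sigmoid"` draws z from a density proportional to a normal-CDF decay of
#' scale `width` centred at `midpoint` (inverse-CDF sampling).  x and y are
#' always uniform.  Deterministic for a fixed seed.
#'
#' @param n Number of particles.
#' @param box Box lengths `c(Lx, Ly, Lz)`, nm (default `c(18, 18, 23)`).
#' @param profile One of `"uniform"`, `"step"`, `"sigmoid"`.
#' @param midpoint Profile midpoint along z, nm (default 3.6).
#' @param width Sigmoid scale (normal-CDF sigma), nm (default 0.5).
#' @param species Species label (default `"A"`).
#' @param seed Integer RNG seed (default 1).
#' @return A [particle_configuration()].
#' @export
generate_gas_config <- function(n = 8000, box = c(18, 18, 23),
                                profile = c("uniform", "step", "sigmoid"),
                                midpoint = 3.6, width = 0.5,
                                species = "A", seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(n >= 1, length(box) == 3, all(box > 0),
            midpoint > 0, midpoint < box[3], width > 0)
  pos <- with_seed(seed, {
    x <- stats::runif(n, 0, box[1])
    y <- stats::runif(n, 0, box[2])
    z <- switch(profile,
      uniform = stats::runif(n, 0, box[3]),
      step = stats::runif(n, 0, midpoint),
      sigmoid = {
        zg <- seq(0, box[3], length.out = 4096)
        dens <- stats::pnorm((midpoint - zg) / width)
        cdf <- pracma::cumtrapz(zg, dens)
        cdf <- as.numeric(cdf / cdf[length(cdf)])
        stats::approx(cdf, zg, xout = stats::runif(n), ties = "ordered")$y
      })
    cbind(x, y, z)
  })
  particle_configuration(pos, rep(species, n), box)
}

#' Generate a pressure-tensor profile with known tension
#'
#' Builds a tabulated pressure-tensor profile whose anisotropy
#' `p_N - p_T` integrates exactly (rectangle) or to quadrature accuracy
#' (Gaussian) to a prescribed surface tension, for validating the
#' pressure-tensor tension integral.
#'
#' @param gamma_target Target surface tension, mN/m.
#' @param shape `"rect"` (rectangular anomaly; edges snapped to grid nodes
#'   and given half height so the trapezoidal integral is exact) or
#'   `"gauss"` (Gaussian anomaly of sigma = `width`).
#' @param z Tabulation grid, nm (default `seq(-10, 10, by = 0.05)`).
#' @param center Anomaly center, nm (default 0).
#' @param width Rectangle full width or Gaussian sigma, nm (default 2 for
#'   rect, 1 for gauss).
#' @return A [pressure_profile()] with `p_tangential = 0` and `p_normal`
#'   equal to the anomaly.
#' @export
generate_pressure_profile <- function(gamma_target,
                                      shape = c("rect", "gauss"),
                                      z = seq(-10, 10, by = 0.05),
                                      center = 0, width = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.finite(gamma_target), length(z) >= 5, all(diff(z) > 0))
  h <- max(diff(z))
  if (shape == "rect") {
    width <- width %||% 2
    if (width < 4 * h) stop("grid too coarse to resolve the rectangle",
                            call. = FALSE)
    a <- z[which.min(abs(z - (center - width / 2)))]
    b <- z[which.min(abs(z - (center + width / 2)))]
    amp <- gamma_target / (b - a)
    p <- numeric(length(z))
    p[z > a & z < b] <- amp
    p[z == a | z == b] <- amp / 2
  } else {
    width <- width %||% 1
    if (width < 4 * h) stop("grid too coarse to resolve the Gaussian",
                            call. = FALSE)
    amp <- gamma_target / (width * sqrt(2 * pi))
    p <- amp * exp(-(z - center)^2 / (2 * width^2))
  }
  pressure_profile(z, p_normal = p, p_tangential = numeric(length(z)))
}
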