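#' Construct a surface pressure-area isotherm
#'
#' An `isotherm_curve` stores one compression isotherm of a Langmuir
#' monolayer: the mean molecular area per lipid (in square Angstrom) and the
#' surface pressure \eqn{\pi} (in mN/m), together with the condition metadata
#' used downstream (membrane model, subphase additive concentration,
#' temperature).  Points are stored in compression order, i.e. with strictly
#' decreasing area.
#'
#' @param area Numeric vector of mean molecular areas, in Angstrom^2.  Must be
#'   strictly monotone; curves supplied in expansion order (increasing area)
#'   are reversed into compression order.
#' @param pressure Numeric vector of surface pressures, in mN/m, same length
#'   as `area`.  Small negative values (down to -0.5 mN/m, sensor noise
#'   around the bare interface) are tolerated.
#' @param model_id Character label for the membrane model (e.g. `"CM1"`).
#' @param scx4_conc Subphase additive concentration, in micromolar.
#' @param temperature Subphase temperature, in degrees Celsius.
#' @param replicate Optional replicate index.
#' @return An object of class `isotherm_curve`: a list with elements `area`,
#'   `pressure`, `model_id`, `scx4_conc`, `temperature`, `replicate`.
#' @examples
#' a <- seq(100, 40, by = -0.5)
#' crv <- isotherm_curve(a, pmax(407.3 / (a - 33) - 7.5, 0), model_id = "CM1")
#' crv
#' @export
isotherm_curve <- function(area, pressure, model_id = "", scx4_conc = 0,
                           temperature = 22, replicate = NA_integer_) {
  area <- as.numeric(area)
  pressure <- as.numeric(pressure)
  if (length(area) != length(pressure)) {
    stop("`area` and `pressure` must have the same length", call. = FALSE)
  }
  if (length(area) < 10L) {
    stop("an isotherm needs at least 10 points", call. = FALSE)
  }
  if (any(!is.finite(area)) || any(!is.finite(pressure))) {
    stop("non-finite values in isotherm data", call. = FALSE)
  }
  if (any(area <= 0)) stop("all areas must be positive", call. = FALSE)
  d <- diff(area)
  if (all(d > 0)) { # expansion order: flip into compression order
    area <- rev(area)
    pressure <- rev(pressure)
  } else if (!all(d < 0)) {
    stop("areas must be strictly monotone (compression order)", call. = FALSE)
  }
  if (any(pressure < -0.5)) {
    stop("surface pressures below -0.5 mN/m are not physical sensor noise",
         call. = FALSE)
  }
  structure(
    list(area = area, pressure = pressure, model_id = model_id,
         scx4_conc = scx4_conc, temperature = temperature,
         replicate = replicate),
    class = "isotherm_curve"
  )
}

#' @export
print.isotherm_curve <- function(x, ...) {
  cat(sprintf(
    "<isotherm_curve> %s, %g uM, %g C: %d points, A %.1f-%.1f A^2, pi %.2f-%.2f mN/m\n",
    if (nzchar(x$model_id)) x$model_id else "(unnamed)", x$scx4_conc,
    x$temperature, length(x$area), min(x$area), max(x$area),
    min(x$pressure), max(x$pressure)))
  invisible(x)
}

#' @export
plot.isotherm_curve <- function(x, ...) {
  graphics::plot(x$area, x$pressure, type = "l",
                 xlab = expression("Mean molecular area (" * ring(A)^2 * ")"),
                 ylab = expression(pi ~ "(mN/m)"),
                 xlim = rev(range(x$area)), ...)
  invisible(x)
}

#' Adjacent-averaging smoother
#'
#' Smooths an ordered series with a running mean over a fixed point-count
#' window, the standard noise-reduction step applied to compressibility
#' curves before differentiation.  For a window of `w` points the value at
#' position `i` averages positions `i - ceiling(w/2) + 1` through
#' `i + floor(w/2)`; near the edges the window shrinks to the largest
#' symmetric window that fits, so the output has the same length as the
#' input and constant series pass through unchanged.
#'
#' @param x Numeric vector (ordered series).
#' @param window Window size in points (default 10, the conventional choice
#'   for compressional-modulus curves).  `window = 1` is the identity.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' smooth_adjacent_average(c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5), window = 10)
#' @export
smooth_adjacent_average <- function(x, window = 10) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) stop("empty series", call. = FALSE)
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window > n) stop("window larger than the series", call. = FALSE)
  a <- as.integer(ceiling(window / 2) - 1) # points before i
  b <- as.integer(floor(window / 2))       # points after i
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- i - a
    hi <- i + b
    if (lo < 1L || hi > n) { # shrink symmetrically at the edges
      h <- min(i - 1L, n - i)
      lo <- i - h
      hi <- i + h
    }
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Smooth the pressure trace of an isotherm
#'
#' Convenience wrapper applying [smooth_adjacent_average()] to the surface
#' pressure of an isotherm while keeping the metadata.
#'
#' @param curve An [isotherm_curve()].
#' @param window Smoothing window in points; `1` disables smoothing.
#' @return An `isotherm_curve` with smoothed pressures.
#' @export
smooth_isotherm <- function(curve, window = 10) {
  stopifnot(inherits(curve, "isotherm_curve"))
  curve$pressure <- smooth_adjacent_average(curve$pressure, window)
  curve
}

# Resample a (possibly noisy) curve onto a uniform, decreasing area grid.
# Returns list(area, pressure) in compression order.
resample_uniform_area <- function(curve, spacing = 0.1) {
  a <- curve$area
  p <- curve$pressure
  grid <- seq(max(a), min(a), by = -abs(spacing))
  list(area = grid,
       pressure = stats::approx(a, p, xout = grid, rule = 2,
                                ties = mean)$y)
}

#' Compressional modulus of a monolayer
#'
#' Computes the surface compressional modulus
#' \deqn{C_S^{-1} = -A \left(\frac{\partial \pi}{\partial A}\right)}
#' from a surface pressure-area isotherm.  The pressure trace is smoothed by
#' adjacent averaging, resampled onto a uniform area grid, and
#' differentiated by central finite differences (one-sided at the
#' endpoints); the resulting modulus curve is smoothed with the same
#' window, the conventional noise-reduction step for compressibility
#' curves.
#'
#' @param curve An [isotherm_curve()] with at least 3 points.
#' @param window Smoothing window in points (default 10; use 1 for none).
#' @param grid_spacing Uniform area-grid spacing in Angstrom^2 (default 0.1).
#' @return An object of class `modulus_curve`: list with `grid` (areas, in
#'   compression order), `modulus` (\eqn{C_S^{-1}} in mN/m), `grid_kind =
#'   "area"`, and `pressure` (smoothed pressure on the same grid, handy for
#'   re-expressing the modulus against pressure).
#' @examples
#' a <- seq(90, 40, by = -0.1)
#' crv <- isotherm_curve(a, 400 / a)     # ideal 2D gas: Cs^-1 == pi
#' m <- compressional_modulus(crv, window = 1)
#' max(abs(m$modulus - m$pressure) / m$pressure)
#' @export
compressional_modulus <- function(curve, window = 10, grid_spacing = 0.1) {
  stopifnot(inherits(curve, "isotherm_curve"))
  if (length(curve$area) < 3L) stop("need at least 3 points", call. = FALSE)
  sm <- smooth_isotherm(curve, window)
  rs <- resample_uniform_area(sm, grid_spacing)
  A <- rs$area
  p <- rs$pressure
  n <- length(A)
  h <- A[2] - A[1] # negative (compression order)
  dpdA <- numeric(n)
  dpdA[1] <- (p[2] - p[1]) / h
  dpdA[n] <- (p[n] - p[n - 1]) / h
  if (n > 2) dpdA[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * h)
  cs <- -A * dpdA
  if (window > 1) cs <- smooth_adjacent_average(cs, min(window, n))
  structure(
    list(grid = A, modulus = cs, grid_kind = "area", pressure = p),
    class = "modulus_curve"
  )
}

#' @export
print.modulus_curve <- function(x, ...) {
  cat(sprintf("<modulus_curve> %d points on %s grid, max Cs^-1 = %.1f mN/m\n",
              length(x$grid), x$grid_kind, max(x$modulus)))
  invisible(x)
}

#' Two-dimensional phase from the compressional modulus
#'
#' Classifies the monolayer phase from the magnitude of \eqn{C_S^{-1}}:
#' values below 25 mN/m imply a low-density liquid, 25-50 mN/m a
#' liquid-expanded (LE) film, 100-250 mN/m a liquid-condensed (LC) film and
#' values above 500 mN/m a solid film.  The unassigned gaps (50-100 and
#' 250-500 mN/m) are reported as `"intermediate"`.
#'
#' @param cs_value Numeric vector of modulus values, mN/m; must be >= 0
#'   (negative measurements should be clipped to 0 before classification).
#' @return Character vector of phase labels: `"low-density liquid"`,
#'   `"liquid-expanded"`, `"intermediate"`, `"liquid-condensed"`, `"solid"`.
#' @examples
#' classify_phase(c(10, 30, 150, 600))
#' @export
classify_phase <- function(cs_value) {
  cs_value <- as.numeric(cs_value)
  if (any(!is.finite(cs_value))) stop("non-finite modulus", call. = FALSE)
  if (any(cs_value < 0)) stop("modulus must be >= 0", call. = FALSE)
  out <- character(length(cs_value))
  out[cs_value < 25] <- "low-density liquid"
  out[cs_value >= 25 & cs_value <= 50] <- "liquid-expanded"
  out[cs_value > 50 & cs_value < 100] <- "intermediate"
  out[cs_value >= 100 & cs_value <= 250] <- "liquid-condensed"
  out[cs_value > 250 & cs_value <= 500] <- "intermediate"
  out[cs_value > 500] <- "solid"
  out
}

#' Limiting (extrapolated) molecular area
#'
#' Extrapolates a tangent line from the most condensed region of the
#' isotherm to zero surface pressure and returns its area intercept, the
#' effective molecular footprint \eqn{A_{ex}}.  The "most ordered phase" is
#' taken operationally as the point of maximum \eqn{C_S^{-1}} (the steepest
#' condensed region); the tangent is a least-squares line fitted to the
#' smoothed isotherm over a small area window centred at that point (a
#' single-point finite difference would pass measurement noise straight
#' into the intercept).  When the maximum sits on the grid boundary the
#' window is one-sided and the result carries attribute `boundary = TRUE`.
#'
#' @inheritParams compressional_modulus
#' @param modulus Optionally, a precomputed `modulus_curve` for `curve`
#'   (with matching `window`/`grid_spacing`); computed if `NULL`.
#' @param tangent_halfwidth Half-width, in Angstrom^2, of the area window
#'   used for the tangent fit (default 1).
#' @return Limiting area in Angstrom^2 (numeric scalar, attribute
#'   `boundary` flags a one-sided tangent).
#' @export
limiting_area <- function(curve, modulus = NULL, window = 10,
                          grid_spacing = 0.1, tangent_halfwidth = 1) {
  if (is.null(modulus)) {
    modulus <- compressional_modulus(curve, window, grid_spacing)
  }
  stopifnot(inherits(modulus, "modulus_curve"), modulus$grid_kind == "area")
  A <- modulus$grid
  p <- modulus$pressure
  i <- which.max(modulus$modulus)
  n <- length(A)
  boundary <- i == 1L || i == n
  sel <- which(abs(A - A[i]) <= tangent_halfwidth)
  if (length(sel) < 2L) sel <- unique(pmax(1L, pmin(n, c(i - 1L, i, i + 1L))))
  fit <- stats::lm.fit(cbind(1, A[sel]), p[sel])
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0) {
    stop("tangent undefined at the point of maximum modulus", call. = FALSE)
  }
  # intercept of the fitted line with pi = 0
  structure(unname(-fit$coefficients[1] / slope), boundary = boundary)
}

#' Collapse pressure of a compression isotherm
#'
#' Detects monolayer collapse as the loss of in-plane elasticity: walking in
#' compression order, once \eqn{C_S^{-1}} has exceeded 25 mN/m (the film has
#' left the low-density regime) the collapse point is the first sample where
#' the modulus falls below a fraction (default 10%) of its running maximum.
#' This detection rule is a convention of this package; reported collapse
#' pressures in the experimental literature are read off plateaus by eye.
#' The scan is restricted to surface pressures above `min_pressure`: in the
#' dilute/coexistence regime the modulus of a noisy isotherm is dominated
#' by amplified measurement noise (the `-A` factor is large there) and
#' collapse below a few mN/m is not physically meaningful.
#'
#' @inheritParams limiting_area
#' @param threshold_frac Fraction of the running maximum modulus below which
#'   the film counts as collapsed (default 0.1).
#' @param activation Modulus (mN/m) that must be exceeded before collapse
#'   detection is armed (default 25).
#' @param min_pressure Smallest surface pressure (mN/m) considered in the
#'   scan (default 5).
#' @return Collapse pressure in mN/m.  If no collapse is detected the
#'   maximum pressure is returned with attribute `no_collapse = TRUE`.
#' @export
collapse_pressure <- function(curve, modulus = NULL, window = 10,
                              grid_spacing = 0.1, threshold_frac = 0.1,
                              activation = 25, min_pressure = 5) {
  if (is.null(modulus)) {
    modulus <- compressional_modulus(curve, window, grid_spacing)
  }
  stopifnot(inherits(modulus, "modulus_curve"))
  cs <- modulus$modulus
  p <- modulus$pressure
  armed <- FALSE
  runmax <- -Inf
  for (i in seq_along(cs)) {
    if (p[i] < min_pressure) next
    runmax <- max(runmax, cs[i])
    if (!armed && runmax > activation) armed <- TRUE
    if (armed && cs[i] < threshold_frac * runmax) {
      return(p[i])
    }
  }
  structure(max(curve$pressure), no_collapse = TRUE)
}

# Compression branch up to the first pressure maximum, on the smoothed
# uniform grid; used for interpolating quantities "at a pressure".
compression_branch <- function(modulus) {
  k <- which.max(modulus$pressure)
  idx <- seq_len(k)
  list(area = modulus$grid[idx], pressure = modulus$pressure[idx],
       modulus = modulus$modulus[idx])
}

#' Scalar monolayer parameters at a reference pressure
#'
#' Summarises an isotherm by the standard scalar parameters reported for
#' monolayer studies: extrapolated area \eqn{A_{ex}}, area at the reference
#' pressure (default the biologically relevant 30 mN/m) \eqn{A_{30}},
#' collapse pressure \eqn{\pi_{col}}, maximum compressional modulus
#' \eqn{C_{S,max}^{-1}} and modulus at the reference pressure
#' \eqn{C_{S,30}^{-1}}.  Interpolations are linear on the smoothed curve,
#' restricted to the compression branch up to the pressure maximum.
#'
#' @inheritParams limiting_area
#' @param pi_ref Reference surface pressure, mN/m (default 30).
#' @return An object of class `monolayer_parameters`: list with `a_ex`,
#'   `a_30`, `pi_col`, `cs_max`, `cs_30`, `pi_ref`, `model_id`, `scx4_conc`,
#'   and logical flags `boundary_tangent`, `no_collapse`.
#' @examples
#' a <- seq(110, 41, by = -0.2)
#' crv <- isotherm_curve(a, pmax(407.3 / (a - 33) - 7.5, 0))
#' parameters_at(crv, window = 1)
#' @export
parameters_at <- function(curve, modulus = NULL, pi_ref = 30, window = 10,
                          grid_spacing = 0.1) {
  stopifnot(inherits(curve, "isotherm_curve"))
  if (is.null(modulus)) {
    modulus <- compressional_modulus(curve, window, grid_spacing)
  }
  br <- compression_branch(modulus)
  if (pi_ref < min(br$pressure) || pi_ref > max(br$pressure)) {
    stop(sprintf("pi_ref = %g mN/m outside the measured range [%.3g, %.3g]",
                 pi_ref, min(br$pressure), max(br$pressure)), call. = FALSE)
  }
  a_ref <- stats::approx(br$pressure, br$area, xout = pi_ref,
                         ties = mean)$y
  cs_ref <- stats::approx(br$pressure, br$modulus, xout = pi_ref,
                          ties = mean)$y
  a_ex <- limiting_area(curve, modulus)
  pi_col <- collapse_pressure(curve, modulus)
  structure(
    list(a_ex = as.numeric(a_ex), a_30 = a_ref, pi_col = as.numeric(pi_col),
         cs_max = max(modulus$modulus), cs_30 = cs_ref, pi_ref = pi_ref,
         model_id = curve$model_id, scx4_conc = curve$scx4_conc,
         boundary_tangent = isTRUE(attr(a_ex, "boundary")),
         no_collapse = isTRUE(attr(pi_col, "no_collapse"))),
    class = "monolayer_parameters"
  )
}

#' @export
print.monolayer_parameters <- function(x, ...) {
  cat(sprintf(
    "<monolayer_parameters> %s @ %g uM: A_ex %.1f, A_%g %.1f A^2, pi_col %.1f, Cs_max %.0f, Cs_%g %.0f mN/m\n",
    if (nzchar(x$model_id)) x$model_id else "(unnamed)", x$scx4_conc,
    x$a_ex, x$pi_ref, x$a_30, x$pi_col, x$cs_max, x$pi_ref, x$cs_30))
  invisible(x)
}

#' Percent change between two measurements
#'
#' `100 * (before - after) / before`; positive values are decreases, the
#' sign convention used when quoting modulus reductions caused by a
#' subphase additive.
#'
#' @param before,after Numeric scalars; `before` must be nonzero.
#' @return Percent change (positive = decrease).
#' @examples
#' percent_change(152, 60) # ~60% decrease
#' @export
percent_change <- function(before, after) {
  if (!is.finite(before) || !is.finite(after)) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (before == 0) stop("`before` must be nonzero", call. = FALSE)
  100 * (before - after) / before
}

#' Surface pressure from surface tensions
#'
#' \eqn{\pi = \gamma_0 - \gamma}: the surface pressure is the reduction of
#' the bare-interface tension \eqn{\gamma_0} (72.8 mN/m for water at room
#' temperature) caused by the film of tension \eqn{\gamma}.  Negative
#' results are reported as-is.
#'
#' @param gamma0 Bare-interface surface tension, mN/m.
#' @param gamma Surface tension with the film present, mN/m.
#' @return Surface pressure, mN/m.
#' @examples
#' surface_pressure_from_tension(72.8, 42.8)
#' @export
surface_pressure_from_tension <- function(gamma0, gamma) {
  if (any(!is.finite(gamma0)) || any(!is.finite(gamma))) {
    stop("tensions must be finite", call. = FALSE)
  }
  gamma0 - gamma
}
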