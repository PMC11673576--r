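#' Particle configuration in an orthorhombic box
#'
#' Holds one frame of a slab/gas particle system: positions in nm (wrapped
#' into `[0, L)` along each axis), a species label per particle, and the
#' orthorhombic box lengths.
#'
#' @param positions Numeric matrix (N x 3) of x, y, z coordinates in nm.
#' @param species Character vector of length N (particle species labels).
#' @param box Numeric vector `c(Lx, Ly, Lz)` in nm, all positive.
#' @return An object of class `particle_configuration` with elements
#'   `positions`, `species`, `box`, `n`, `rho` (number density, nm^-3).
#' @export
particle_configuration <- function(positions, species, box) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(box) == 3, all(box > 0),
            length(species) == nrow(positions))
  if (any(!is.finite(positions))) stop("non-finite positions", call. = FALSE)
  for (k in 1:3) positions[, k] <- positions[, k] %% box[k]
  structure(
    list(positions = positions, species = as.character(species),
         box = as.numeric(box), n = nrow(positions),
         rho = nrow(positions) / prod(box)),
    class = "particle_configuration"
  )
}

#' @export
print.particle_configuration <- function(x, ...) {
  cat(sprintf(
    "<particle_configuration> %d particles (%s) in %.4g x %.4g x %.4g nm box\n",
    x$n, paste(unique(x$species), collapse = ","),
    x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

as_config_list <- function(configs) {
  if (inherits(configs, "particle_configuration")) configs <- list(configs)
  stopifnot(length(configs) >= 1,
            all(vapply(configs, inherits, logical(1),
                       "particle_configuration")))
  box <- configs[[1]]$box
  for (cf in configs) {
    if (!isTRUE(all.equal(cf$box, box))) {
      stop("all frames must share the same box", call. = FALSE)
    }
  }
  configs
}

#' Number-density profile along z
#'
#' Histograms particle z coordinates in bins of fixed width, averages over
#' frames, and normalises by the bin volume `Lx * Ly * bin_width`, giving a
#' number density in nm^-3 per species.  By construction the bin sums
#' reproduce the particle counts exactly.
#'
#' @param configs A `particle_configuration` or list of frames sharing one
#'   box.
#' @param bin_width Bin width along z, nm; must be positive and no larger
#'   than the box height.
#' @param species Optional character vector restricting the profile to some
#'   species.
#' @return An object of class `density_profile`: list with `z_centers`,
#'   `density` (bins x species matrix, nm^-3), `counts` (mean raw counts),
#'   `bin_width`, `box`, `n_frames`.
#' @export
density_profile <- function(configs, bin_width = 0.1, species = NULL) {
  configs <- as_config_list(configs)
  box <- configs[[1]]$box
  if (bin_width <= 0 || bin_width > box[3]) {
    stop("bin_width must lie in (0, Lz]", call. = FALSE)
  }
  nbins <- as.integer(ceiling(box[3] / bin_width - 1e-9))
  centers <- (seq_len(nbins) - 0.5) * bin_width
  sp_all <- sort(unique(unlist(lapply(configs, `[[`, "species"))))
  if (!is.null(species)) sp_all <- intersect(sp_all, species)
  if (length(sp_all) == 0L) stop("no matching species", call. = FALSE)
  counts <- matrix(0, nbins, length(sp_all), dimnames = list(NULL, sp_all))
  for (cf in configs) {
    for (sp in sp_all) {
      z <- cf$positions[cf$species == sp, 3]
      idx <- pmin(floor(z / bin_width) + 1L, nbins)
      tab <- tabulate(idx, nbins)
      counts[, sp] <- counts[, sp] + tab
    }
  }
  counts <- counts / length(configs)
  vol <- box[1] * box[2] * bin_width
  structure(
    list(z_centers = centers, density = counts / vol, counts = counts,
         bin_width = bin_width, box = box, n_frames = length(configs)),
    class = "density_profile"
  )
}

#' Construct a density profile from tabulated values
#'
#' Builds a `density_profile` directly from bin centers and densities, for
#' analytically defined profiles or externally tabulated data.
#'
#' @param z_centers Strictly increasing, uniformly spaced bin centers, nm.
#' @param density Numeric vector (one species) or matrix (bins x species)
#'   of number densities, nm^-3.
#' @param bin_width Bin width, nm; defaults to the center spacing.
#' @return A `density_profile`.
#' @export
density_profile_from_values <- function(z_centers, density,
                                        bin_width = NULL) {
  z_centers <- as.numeric(z_centers)
  stopifnot(length(z_centers) >= 2, all(diff(z_centers) > 0))
  if (is.null(bin_width)) bin_width <- z_centers[2] - z_centers[1]
  if (is.null(dim(density))) {
    density <- matrix(density, ncol = 1, dimnames = list(NULL, "A"))
  }
  stopifnot(nrow(density) == length(z_centers), all(density >= 0))
  structure(
    list(z_centers = z_centers, density = density,
         counts = NULL, bin_width = bin_width, box = NULL, n_frames = 1L),
    class = "density_profile"
  )
}

profile_species_column <- function(profile, species) {
  dens <- profile$density
  if (is.null(species)) {
    if (ncol(dens) != 1L) {
      stop("profile has several species; name one", call. = FALSE)
    }
    return(dens[, 1])
  }
  if (!species %in% colnames(dens)) {
    stop(sprintf("species '%s' not in profile", species), call. = FALSE)
  }
  dens[, species]
}

# Bulk density: mean over the densest contiguous 20% of bins.
bulk_density <- function(z, d) {
  n <- length(d)
  w <- max(1L, as.integer(ceiling(0.2 * n)))
  cs <- cumsum(c(0, d))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  i0 <- which.max(means)
  list(bulk = means[i0], start = i0, end = i0 + w - 1L)
}

# First downward crossing of `level`, scanning in +z from `from` (bin index),
# linearly interpolated between bin centers.
first_crossing <- function(z, d, level, from = 1L) {
  n <- length(d)
  hits <- integer(0)
  for (k in seq(max(from, 1L), n - 1L)) {
    if (d[k] >= level && d[k + 1] < level) hits <- c(hits, k)
  }
  if (length(hits) == 0L) return(NULL)
  k <- hits[1]
  frac <- (d[k] - level) / (d[k] - d[k + 1])
  list(z = z[k] + frac * (z[k + 1] - z[k]), multiple = length(hits) > 1L)
}

# Last downward crossing of `level`: robust to statistical dips inside the
# bulk plateau (the dilute tail cannot fluctuate up to the level, so the
# last crossing is the true decay).
last_crossing <- function(z, d, level, from = 1L) {
  n <- length(d)
  for (k in seq(n - 1L, max(from, 1L))) {
    if (d[k] >= level && d[k + 1] < level) {
      frac <- (d[k] - level) / (d[k] - d[k + 1])
      return(list(z = z[k] + frac * (z[k + 1] - z[k])))
    }
  }
  NULL
}

#' Gibbs dividing surface position
#'
#' Locates the plane separating the dense phase from the dilute one: the z
#' where the species density first decays through half its bulk value,
#' scanning in +z from the bulk region and interpolating linearly between
#' bins.  The bulk reference is the mean density over the densest
#' contiguous 20% of bins.
#'
#' @param profile A `density_profile`.
#' @param species Species column to use (may be omitted for single-species
#'   profiles).
#' @return z position of the dividing surface, nm, with attributes `bulk`
#'   (reference density) and `multiple` (`TRUE` if the density re-crosses
#'   the half-bulk level further out, in which case the first crossing is
#'   returned).
#' @export
gibbs_dividing_surface <- function(profile, species = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  d <- profile_species_column(profile, species)
  z <- profile$z_centers
  bk <- bulk_density(z, d)
  cr <- first_crossing(z, d, bk$bulk / 2, from = bk$start)
  if (is.null(cr)) {
    stop("no decay through half the bulk density found along +z",
         call. = FALSE)
  }
  structure(cr$z, bulk = bk$bulk, multiple = cr$multiple)
}

#' Interfacial region width
#'
#' Bounds the interfacial region by the 10% and 90% bulk-density crossing
#' positions of the decaying profile and reports their separation
#' \eqn{\Delta z^*} (the 10-90 width).  This operational definition is a
#' convention of this package; interfacial widths in the literature are
#' often read off plots.  The crossings are located scanning from the
#' dilute side (last downward crossing), since statistical fluctuations
#' inside the bulk plateau can graze the 90% level but the tail cannot
#' reach it.
#'
#' @inheritParams gibbs_dividing_surface
#' @return Named numeric vector `c(z_low, z_high, delta_z_star)`, nm:
#'   `z_low` is the 90%-of-bulk crossing (dense side), `z_high` the
#'   10%-of-bulk crossing (dilute side).
#' @export
interface_region <- function(profile, species = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  d <- profile_species_column(profile, species)
  z <- profile$z_centers
  bk <- bulk_density(z, d)
  hi <- last_crossing(z, d, 0.9 * bk$bulk, from = bk$start)
  lo <- last_crossing(z, d, 0.1 * bk$bulk, from = bk$start)
  if (is.null(hi) || is.null(lo)) {
    stop("profile does not decay through the 10-90% bulk levels",
         call. = FALSE)
  }
  c(z_low = hi$z, z_high = lo$z, delta_z_star = lo$z - hi$z)
}

#' Tabulated pressure-tensor profile
#'
#' Stores the normal and tangential components of the pressure tensor along
#' z, the inputs of the mechanical (pressure-tensor) route to the surface
#' tension.  Units are chosen so the tension integral needs no conversion:
#' z in nm, pressures in MPa, hence `MPa * nm = mN/m`.
#'
#' @param z Strictly increasing positions, nm.
#' @param p_normal,p_tangential Pressure components, MPa.
#' @param bounds Integration limits `c(-L_b, L_a)`, nm; default the full
#'   tabulated range.
#' @return An object of class `pressure_profile`.
#' @export
pressure_profile <- function(z, p_normal, p_tangential, bounds = range(z)) {
  z <- as.numeric(z)
  stopifnot(length(z) >= 2, all(diff(z) > 0),
            length(p_normal) == length(z),
            length(p_tangential) == length(z), length(bounds) == 2)
  if (bounds[1] < min(z) || bounds[2] > max(z) || bounds[1] >= bounds[2]) {
    stop("bounds must lie within the tabulated z range", call. = FALSE)
  }
  structure(
    list(z = z, p_normal = as.numeric(p_normal),
         p_tangential = as.numeric(p_tangential), bounds = bounds),
    class = "pressure_profile"
  )
}

#' Surface tension from a pressure-tensor profile
#'
#' Mechanical route to the interfacial tension of a planar system:
#' \deqn{\gamma = \int_{-L_b}^{L_a} \left[p_N(z) - p_T(z)\right] dz,}
#' evaluated by the trapezoidal rule over the profile bounds (with linear
#' interpolation at the bound endpoints).  With z in nm and pressures in
#' MPa the result is in mN/m with no unit factor.
#'
#' @param profile A `pressure_profile`.
#' @param bounds Optional integration limits overriding the profile's.
#' @return Surface tension, mN/m.
#' @export
surface_tension <- function(profile, bounds = NULL) {
  stopifnot(inherits(profile, "pressure_profile"))
  bounds <- bounds %||% profile$bounds
  integrand <- profile$p_normal - profile$p_tangential
  if (any(is.na(integrand))) stop("NaN in p_N - p_T", call. = FALSE)
  z <- profile$z
  keep <- z > bounds[1] & z < bounds[2]
  zi <- c(bounds[1], z[keep], bounds[2])
  fi <- c(stats::approx(z, integrand, xout = bounds[1])$y,
          integrand[keep],
          stats::approx(z, integrand, xout = bounds[2])$y)
  pracma::trapz(zi, fi)
}

#' Interface summary
#'
#' Bundles the interfacial observables of one slab system: the Gibbs
#' dividing surface, the 10-90 interfacial width, the pressure-tensor
#' surface tension and the surface pressure relative to a bare-interface
#' reference, `pi = gamma0 - gamma`.
#'
#' @param profile A `density_profile` for the dense phase species.
#' @param pressure A `pressure_profile`.
#' @param gamma0 Bare-interface surface tension, mN/m (default 72.8, water
#'   at room temperature).
#' @param species Species column of `profile` to use.
#' @return An object of class `interface_summary`: list with `z_gds`,
#'   `delta_z_star`, `gamma`, `gamma0`, `pi`.
#' @export
interface_summary <- function(profile, pressure, gamma0 = 72.8,
                              species = NULL) {
  gds <- gibbs_dividing_surface(profile, species)
  reg <- interface_region(profile, species)
  gamma <- surface_tension(pressure)
  structure(
    list(z_gds = as.numeric(gds), delta_z_star = unname(reg["delta_z_star"]),
         gamma = gamma, gamma0 = gamma0,
         pi = surface_pressure_from_tension(gamma0, gamma)),
    class = "interface_summary"
  )
}

#' @export
print.interface_summary <- function(x, ...) {
  cat(sprintf(
    "<interface_summary> GDS %.3f nm, dz* %.3f nm, gamma %.2f mN/m, pi %.2f mN/m\n",
    x$z_gds, x$delta_z_star, x$gamma, x$pi))
  invisible(x)
}
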