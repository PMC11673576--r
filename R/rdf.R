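#' Radial distribution function
#'
#' Computes the pair correlation function g(r) between two species in an
#' orthorhombic periodic box using the minimum-image convention: a
#' pair-distance histogram (each unordered pair counted once, self pairs
#' excluded) normalised, frame by frame, by the ideal-gas expectation for
#' the same pair count in each spherical shell (exact shell volumes
#' \eqn{\frac{4}{3}\pi (r_2^3 - r_1^3)} are used).
#'
#' @param configs A `particle_configuration` or list of frames with the
#'   same box.
#' @param species_a,species_b Species labels of the pair (may be equal).
#' @param bin_width Histogram bin width, nm.
#' @param r_max Histogram range, nm; must not exceed half the smallest box
#'   length (minimum-image validity).
#' @return An object of class `radial_distribution`: list with `r_centers`
#'   (nm), `g`, `pair`, `counts` (mean pair counts per bin per frame),
#'   `pmf` (`NULL` until [pmf_from_g()] is applied), `temperature`.
#' @export
radial_distribution <- function(configs, species_a, species_b,
                                bin_width = 0.05, r_max = NULL) {
  configs <- as_config_list(configs)
  box <- configs[[1]]$box
  half <- min(box) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-12) {
    stop(sprintf("r_max = %g nm exceeds half the smallest box length (%g nm)",
                 r_max, half), call. = FALSE)
  }
  if (bin_width <= 0 || bin_width > r_max) {
    stop("bin_width must lie in (0, r_max]", call. = FALSE)
  }
  nbins <- as.integer(floor(r_max / bin_width + 1e-9))
  edges <- (0:nbins) * bin_width
  shell <- 4 / 3 * pi * diff(edges^3)
  V <- prod(box)
  same <- identical(species_a, species_b)
  counts <- numeric(nbins)
  npairs <- NULL
  for (cf in configs) {
    pa <- cf$positions[cf$species == species_a, , drop = FALSE]
    pb <- cf$positions[cf$species == species_b, , drop = FALSE]
    if (nrow(pa) == 0L || nrow(pb) == 0L) {
      stop("a species has no particles in some frame", call. = FALSE)
    }
    np <- if (same) nrow(pa) * (nrow(pa) - 1) / 2 else nrow(pa) * nrow(pb)
    npairs <- npairs %||% np
    counts <- counts + pair_histogram(pa, pb, box, bin_width, nbins, same)
  }
  counts <- counts / length(configs)
  expected <- npairs * shell / V
  structure(
    list(r_centers = edges[-1] - bin_width / 2, g = counts / expected,
         pair = c(species_a, species_b), counts = counts,
         n_pairs = npairs, bin_width = bin_width, box = box,
         n_frames = length(configs), pmf = NULL, temperature = NA_real_),
    class = "radial_distribution"
  )
}

#' @export
print.radial_distribution <- function(x, ...) {
  cat(sprintf(
    "<radial_distribution> %s-%s, %d bins of %.3g nm over %d frame(s)%s\n",
    x$pair[1], x$pair[2], length(x$g), x$bin_width, x$n_frames,
    if (is.null(x$pmf)) "" else ", PMF attached"))
  invisible(x)
}

#' Potential of mean force from g(r)
#'
#' Inverts the equilibrium relation between the pair correlation function
#' and the pair free energy, \eqn{U(r) = -k_B T \ln g(r)}, reported in
#' units of \eqn{k_B T} (so numerically `-log(g)`).  Bins with `g = 0` get
#' a `+Inf` sentinel and are excluded from downstream extremum searches.
#'
#' @param rdf A `radial_distribution`.
#' @param temperature Temperature in K recorded alongside the PMF
#'   (default 300).
#' @return The `radial_distribution` with `pmf` (in kT) and `temperature`
#'   filled in.
#' @export
pmf_from_g <- function(rdf, temperature = 300) {
  stopifnot(inherits(rdf, "radial_distribution"))
  pmf <- ifelse(rdf$g > 0, -log(rdf$g), Inf)
  rdf$pmf <- pmf
  rdf$temperature <- temperature
  rdf
}

#' First peak of g(r)
#'
#' Position of the first local maximum of g(r) whose height reaches
#' `1 + prominence` above the uncorrelated baseline; the contact distance
#' of the pair.  Returns `NA` with attribute `no_peak = TRUE` when no such
#' maximum exists (e.g. an uncorrelated gas).
#'
#' @param rdf A `radial_distribution`.
#' @param prominence Minimum height above the g = 1 baseline (default 0.1).
#' @return Peak position in nm (bin center), or `NA`.
#' @export
first_peak <- function(rdf, prominence = 0.1) {
  stopifnot(inherits(rdf, "radial_distribution"))
  g <- rdf$g
  n <- length(g)
  for (i in 2:(n - 1)) {
    if (g[i] >= 1 + prominence && g[i] >= g[i - 1] && g[i] >= g[i + 1] &&
        (g[i] > g[i - 1] || g[i] > g[i + 1])) {
      return(rdf$r_centers[i])
    }
  }
  structure(NA_real_, no_peak = TRUE)
}
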