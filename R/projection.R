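#' Feature matrix from a family of curves
#'
#' Resamples each curve onto a common surface-pressure grid so that whole
#' isotherms (feature: area at pressure) or whole modulus curves (feature:
#' \eqn{C_S^{-1}} at pressure) become fixed-length vectors that can be
#' compared by Euclidean distance.  The conventional comparison window for
#' monolayer work is 0 to 35 mN/m.
#'
#' @param curves A named list of [isotherm_curve()] or `modulus_curve`
#'   objects (names become item labels; unnamed lists are labelled from the
#'   curve metadata or by index).
#' @param pi_lo,pi_hi Pressure window, mN/m (defaults 0 and 35).
#' @param n_points Number of uniform grid points across the window
#'   (default 351, i.e. 0.1 mN/m spacing over 0-35).
#' @param window Adjacent-average smoothing window applied to isotherm
#'   pressures before interpolation (default 10; ignored for precomputed
#'   modulus curves).
#' @return An object of class `curve_feature_matrix`: list with `features`
#'   (matrix, one row per curve), `grid` (pressures), `items` (labels) and
#'   `source_kind` (`"isotherm"` or `"modulus"`).
#' @export
build_feature_matrix <- function(curves, pi_lo = 0, pi_hi = 35,
                                 n_points = 351, window = 10) {
  stopifnot(is.list(curves), length(curves) >= 1, pi_hi > pi_lo,
            n_points >= 2)
  items <- names(curves)
  if (is.null(items) || any(!nzchar(items))) {
    items <- vapply(seq_along(curves), function(i) {
      crv <- curves[[i]]
      if (inherits(crv, "isotherm_curve") && nzchar(crv$model_id)) {
        sprintf("%s_c%g_r%s", crv$model_id, crv$scx4_conc, crv$replicate)
      } else {
        sprintf("curve_%d", i)
      }
    }, character(1))
  }
  grid <- seq(pi_lo, pi_hi, length.out = n_points)
  kinds <- vapply(curves, function(crv) {
    if (inherits(crv, "isotherm_curve")) "isotherm"
    else if (inherits(crv, "modulus_curve")) "modulus"
    else stop("curves must be isotherm_curve or modulus_curve objects",
              call. = FALSE)
  }, character(1))
  if (length(unique(kinds)) != 1L) {
    stop("mixed curve kinds in one feature matrix", call. = FALSE)
  }
  feats <- matrix(NA_real_, nrow = length(curves), ncol = n_points,
                  dimnames = list(items, NULL))
  for (i in seq_along(curves)) {
    crv <- curves[[i]]
    if (kinds[1] == "isotherm") {
      m <- compressional_modulus(crv, window = window)
      br <- compression_branch(m)
      px <- br$pressure
      val <- br$area
    } else {
      br <- compression_branch(crv)
      px <- br$pressure
      val <- br$modulus
    }
    if (max(px) < pi_hi || min(px) > pi_lo) {
      stop(sprintf(
        "curve '%s' spans [%.3g, %.3g] mN/m and does not cover the window [%g, %g]",
        items[i], min(px), max(px), pi_lo, pi_hi), call. = FALSE)
    }
    feats[i, ] <- stats::approx(px, val, xout = grid, ties = mean)$y
  }
  structure(list(features = feats, grid = grid, items = items,
                 source_kind = unname(kinds[1])),
            class = "curve_feature_matrix")
}

#' Pairwise Euclidean distance matrix
#'
#' Standard L2 distances between the rows of a feature matrix, with the
#' off-diagonal extremes \eqn{\delta_{min}} and \eqn{\delta_{max}} recorded
#' for the min-max normalisation used by the projection stress.
#'
#' @param X A `curve_feature_matrix` or a plain numeric matrix
#'   (rows = items).
#' @return An object of class `distance_matrix`: list with `d` (symmetric
#'   matrix, zero diagonal), `delta_min`, `delta_max`, `items`.
#' @export
euclidean_distance_matrix <- function(X) {
  M <- if (inherits(X, "curve_feature_matrix")) X$features else as.matrix(X)
  if (nrow(M) < 2L) stop("need at least 2 items", call. = FALSE)
  if (any(!is.finite(M))) stop("non-finite feature values", call. = FALSE)
  d <- as.matrix(stats::dist(M))
  off <- d[upper.tri(d)]
  structure(list(d = d, delta_min = min(off), delta_max = max(off),
                 items = rownames(M) %||% as.character(seq_len(nrow(M)))),
            class = "distance_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_dist_matrix <- function(D) {
  if (inherits(D, "distance_matrix")) return(D$d)
  as.matrix(D)
}

#' Fastmap embedding of a distance matrix
#'
#' Classic Fastmap: for each axis a far-apart pivot pair is chosen by a
#' deterministic farthest-point heuristic (two sweeps starting from the
#' first item, ties broken by lowest index), every item gets the cosine-law
#' coordinate
#' \deqn{x_i = \frac{d(a,i)^2 + d(a,b)^2 - d(b,i)^2}{2\,d(a,b)},}
#' and the procedure recurses on the residual distances
#' \eqn{d'^2 = d^2 - (x_i - x_j)^2}.  Degenerate axes (all residual
#' distances zero) yield zero coordinates.
#'
#' @param D A `distance_matrix` or symmetric numeric matrix.
#' @param dims Number of output dimensions (default 2).
#' @return Numeric matrix (items x dims).
#' @export
fastmap_embed <- function(D, dims = 2) {
  d <- as_dist_matrix(D)
  n <- nrow(d)
  Y <- matrix(0, n, dims)
  d2 <- d^2
  for (k in seq_len(dims)) {
    a <- which.max(d2[1, ])
    b <- which.max(d2[a, ])
    dab2 <- d2[a, b]
    if (dab2 <= 0) break # all remaining distances zero
    dab <- sqrt(dab2)
    x <- (d2[a, ] + dab2 - d2[b, ]) / (2 * dab)
    Y[, k] <- x
    d2 <- d2 - outer(x, x, "-")^2
    d2[d2 < 0] <- 0 # numerical guard: residuals are distances squared
  }
  rownames(Y) <- if (inherits(D, "distance_matrix")) D$items else rownames(d)
  Y
}

normalized_delta <- function(D) {
  stopifnot(inherits(D, "distance_matrix"))
  rng <- D$delta_max - D$delta_min
  if (rng <= 0) {
    dn <- D$d * 0
  } else {
    dn <- (D$d - D$delta_min) / rng
    diag(dn) <- 0
  }
  dn
}

#' Projection stress (IDMAP objective)
#'
#' The objective minimised by the projection: the sum over unordered item
#' pairs of the squared difference between the min-max-normalised
#' original-space distance and the (unnormalised) projected-plane distance,
#' \deqn{\sum_{i<j} \left[\frac{\delta(x_i,x_j) - \delta_{min}}
#'   {\delta_{max} - \delta_{min}} - d(y_i, y_j)\right]^2.}
#' When \eqn{\delta_{max} = \delta_{min}} all normalised distances are
#' defined as 0.
#'
#' @param D A `distance_matrix`.
#' @param Y Numeric matrix of 2D coordinates (items x 2).
#' @return Nonnegative scalar stress.
#' @export
idmap_stress <- function(D, Y) {
  dn <- normalized_delta(D)
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(dn))
  dy <- as.matrix(stats::dist(Y))
  sum(((dn - dy)[upper.tri(dn)])^2)
}

idmap_gradient <- function(dn, Y) {
  dy <- as.matrix(stats::dist(Y))
  w <- dn - dy
  inv <- ifelse(dy > 0, 1 / dy, 0)
  f <- -2 * w * inv # factor multiplying (y_i - y_j)
  G <- matrix(0, nrow(Y), ncol(Y))
  for (k in seq_len(ncol(Y))) {
    diffk <- outer(Y[, k], Y[, k], "-")
    G[, k] <- rowSums(f * diffk)
  }
  G
}

#' Project items to the plane by stress minimisation
#'
#' Embeds the items of a distance matrix in 2D by minimising
#' [idmap_stress()]: coordinates are initialised with [fastmap_embed()] on
#' the min-max-normalised distances, then refined by gradient descent with
#' a backtracking (Armijo) line search, which guarantees a non-increasing
#' stress trace.  The run is fully deterministic; `seed` is recorded in the
#' result for provenance (no randomness is consumed unless ties were broken
#' randomly, which this implementation never does).
#'
#' @param D A `distance_matrix`.
#' @param max_iter Maximum number of descent iterations (default 500).
#' @param tol Relative stress-change stopping tolerance (default 1e-10).
#' @param seed Integer recorded in the output (default 1).
#' @return An object of class `projection_2d`: list with `coords` (items x
#'   2), `stress`, `stress_normalized` (stress divided by the sum of
#'   squared normalised distances), `trace` (stress per iteration, starting
#'   at the initial configuration), `seed`, `n_iter`, `converged`, `items`.
#' @export
idmap_project <- function(D, max_iter = 500, tol = 1e-10, seed = 1L) {
  stopifnot(inherits(D, "distance_matrix"))
  dn <- normalized_delta(D)
  Dn <- structure(list(d = dn, delta_min = 0, delta_max = max(dn),
                       items = D$items), class = "distance_matrix")
  Y <- fastmap_embed(Dn, dims = 2)
  denom <- sum(dn[upper.tri(dn)]^2)
  S <- idmap_stress(D, Y)
  trace <- S
  step <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    G <- idmap_gradient(dn, Y)
    g2 <- sum(G^2)
    if (g2 == 0) { converged <- TRUE; trace <- c(trace, S); break }
    step <- step * 2 # allow the step to grow again after cautious iterations
    accepted <- FALSE
    for (bt in 1:60) {
      Ynew <- Y - step * G
      Snew <- idmap_stress(D, Ynew)
      if (!is.finite(Snew)) {
        stop(sprintf("non-finite stress at iteration %d", iter),
             call. = FALSE)
      }
      if (Snew <= S - 1e-4 * step * g2) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { trace <- c(trace, S); converged <- TRUE; break }
    rel <- (S - Snew) / max(S, .Machine$double.eps)
    Y <- Ynew
    S <- Snew
    trace <- c(trace, S)
    if (rel < tol) { converged <- TRUE; break }
  }
  structure(
    list(coords = Y, stress = S,
         stress_normalized = if (denom > 0) S / denom else 0,
         trace = trace, seed = seed, n_iter = iter, converged = converged,
         items = D$items),
    class = "projection_2d"
  )
}

#' @export
print.projection_2d <- function(x, ...) {
  cat(sprintf(
    "<projection_2d> %d items, stress %.3g (normalized %.3g), %d iterations%s\n",
    nrow(x$coords), x$stress, x$stress_normalized, x$n_iter,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
plot.projection_2d <- function(x, labels = NULL, ...) {
  graphics::plot(x$coords[, 1], x$coords[, 2], xlab = "y1", ylab = "y2",
                 pch = 19,
                 col = if (is.null(labels)) 1 else as.factor(labels), ...)
  invisible(x)
}

#' Mean silhouette coefficient
#'
#' Projection-quality score in \eqn{[-1, 1]}: for each item, `a` is its mean
#' distance to the other members of its own group and `b` the smallest mean
#' distance to any other group; the silhouette is the mean of
#' \eqn{(b - a)/\max(a, b)}.  Items in singleton groups contribute 0.
#' Computed here on the projected 2D coordinates (it scores the map, not
#' the raw features).
#'
#' @param x A `projection_2d`, a coordinate matrix, or a `distance_matrix`.
#' @param labels Group label per item (at least two distinct values).
#' @return Mean silhouette (scalar), with per-item widths in attribute
#'   `widths`.
#' @export
silhouette_score <- function(x, labels) {
  d <- if (inherits(x, "projection_2d")) {
    as.matrix(stats::dist(x$coords))
  } else if (inherits(x, "distance_matrix")) {
    x$d
  } else {
    as.matrix(stats::dist(as.matrix(x)))
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(d))
  if (length(unique(labels)) < 2L) {
    stop("silhouette needs at least two distinct labels", call. = FALSE)
  }
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (length(own) == 0L) { s[i] <- 0; next } # singleton convention
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    m <- max(a, b)
    s[i] <- if (m > 0) (b - a) / m else 0
  }
  structure(mean(s), widths = s)
}

#' Relative separation of labelled groups on a map
#'
#' Centroid-to-centroid Euclidean distances between labelled groups on the
#' projected plane, normalised so that a declared reference pair has
#' distance 1.  Only relative distances are meaningful on a stress-minimised
#' map (the plane has no absolute scale).
#'
#' @param Y A `projection_2d` or coordinate matrix.
#' @param labels Group label per item; every group must be non-empty.
#' @param reference_pair Character vector of two group labels whose centroid
#'   distance defines the unit.
#' @return An object of class `group_separation_report`: list with
#'   `silhouette`, `relative_distances` (symmetric matrix), `reference_pair`
#'   and `reference_distance` (the raw unit, in map coordinates).
#' @export
group_distance_report <- function(Y, labels, reference_pair) {
  coords <- if (inherits(Y, "projection_2d")) Y$coords else as.matrix(Y)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(coords), length(reference_pair) == 2)
  groups <- unique(labels)
  if (!all(reference_pair %in% groups)) {
    stop("reference_pair must name existing groups", call. = FALSE)
  }
  cent <- t(vapply(groups, function(g) {
    colMeans(coords[labels == g, , drop = FALSE])
  }, numeric(ncol(coords))))
  d <- as.matrix(stats::dist(cent))
  dimnames(d) <- list(groups, groups)
  ref <- d[reference_pair[1], reference_pair[2]]
  if (ref == 0) stop("reference pair has zero centroid distance",
                     call. = FALSE)
  structure(
    list(silhouette = as.numeric(silhouette_score(coords, labels)),
         relative_distances = d / ref, reference_pair = reference_pair,
         reference_distance = ref),
    class = "group_separation_report"
  )
}

#' @export
print.group_separation_report <- function(x, ...) {
  cat(sprintf(
    "<group_separation_report> silhouette %.3f, unit = d(%s, %s)\n",
    x$silhouette, x$reference_pair[1], x$reference_pair[2]))
  print(round(x$relative_distances, 3))
  invisible(x)
}
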