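test_that("feature matrices resample curves onto the pressure window", {
  crv <- volmer_curve(pi_collapse = 52.7, area_min = 41, by = 0.1)
  X <- build_feature_matrix(list(a = crv, b = crv), window = 1)
  expect_equal(dim(X$features), c(2L, 351L))
  expect_equal(X$grid[1], 0)
  expect_equal(X$grid[351], 35)
  expect_equal(X$features[1, ], X$features[2, ])
  D <- euclidean_distance_matrix(X)
  expect_equal(D$d[1, 2], 0)
})

test_that("curves not spanning the window are reported by name", {
  short <- volmer_curve(pi_collapse = 30, area_min = 41, by = 0.1)
  full <- volmer_curve(pi_collapse = 52.7, area_min = 41, by = 0.1)
  expect_error(
    build_feature_matrix(list(ok = full, short_one = short), window = 1),
    "short_one")
})

test_that("modulus curves can be projected too", {
  curves <- lapply(c(33, 35), function(ae) {
    volmer_curve(a_exc = ae, pi_collapse = 52.7, area_min = ae + 8,
                 by = 0.1)
  })
  mods <- lapply(curves, compressional_modulus, window = 1)
  names(mods) <- c("a", "b")
  X <- build_feature_matrix(mods, pi_hi = 35)
  expect_identical(X$source_kind, "modulus")
  expect_true(all(is.finite(X$features)))
})

test_that("Euclidean distances have the textbook values and extremes", {
  D <- euclidean_distance_matrix(rbind(c(0, 0), c(3, 4)))
  expect_equal(D$d[1, 2], 5)
  expect_equal(D$d[2, 1], 5)
  expect_equal(unname(diag(D$d)), c(0, 0))
  # three collinear rows at coordinates 0, 1, 3
  D3 <- euclidean_distance_matrix(cbind(c(0, 1, 3)))
  expect_equal(D3$delta_min, 1)
  expect_equal(D3$delta_max, 3)
  expect_error(euclidean_distance_matrix(rbind(c(1, 2))), "2 items")
})

test_that("Fastmap reproduces embeddable distance sets", {
  # two points at distance d
  d2 <- matrix(c(0, 7, 7, 0), 2)
  Y <- fastmap_embed(d2)
  expect_equal(dist(Y)[1], 7)
  # unit square: embedded distances reproduce the input
  sq <- as.matrix(dist(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
  Y <- fastmap_embed(sq)
  expect_equal(as.matrix(dist(Y)), sq, ignore_attr = TRUE,
               tolerance = 1e-9)
  # all-identical items map to the origin
  Z <- fastmap_embed(matrix(0, 5, 5))
  expect_equal(Z, matrix(0, 5, 2), ignore_attr = TRUE)
})

test_that("the stress is zero iff projected distances match normalised ones", {
  P <- planar_points_embeddable(6, seed = 3)
  D <- euclidean_distance_matrix(P)
  # scaling the configuration by 1/delta_max realises the normalised
  # distances exactly (delta_min = 0 by construction)
  expect_equal(idmap_stress(D, P / D$delta_max), 0, tolerance = 1e-20)
  # hand-computed value: collinear items at 0, 1, 3 have normalised
  # distances 0, 0.5, 1; projecting everything onto one point leaves
  # 0^2 + 0.5^2 + 1^2
  D3 <- euclidean_distance_matrix(cbind(c(0, 1, 3), c(0, 0, 0)))
  expect_equal(idmap_stress(D3, matrix(0, 3, 2)), 1.25)
  # a lone pair is degenerate (delta_min = delta_max): normalised
  # distances are defined as 0, so coincident points are already optimal
  D2 <- euclidean_distance_matrix(rbind(c(0, 0), c(2, 0)))
  expect_equal(idmap_stress(D2, matrix(0, 2, 2)), 0)
  # stress is nonnegative for arbitrary configurations
  set.seed(9)
  expect_gte(idmap_stress(D, matrix(rnorm(12), 6, 2)), 0)
})

test_that("projection recovers exactly embeddable distance sets", {
  for (s in 1:4) {
    P <- planar_points_embeddable(8, seed = s)
    D <- euclidean_distance_matrix(P)
    pr <- idmap_project(D)
    expect_lt(pr$stress_normalized, 1e-6)
    expect_true(all(diff(pr$trace) <= 1e-12))
  }
})

test_that("projection is deterministic and initialisation is useful", {
  curves <- generate_condition_set(replicates = 1, seed = 5)
  D <- euclidean_distance_matrix(build_feature_matrix(curves))
  p1 <- idmap_project(D, max_iter = 50)
  p2 <- idmap_project(D, max_iter = 50)
  expect_identical(p1$coords, p2$coords)
  # Fastmap start beats the all-zero configuration
  Y0 <- matrix(0, nrow(D$d), 2)
  Yf <- fastmap_embed(
    structure(list(d = (D$d - D$delta_min) / (D$delta_max - D$delta_min) *
                     (upper.tri(D$d) | lower.tri(D$d)),
                   delta_min = 0, delta_max = 1, items = D$items),
              class = "distance_matrix"))
  expect_lt(idmap_stress(D, Yf), idmap_stress(D, Y0))
})

test_that("stress is invariant under rotation and translation of the map", {
  P <- planar_points_embeddable(7, seed = 11)
  D <- euclidean_distance_matrix(P)
  pr <- idmap_project(D, max_iter = 100)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Yrot <- sweep(pr$coords %*% R, 2, c(3, -2), "+")
  expect_equal(idmap_stress(D, Yrot), pr$stress, tolerance = 1e-10)
})

test_that("silhouette follows its definition and the cluster package", {
  # two tight clusters far apart
  set.seed(2)
  Y <- rbind(matrix(rnorm(20, 0, 0.01), 10),
             matrix(rnorm(20, 50, 0.01), 10))
  labs <- rep(c("a", "b"), each = 10)
  expect_gt(as.numeric(silhouette_score(Y, labs)), 0.99)
  expect_error(silhouette_score(Y, rep("a", 20)), "two distinct")
  # singleton groups contribute zero
  Y3 <- rbind(c(0, 0), c(0.1, 0), c(9, 9))
  s <- silhouette_score(Y3, c("a", "a", "b"))
  expect_equal(attr(s, "widths")[3], 0)
  # cross-check the non-singleton case against cluster::silhouette
  set.seed(4)
  Yc <- matrix(rnorm(60), 30, 2)
  labsc <- rep(1:3, each = 10)
  ours <- as.numeric(silhouette_score(Yc, labsc))
  ref <- mean(cluster::silhouette(labsc, dist(Yc))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("group distances are reported relative to the reference pair", {
  # clusters centred at x = 0, 1, 2, 4 -> ratios 1, 2, 4 to the first pair
  set.seed(6)
  mk <- function(cx) cbind(rnorm(40, cx, 0.005), rnorm(40, 0, 0.005))
  Y <- rbind(mk(0), mk(1), mk(2), mk(4))
  labs <- rep(c("g0", "g1", "g2", "g4"), each = 40)
  rep_ <- group_distance_report(Y, labs, c("g0", "g1"))
  expect_equal(rep_$relative_distances["g0", "g1"], 1)
  expect_equal(rep_$relative_distances["g0", "g2"], 2, tolerance = 0.01)
  expect_equal(rep_$relative_distances["g0", "g4"], 4, tolerance = 0.01)
  expect_equal(diag(rep_$relative_distances), c(0, 0, 0, 0),
               ignore_attr = TRUE)
  # coincident reference centroids are an error
  pts <- mk(0)
  Yd <- rbind(pts, pts) # the two groups share every point exactly
  expect_error(
    group_distance_report(Yd, rep(c("a", "b"), each = 40), c("a", "b")),
    "zero")
})
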