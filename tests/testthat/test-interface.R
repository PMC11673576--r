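test_that("density profiles conserve particle counts exactly", {
  cfg <- generate_gas_config(8000, profile = "uniform", seed = 1)
  prof <- density_profile(cfg, bin_width = 0.1)
  vol <- prof$box[1] * prof$box[2] * prof$bin_width
  expect_equal(sum(prof$density[, "A"]) * vol, 8000)
  expect_identical(sum(prof$counts), 8000)
  # every bin of a uniform gas within 4 Poisson standard deviations
  expected <- 8000 / nrow(prof$density)
  expect_true(all(abs(prof$counts - expected) < 4 * sqrt(expected)))
})

test_that("a slab leaves the empty region at exactly zero density", {
  cfg <- generate_gas_config(4000, profile = "step", midpoint = 10,
                             seed = 2)
  prof <- density_profile(cfg, bin_width = 0.1)
  expect_true(all(prof$density[prof$z_centers > 10.05, "A"] == 0))
})

test_that("density profiles reject unusable bin widths", {
  cfg <- generate_gas_config(100, seed = 3)
  expect_error(density_profile(cfg, bin_width = 0), "bin_width")
  expect_error(density_profile(cfg, bin_width = 30), "bin_width")
})

test_that("the dividing surface sits at the half-bulk crossing", {
  z <- seq(0.05, 9.95, by = 0.1)
  # sharp step at 3.6 nm
  step <- density_profile_from_values(z, ifelse(z < 3.6, 2, 0))
  expect_equal(as.numeric(gibbs_dividing_surface(step)), 3.6,
               tolerance = 1e-9)
  # linear ramp from bulk to zero over [2, 4]: midpoint 3
  ramp <- density_profile_from_values(z, pmin(pmax((4 - z) / 2, 0), 1))
  expect_equal(as.numeric(gibbs_dividing_surface(ramp)), 3,
               tolerance = 1e-9)
  # noisy sigmoid with midpoint 3.6: recovered within one bin width
  set.seed(8)
  sig <- stats::pnorm((3.6 - z) / 0.3)
  noisy <- density_profile_from_values(z, pmax(sig + rnorm(length(z),
                                                           0, 0.05), 0))
  expect_equal(as.numeric(gibbs_dividing_surface(noisy)), 3.6,
               tolerance = 0.1)
  # a profile with no decay is an error
  flat <- density_profile_from_values(z, rep(1, length(z)))
  expect_error(gibbs_dividing_surface(flat), "decay")
})

test_that("the interfacial width follows the 10-90 rule", {
  z <- seq(0.05, 9.95, by = 0.1)
  step <- density_profile_from_values(z, ifelse(z < 3.6, 2, 0))
  expect_lte(interface_region(step)["delta_z_star"], 0.1)
  # linear ramp of width w: 10-90 width is 0.8 w
  ramp <- density_profile_from_values(z, pmin(pmax((4 - z) / 2, 0), 1))
  expect_equal(unname(interface_region(ramp)["delta_z_star"]), 1.6,
               tolerance = 1e-9)
  # error-function profile of scale s: width 2.563 s (normal quantiles)
  s <- 0.5
  erfp <- density_profile_from_values(z, stats::pnorm((5 - z) / s))
  expect_equal(unname(interface_region(erfp)["delta_z_star"]),
               2 * stats::qnorm(0.9) * s, tolerance = 0.02 * 2.563 * s)
})

test_that("dividing surface and width are shift-equivariant", {
  z <- seq(0.05, 19.95, by = 0.1)
  d <- stats::pnorm((4 - z) / 0.4)
  p1 <- density_profile_from_values(z, d)
  p2 <- density_profile_from_values(z + 2.5, d) # rigid translation
  expect_equal(as.numeric(gibbs_dividing_surface(p2)),
               as.numeric(gibbs_dividing_surface(p1)) + 2.5,
               tolerance = 1e-12)
  expect_equal(interface_region(p2)[["delta_z_star"]],
               interface_region(p1)[["delta_z_star"]], tolerance = 1e-12)
})

test_that("surface tension integrates the pressure anisotropy", {
  z <- seq(-10, 10, by = 0.05)
  # isotropic bulk: exactly zero
  iso <- pressure_profile(z, rep(3, length(z)), rep(3, length(z)))
  expect_identical(surface_tension(iso), 0)
  # rectangular anisotropy of height 1 MPa over 2 nm
  rect <- generate_pressure_profile(2, "rect", z = z, width = 2)
  expect_equal(surface_tension(rect), 2, tolerance = 1e-12)
  # Gaussian anisotropy, amplitude 1, sigma 1: integral sqrt(2*pi)
  gauss <- generate_pressure_profile(sqrt(2 * pi), "gauss", z = z,
                                     width = 1)
  expect_equal(surface_tension(gauss), sqrt(2 * pi),
               tolerance = 1e-3 * sqrt(2 * pi))
  # linearity: scaling the anisotropy scales gamma to machine precision
  tripled <- pressure_profile(z, 3 * gauss$p_normal,
                              3 * gauss$p_tangential)
  expect_equal(surface_tension(tripled), 3 * surface_tension(gauss),
               tolerance = 1e-14)
  # restricting the bounds drops tail mass only
  expect_lt(surface_tension(gauss, bounds = c(-1, 1)),
            surface_tension(gauss))
  expect_error(pressure_profile(z, z, z, bounds = c(-50, 50)), "bounds")
})

test_that("interface summaries tie pi to the tension deficit", {
  cfg <- generate_gas_config(4000, profile = "sigmoid", midpoint = 10,
                             width = 0.5, species = "W", seed = 4)
  prof <- density_profile(cfg, bin_width = 0.1)
  pp <- generate_pressure_profile(42.8, "gauss", width = 1)
  summ <- interface_summary(prof, pp, gamma0 = 72.8, species = "W")
  expect_equal(summ$pi, summ$gamma0 - summ$gamma)
  expect_equal(summ$pi, 30, tolerance = 0.05)
  expect_gte(summ$delta_z_star, 0)
  expect_equal(summ$z_gds, 10, tolerance = 0.15)
})
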