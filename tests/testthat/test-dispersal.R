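uniform_field <- function(u = 0.1, v = 0, days = 12, ...) {
  simulate_current_field("uniform", lon_range = c(-2, 8), lat_range = c(-4, 4),
                         res = 0.25, days = days, params = list(u = u, v = v),
                         ...)
}

test_that("velocity interpolation is exact at nodes and bilinear in cells", {
  fld <- simulate_current_field("uniform", res = 0.5, days = 3,
                                params = list(u = 0.07, v = -0.03))
  at_node <- interp_velocity(fld, 1, fld$lon[3], fld$lat[4])
  expect_equal(unname(at_node[1, ]), c(0.07, -0.03))
  # single corner active in u: cell-centre value is the 1/4 weight
  fld$u[, , ] <- 0
  fld$u[3, 4, ] <- 1
  centre <- interp_velocity(fld, 0,
                            mean(fld$lon[3:4]), mean(fld$lat[4:5]))
  expect_equal(unname(centre[1, "u"]), 0.25)
  # bilinear interpolation is exact for a plane
  plane <- simulate_current_field("solid_body", lon_range = c(-1, 1),
                                  lat_range = c(-1, 1), res = 0.25, days = 2,
                                  params = list(lon0 = 0, lat0 = 0, omega = 1e-5))
  pts <- cbind(runif(50, -0.9, 0.9), runif(50, -0.9, 0.9))
  got <- interp_velocity(plane, 0, pts[, 1], pts[, 2])
  want <- plane$meta$analytic(pts[, 1], pts[, 2], 0)
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
})

test_that("masked corners get zero weight and all-land cells return rest", {
  fld <- simulate_current_field("uniform", res = 1, days = 2,
                                lon_range = c(0, 3), lat_range = c(0, 3),
                                params = list(u = 1, v = 0),
                                land = list(c(-0.5, 3.5, -0.5, 0.5)))
  # cell straddling the land row: water corners still give u = 1
  got <- interp_velocity(fld, 0, 1.5, 0.5)
  expect_equal(unname(got[1, "u"]), 1)
  fld2 <- simulate_current_field("uniform", res = 1, days = 2,
                                 lon_range = c(0, 3), lat_range = c(0, 3),
                                 params = list(u = 1, v = 0),
                                 land = list(c(-0.5, 3.5, -0.5, 3.5)))
  expect_equal(unname(interp_velocity(fld2, 0, 1.5, 1.5)[1, ]), c(0, 0))
})

test_that("diffusive displacements vanish at their analytic zeros", {
  set.seed(1)
  expect_true(all(diffusive_step(0, 3600, 100) == 0))
  # K = 0 when R_NA = 0 (log term) or R_NB = 0.25 (cosine term)
  k1 <- sqrt(-4 * 5 * 3600 * log(1 - 0)) * cos(2 * pi * 0.5)
  expect_equal(k1, 0)
  expect_equal(sqrt(-4 * 5 * 3600 * log(1 - 0.3)) * cos(2 * pi * 0.25), 0,
               tolerance = 1e-12)
})

test_that("diffusive displacement variance approaches 2 E_h dt", {
  set.seed(2)
  k <- diffusive_step(5, 3600, 2e5)
  expect_equal(var(k[, 1]), 2 * 5 * 3600, tolerance = 0.05)
  expect_equal(var(k[, 2]), 2 * 5 * 3600, tolerance = 0.05)
  expect_lt(abs(cor(k[, 1], k[, 2])), 0.01)
})

test_that("a uniform current moves particles by u dt metres east", {
  fld <- uniform_field(u = 0.1, v = 0, days = 3)
  cfg <- dispersal_config(e_h = 0, particles_per_day = 4, release_days = 1,
                          run_days = 1, seed = 3L)
  p <- tibble::tibble(lon = c(0, 1), lat = c(0, 0), age = 0,
                      seed_region = "s", active = TRUE)
  p2 <- step_particles(p, fld, 0, cfg)
  expect_equal(p2$lon - p$lon, rep(360 / 111320, 2), tolerance = 1e-12)
  expect_equal(p2$lat, p$lat)
  expect_equal(p2$age, rep(3600 / 86400, 2))
  # zero field, zero diffusion: nothing moves
  fld0 <- uniform_field(u = 0, v = 0)
  p3 <- step_particles(p, fld0, 0, cfg)
  expect_equal(p3$lon, p$lon)
  expect_equal(p3$lat, p$lat)
})

test_that("solid-body rotation conserves orbit radius at small time steps", {
  omega <- 2 * pi / (20 * 86400)   # one revolution per 20 days (mesoscale eddy)
  fld <- simulate_current_field("solid_body", lon_range = c(-2, 2),
                                lat_range = c(-2, 2), res = 0.1, days = 12,
                                params = list(lon0 = 0, lat0 = 0, omega = omega))
  cfg <- dispersal_config(timestep_s = 360, e_h = 0, particles_per_day = 1,
                          release_days = 1, run_days = 10, seed = 4L)
  p <- tibble::tibble(lon = 0.5, lat = 0, age = 0, seed_region = "s",
                      active = TRUE)
  for (step in seq_len(10 * 240)) {
    p <- step_particles(p, fld, (step - 1) * 360 / 86400, cfg)
  }
  r_end <- sqrt(p$lon^2 + p$lat^2)
  expect_lt(abs(r_end - 0.5) / 0.5, 0.01)
})

test_that("particles leaving the grid deactivate; land destinations stay put", {
  fld <- simulate_current_field("uniform", lon_range = c(0, 1),
                                lat_range = c(0, 1), res = 0.25, days = 3,
                                params = list(u = 50, v = 0))
  cfg <- dispersal_config(e_h = 0, particles_per_day = 1, release_days = 1,
                          run_days = 1, seed = 5L)
  p <- tibble::tibble(lon = 0.99, lat = 0.5, age = 0, seed_region = "s",
                      active = TRUE)
  p2 <- step_particles(p, fld, 0, cfg)   # 180 km step exits the grid
  expect_false(p2$active)
  expect_equal(p2$lon, 0.99)             # frozen at last water position
  # a land destination keeps the particle in place but active
  fld_land <- simulate_current_field("uniform", lon_range = c(0, 2),
                                     lat_range = c(0, 1), res = 0.25, days = 3,
                                     params = list(u = 10, v = 0),
                                     land = list(c(1.2, 2, -0.5, 1.5)))
  p3 <- tibble::tibble(lon = 1.1, lat = 0.5, age = 0, seed_region = "s",
                       active = TRUE)
  p4 <- step_particles(p3, fld_land, 0, cfg)
  expect_true(p4$active)
  expect_equal(p4$lon, 1.1)
})

test_that("seeding is uniform over the polygon's water area", {
  fld <- simulate_current_field("uniform", lon_range = c(0, 4),
                                lat_range = c(0, 4), res = 0.25, days = 2,
                                params = list(u = 0, v = 0),
                                land = list(c(0, 2, 0, 4)))
  poly <- cbind(c(0.5, 3.5, 3.5, 0.5), c(0.5, 0.5, 3.5, 3.5))
  set.seed(6)
  p <- seed_particles(2000, poly, fld, "s")
  expect_equal(nrow(p), 2000L)
  expect_true(all(p$age == 0))
  expect_true(all(p$lon >= 2))       # the western half is land
  # uniformity over the water part (chi-square on a 4 x 6 partition)
  tab <- table(cut(p$lon, seq(2.125, 3.5, length.out = 5)),
               cut(p$lat, seq(0.5, 3.5, length.out = 7)))
  expect_gt(stats::chisq.test(as.vector(tab))$p.value, 0.01)
  land_poly <- cbind(c(0.5, 1.5, 1.5, 0.5), c(0.5, 0.5, 1.5, 1.5))
  expect_error(seed_particles(10, land_poly, fld), "no water")
})

test_that("run_dispersal is deterministic and obeys the closed-form drift", {
  fld <- uniform_field(u = 0.1, v = 0, days = 8)
  poly <- list(s1 = cbind(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5)))
  cfg <- dispersal_config(e_h = 1, particles_per_day = 50, release_days = 1,
                          run_days = 5, seed = 7L)
  r1 <- run_dispersal(fld, cfg, poly)
  r2 <- run_dispersal(fld, cfg, poly)
  expect_identical(r1$particles, r2$particles)
  drift_deg <- 0.1 * 5 * 86400 / 111320
  start_mean <- 0   # polygon centred on zero
  se <- sqrt(2 * 1 * 3600 * 5 * 24) / 111320 / sqrt(50) + 1 / sqrt(12 * 50)
  expect_lt(abs(mean(r1$particles$lon) - (start_mean + drift_deg)), 4 * se)
  # run_days = 0 keeps only the seeded positions
  cfg0 <- dispersal_config(e_h = 0, particles_per_day = 20, release_days = 1,
                           run_days = 0, seed = 8L)
  r0 <- run_dispersal(fld, cfg0, poly)
  expect_equal(nrow(r0$particles), 20L)
  expect_true(all(r0$particles$age == 0))
})

test_that("field shorter than the run window is rejected before stepping", {
  fld <- uniform_field(days = 3)
  cfg <- dispersal_config(particles_per_day = 1, release_days = 1,
                          run_days = 30)
  expect_error(run_dispersal(fld, cfg, list(s = cbind(0:1, 0:1))), "shorter")
})

test_that("connectivity fractions behave as a partition bound", {
  p <- tibble::tibble(lon = c(0.5, 0.5, 2.5, 9), lat = c(0.5, 0.5, 0.5, 9),
                      age = 1, seed_region = c("a", "a", "a", "b"),
                      active = c(TRUE, TRUE, TRUE, TRUE))
  sinks <- list(s1 = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                s2 = cbind(c(2, 3, 3, 2), c(0, 0, 1, 1)))
  cm <- connectivity_matrix(p, sinks)
  expect_equal(cm["a", "s1"], 2 / 3)
  expect_equal(cm["a", "s2"], 1 / 3)
  expect_equal(unname(cm["b", ]), c(0, 0))
  expect_true(all(rowSums(cm) <= 1 + 1e-12))
  # at t = 0 with sinks equal to the seed region the diagonal is 1
  fld <- uniform_field()
  poly <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  set.seed(9)
  seeded <- seed_particles(100, poly, fld, "a")
  cm0 <- connectivity_matrix(seeded, list(a = poly))
  expect_equal(unname(cm0["a", "a"]), 1)
  # overlapping sinks warn and count particles once
  expect_warning(cm_ov <- connectivity_matrix(p, list(s1 = sinks$s1, s1b = sinks$s1)),
                 "overlapping")
  expect_equal(unname(cm_ov["a", ]), c(2 / 3, 0))
})

test_that("diffusion-only spreading grows linearly at rate 2 E_h per axis", {
  fld <- uniform_field(u = 0, v = 0, days = 6)
  cfg <- dispersal_config(e_h = 5, particles_per_day = 3000, release_days = 1,
                          run_days = 3, seed = 10L)
  poly <- list(s = cbind(c(-0.01, 0.01, 0.01, -0.01), c(-0.01, -0.01, 0.01, 0.01)))
  r <- run_dispersal(fld, cfg, poly)
  t_s <- 3 * 86400
  var0 <- (0.02 * 111320)^2 / 12        # uniform seeding variance
  msd_x <- var(r$particles$lon * 111320)
  expect_equal(msd_x, 2 * 5 * t_s + var0, tolerance = 0.1)
})
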