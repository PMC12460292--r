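test_that("a smooth disc has the analytic cylinder volume and density", {
  spec <- disc_spec(seed = 50, sensor_noise = 0, occlude_bottom = FALSE)
  d <- generate_disc(spec)
  expect_equal(d$true_volume, pi * 15^2 * 5, tolerance = 1e-6)
  # realized point count within 5% of density x total surface area
  area_cm2 <- 2 * pi * 15 * 5 + 2 * pi * 15^2
  expect_lt(abs(n_points(d$cloud) / (10 * area_cm2) - 1), 0.05)
})

test_that("bottom occlusion removes the base and crops at the ground", {
  d <- generate_disc(disc_spec(seed = 51))
  pts <- d$cloud$points
  expect_gte(min(pts[, 3]), 0)
  # the lowest points are wall-rim points, not interior base points
  low <- pts[pts[, 3] < 0.2, , drop = FALSE]
  r <- sqrt(low[, 1]^2 + low[, 2]^2)
  expect_gt(min(r), 13)
  # no-occlusion discs do carry interior base points
  d2 <- generate_disc(disc_spec(seed = 51, occlude_bottom = FALSE))
  pts2 <- d2$cloud$points
  low2 <- pts2[pts2[, 3] < 0.2, , drop = FALSE]
  expect_lt(min(sqrt(low2[, 1]^2 + low2[, 2]^2)), 5)
})

test_that("disc generation is reproducible from the seed", {
  a <- generate_disc(disc_spec(seed = 52))
  b <- generate_disc(disc_spec(seed = 52))
  cc <- generate_disc(disc_spec(seed = 53))
  expect_identical(a$cloud$points, b$cloud$points)
  expect_identical(a$true_volume, b$true_volume)
  expect_false(isTRUE(all.equal(a$cloud$points, cc$cloud$points)))
})

test_that("station visibility trims azimuths no station can see", {
  d <- generate_disc(disc_spec(seed = 54, stations = 90, station_fov = 45,
                               sensor_noise = 0))
  pts <- d$cloud$points
  wall <- pts[pts[, 3] < 4.5, , drop = FALSE]
  th <- atan2(wall[, 2], wall[, 1]) %% (2 * pi)
  dist <- pmin(abs(th - pi / 2), 2 * pi - abs(th - pi / 2))
  expect_lte(max(dist), 45 * pi / 180 + 1e-6)
})

test_that("true profile volume integrates analytic and rough profiles", {
  circ <- disc_spec(radius_a = 10, height = 5, seed = 55)
  expect_rel_equal(true_profile_volume(circ), 500 * pi, 1e-4)
  ell <- disc_spec(radius_a = 10, radius_b = 20, height = 5, seed = 55)
  expect_rel_equal(true_profile_volume(ell), 1000 * pi, 1e-4)

  rough <- generate_disc(disc_spec(seed = 56, bark_amplitude = 0.8))
  v1 <- true_profile_volume(rough$spec, rough$realization, n_vertices = 3600)
  v2 <- true_profile_volume(rough$spec, rough$realization, n_vertices = 7200)
  expect_lt(abs(v2 / v1 - 1), 1e-4)
  expect_equal(rough$true_volume, v1, tolerance = 1e-12)

  # Monte-Carlo point-in-polygon oracle
  set.seed(57)
  rf <- rough$realization$radius_fn
  rmax <- max(rf(seq(0, 2 * pi, length.out = 3600))) * 1.01
  n_mc <- 200000
  x <- runif(n_mc, -rmax, rmax); y <- runif(n_mc, -rmax, rmax)
  inside <- sqrt(x^2 + y^2) <= rf(atan2(y, x) %% (2 * pi))
  p <- mean(inside)
  mc_area <- p * (2 * rmax)^2
  se <- sqrt(p * (1 - p) / n_mc) * (2 * rmax)^2
  expect_lt(abs(v1 / rough$spec$height - mc_area), 3 * se)
})

test_that("rough bark degrades the returns of the wall", {
  smooth <- generate_disc(disc_spec(seed = 58))
  rough <- generate_disc(disc_spec(seed = 58, bark_amplitude = 1))
  # dropouts: fewer wall returns at equal nominal density
  expect_lt(n_points(rough$cloud), n_points(smooth$cloud))
  # truth reflects the realized solid, not the nominal ellipse
  expect_false(isTRUE(all.equal(rough$true_volume, pi * 15^2 * 5)))
})

test_that("paired datasets propagate their generating parameters", {
  # zero bias and noise: estimates equal the underlying truth
  specs <- data.frame(species = c("a", "b"), n = c(10L, 8L),
                      mean_volume = c(150, 250), volume_spread = c(30, 40),
                      bias = 0, noise_sd = 0)
  tab <- generate_paired_dataset(specs, replicate_sd = 0, seed = 59)
  expect_equal(nrow(tab), 18L)
  expect_equal(tab$estimated_volume, tab$reference_volume)
  rep <- build_report(tab)
  expect_equal(rep$overall$rmse, 0)
  expect_equal(rep$overall$ccc, 1)

  # injected bias recovered within the sampling-error bound 3 sd / sqrt(n)
  for (seed in 1:3) {
    tab2 <- generate_paired_dataset(
      data.frame(species = "a", n = 123L, mean_volume = 171.42,
                 volume_spread = 60, bias = -5, noise_sd = 25),
      replicate_sd = 2, seed = seed)
    ba <- bland_altman(tab2$reference_volume, tab2$estimated_volume)
    expect_lt(abs(ba$mean_diff - (-5)), 3 * 25 / sqrt(123))
  }
})
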