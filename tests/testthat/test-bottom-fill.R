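test_that("detect_lowest finds the global minimum Z", {
  expect_equal(detect_lowest(point_cloud(rbind(c(0, 0, 5)), unit = "cm")), 5)
  pc <- point_cloud(cbind(0, 0, c(0.051, 0.002, 0.049)), unit = "m")
  expect_equal(detect_lowest(pc), 0.002)
  set.seed(1)
  pts <- cbind(runif(1000), runif(1000), runif(1000, -1, 1))
  zmin <- Inf
  for (i in seq_len(nrow(pts))) if (pts[i, 3] < zmin) zmin <- pts[i, 3]
  expect_identical(detect_lowest(point_cloud(pts, unit = "cm")), zmin)
})

test_that("project_to_base keeps XY and sets Z to the base plane", {
  pc <- point_cloud(rbind(c(1, 2, 3), c(4, 4, 0), c(0, 0, 1)), unit = "cm")
  pr <- project_to_base(pc, 0)
  expect_equal(pr$points[1, ], c(x = 1, y = 2, z = 0))
  expect_equal(pr$points[2, ], c(x = 4, y = 4, z = 0))  # fixed point
  expect_equal(n_points(pr), n_points(pc))

  set.seed(2)
  cloud <- point_cloud(matrix(rnorm(300), ncol = 3), unit = "cm")
  pr2 <- project_to_base(cloud)
  # XY multiset identical
  o1 <- order(cloud$points[, 1], cloud$points[, 2])
  o2 <- order(pr2$points[, 1], pr2$points[, 2])
  expect_equal(cloud$points[o1, 1:2], pr2$points[o2, 1:2])
  expect_true(all(pr2$points[, 3] == detect_lowest(cloud)))

  expect_error(project_to_base(pc, 0.5), "above the lowest")
})

test_that("fill_bottom merges original and projection under the dedupe policy", {
  pts5 <- rbind(c(0, 0, 0),    # already at z_min: its projection coincides
                c(1, 0, 1), c(0, 1, 2), c(1, 1, 1.5), c(2, 2, 3))
  pc <- point_cloud(pts5, unit = "cm")
  # literal union (dedupe disabled): |complete| = 2 |original|
  expect_equal(fill_bottom(pc, dedupe_tol = NULL)$n_complete, 10L)
  # exact-duplicate removal drops the one coincident pair
  f0 <- fill_bottom(pc, dedupe_tol = 0)
  expect_equal(f0$n_complete, 9L)
  expect_equal(f0$n_projected, 4L)
  expect_equal(f0$z_min, 0)

  # flat cloud: projection coincides entirely; complete = original
  flat <- point_cloud(cbind(runif(20), runif(20), 2), unit = "cm")
  ff <- fill_bottom(flat, dedupe_tol = 0)
  expect_equal(ff$n_complete, 20L)

  # idempotence: filling an already-filled cloud adds nothing
  f1 <- fill_bottom(pc)
  f2 <- fill_bottom(f1$complete)
  expect_equal(f2$n_complete, f1$n_complete)
})

test_that("fill preserves z extremes and the XY footprint", {
  set.seed(3)
  th <- runif(2000, 0, 2 * pi)
  wall <- cbind(10 * cos(th), 10 * sin(th), runif(2000, 0, 5))
  pc <- point_cloud(wall, unit = "cm")
  fc <- fill_bottom(pc)
  expect_equal(min(fc$complete$points[, 3]), fc$z_min)
  expect_equal(max(fc$complete$points[, 3]), max(wall[, 3]))
  expect_equal(hull_area_xy(fc$complete$points[, 1:2]),
               hull_area_xy(wall[, 1:2]))
})

test_that("filling an open-bottom cylinder produces a filled base disc", {
  set.seed(4)
  n <- 4000
  th <- runif(n, 0, 2 * pi)
  r <- 15
  wall <- cbind(r * cos(th), r * sin(th), runif(n, 0, 5))
  fc <- fill_bottom(point_cloud(wall, unit = "cm"))
  base <- fc$complete$points[fc$complete$points[, 3] == fc$z_min, 1:2]
  expect_gte(hull_area_xy(base), 0.95 * pi * r^2)
})
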