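test_that("quadratic patches are recovered exactly on noiseless data", {
  g <- expand.grid(x = -1:1, y = -1:1)
  flat <- fit_quadratic_patch(cbind(g$x, g$y, 0))
  expect_true(all(abs(flat$coef) < 1e-9))

  bowl <- fit_quadratic_patch(cbind(g$x, g$y, g$x^2 + g$y^2))
  expect_equal(unname(bowl$coef), c(1, 1, 0, 0, 0, 0), tolerance = 1e-9)
  # against a generic linear-system solve
  A <- cbind(g$x^2, g$y^2, g$x * g$y, g$x, g$y, 1)
  expect_equal(unname(bowl$coef),
               unname(solve(crossprod(A), crossprod(A, g$x^2 + g$y^2))[, 1]),
               tolerance = 1e-9)

  xy <- cbind(c(0, 1, 0, 2, 1, 3), c(0, 0, 1, 1, 2, 2))
  ramp <- fit_quadratic_patch(cbind(xy, 2 * xy[, 1]))
  expect_equal(unname(ramp$coef), c(0, 0, 0, 2, 0, 0), tolerance = 1e-9)

  expect_error(fit_quadratic_patch(cbind(0:5, 0, 0)), "degenerate")
  expect_error(fit_quadratic_patch(matrix(0, 5, 3)), "at least 6")
})

test_that("patch normals follow the surface gradient", {
  expect_equal(patch_normal(c(0, 0, 0, 0, 0, 0)), c(0, 0, 1))
  expect_equal(patch_normal(c(0, 0, 0, 2, 0, 0)), c(-2, 0, 1) / sqrt(5))
  # gradient of x^2 + y^2 at (1, 0)
  expect_equal(patch_normal(c(1, 1, 0, 0, 0, 0), at = c(1, 0)),
               c(-2, 0, 1) / sqrt(5))
  expect_equal(sqrt(sum(patch_normal(c(3, -2, 1, 4, -1, 0))^2)), 1)
})

test_that("estimated normals match the analytic surface direction", {
  set.seed(10)
  sc <- sphere_cloud(10000)
  rad <- sc$points / sqrt(rowSums(sc$points^2))
  est <- estimate_normals(point_cloud(sc$points, unit = "cm"), k = 6)
  dots <- abs(rowSums(cloud_normals(est) * rad))
  expect_gte(mean(dots >= 0.99), 0.99)
  expect_equal(unname(sqrt(rowSums(cloud_normals(est)^2))),
               rep(1, 10000), tolerance = 1e-9)

  # flat grid: every normal is +/- (0, 0, 1)
  g <- as.matrix(expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1)))
  flat <- estimate_normals(point_cloud(cbind(g, 0), unit = "cm"), k = 8)
  expect_true(all(abs(cloud_normals(flat)[, 3]) > 1 - 1e-9))

  # cylinder wall: normals orthogonal to the axis within 2 degrees
  set.seed(11)
  cyl <- estimate_normals(cylinder_wall_cloud(5000), k = 8)
  axis_dev <- abs(cloud_normals(cyl)[, 3])
  expect_gte(mean(axis_dev < sin(2 * pi / 180)), 0.95)
})

test_that("covariance normals are available as an alternative path", {
  set.seed(12)
  sc <- sphere_cloud(5000)
  rad <- sc$points / sqrt(rowSums(sc$points^2))
  est <- estimate_normals(point_cloud(sc$points, unit = "cm"),
                          k = 8, method = "covariance")
  expect_gte(mean(abs(rowSums(cloud_normals(est) * rad)) >= 0.99), 0.99)
})

test_that("MST orientation makes signs globally consistent and outward", {
  # flat grid with half the normals pre-flipped -> all equal after orientation
  g <- as.matrix(expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1)))
  pc <- point_cloud(cbind(g, 0), unit = "cm")
  set.seed(13)
  signs <- sample(c(-1, 1), nrow(g), replace = TRUE)
  pc <- disctls:::set_normals(pc, cbind(0, 0, signs))
  or <- orient_normals_mst(pc)
  nz <- cloud_normals(or)[, 3]
  expect_true(all(nz == nz[1]))

  # sphere: outward, not inward
  set.seed(14)
  sc <- sphere_cloud(4000)
  rad <- sc$points / sqrt(rowSums(sc$points^2))
  scr <- disctls:::set_normals(point_cloud(sc$points, unit = "cm"),
                               rad * sample(c(-1, 1), 4000, replace = TRUE))
  or2 <- orient_normals_mst(scr)
  expect_gte(mean(rowSums(cloud_normals(or2) * rad)), 0.95)
})

test_that("normals rotate with the cloud (up to sign before orientation)", {
  set.seed(15)
  sc <- sphere_cloud(2000)
  ang <- c(0.3, -0.5, 1.1)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  R <- Rz %*% Rx
  base <- estimate_normals(point_cloud(sc$points, unit = "cm"), k = 8)
  rot <- estimate_normals(point_cloud(sc$points %*% t(R), unit = "cm"), k = 8)
  agree <- abs(rowSums((cloud_normals(base) %*% t(R)) * cloud_normals(rot)))
  expect_equal(unname(agree), rep(1, 2000), tolerance = 1e-6)
})
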