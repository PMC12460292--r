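test_that("watertightness diagnostics classify the textbook cases", {
  cube <- mesh_cube()
  wt <- check_watertight(cube)
  expect_true(wt$is_watertight)
  expect_equal(wt$open_edges, 0L)
  expect_equal(wt$components, 1L)

  # removing one quad (two triangles) leaves its 4 boundary edges open
  holed <- triangle_mesh(cube$vertices, cube$faces[-(1:2), ], unit = "cm")
  wt2 <- check_watertight(holed)
  expect_false(wt2$is_watertight)
  expect_equal(wt2$open_edges, 4L)

  # two disjoint closed tetrahedra: closed but 2 components
  t1 <- mesh_tetrahedron()
  t2v <- t1$vertices + 10
  both <- triangle_mesh(rbind(t1$vertices, t2v),
                        rbind(t1$faces, t1$faces + 4L), unit = "cm")
  wt3 <- check_watertight(both)
  expect_equal(wt3$components, 2L)
  expect_false(wt3$is_watertight)
  expect_equal(wt3$open_edges, 0L)

  # inconsistent orientation is caught
  bad <- triangle_mesh(cube$vertices,
                       rbind(cube$faces[-1, ], cube$faces[1, c(1, 3, 2)]),
                       unit = "cm")
  expect_false(check_watertight(bad)$is_watertight)
})

test_that("reconstruction recovers analytic volumes from oriented samples", {
  set.seed(30)
  sphere <- sphere_cloud(20000)
  ms <- reconstruct_surface(sphere, reconstruction_settings(octree_depth = 7))
  expect_true(check_watertight(ms)$is_watertight)
  expect_rel_equal(as.numeric(divergence_volume(ms)), 4 * pi / 3, 0.05)

  cube <- cube_cloud(20000)
  mc <- reconstruct_surface(cube, reconstruction_settings(octree_depth = 7))
  expect_true(check_watertight(mc)$is_watertight)
  expect_rel_equal(as.numeric(divergence_volume(mc)), 1, 0.05)
})

test_that("the full disc pipeline recovers the known cylinder volume", {
  d <- generate_disc(disc_spec(seed = 101))
  expect_equal(d$true_volume, pi * 15^2 * 5, tolerance = 1e-6)
  filled <- fill_bottom(d$cloud)
  oc <- orient_normals_mst(estimate_normals(filled$complete))
  mesh <- reconstruct_surface(oc, reconstruction_settings(octree_depth = 7))
  expect_true(check_watertight(mesh)$is_watertight)
  v <- as.numeric(divergence_volume(mesh))
  expect_lt(abs(v / d$true_volume - 1), 0.03)
})

test_that("one extra octree level changes the sphere error by < 1 point", {
  set.seed(31)
  sphere <- sphere_cloud(20000)
  e <- sapply(c(6L, 7L), function(d) {
    m <- reconstruct_surface(sphere, reconstruction_settings(octree_depth = d))
    abs(as.numeric(divergence_volume(m)) / (4 * pi / 3) - 1)
  })
  expect_lt(e[2] - e[1], 0.01)
})

test_that("reconstructed volume is invariant under rigid motion", {
  set.seed(32)
  sphere <- sphere_cloud(12000)
  v1 <- as.numeric(divergence_volume(
    reconstruct_surface(sphere, reconstruction_settings(octree_depth = 6))))
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  moved <- disctls:::set_normals(
    point_cloud(sphere$points %*% t(R) + 3, unit = "cm"),
    cloud_normals(sphere) %*% t(R))
  v2 <- as.numeric(divergence_volume(
    reconstruct_surface(moved, reconstruction_settings(octree_depth = 6))))
  expect_lt(abs(v2 / v1 - 1), 0.005)
})

test_that("reconstruction rejects unusable input", {
  pc <- point_cloud(matrix(rnorm(30), ncol = 3), unit = "cm")
  expect_error(reconstruct_surface(pc), "no normals")
  oc <- disctls:::set_normals(pc, matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE))
  expect_error(reconstruct_surface(oc), "at least 100")
  expect_error(reconstruction_settings(octree_depth = 3), ">= 4")
})
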