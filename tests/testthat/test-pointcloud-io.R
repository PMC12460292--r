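test_that("point_cloud validates its invariants", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), unit = "cm")
  expect_equal(n_points(pc), 3L)
  expect_error(point_cloud(matrix(numeric(0), 0, 3)), "empty")
  expect_error(point_cloud(rbind(c(0, 0, NA))), "finite")
  expect_error(point_cloud(matrix(1, 2, 2)), "3 columns")
})

test_that("unit conversion scales lengths exactly and volumes cubically", {
  pc <- point_cloud(rbind(c(1, 2, 3), c(0.5, 0, -1)), unit = "m")
  cm <- convert_unit(pc, "cm")
  expect_identical(cm$points, pc$points * 100)
  expect_identical(convert_unit(cm, "m")$points, pc$points)
  # volume reporting applies the cube of the length factor
  cube_m <- mesh_cube(unit = "m")
  expect_equal(as.numeric(divergence_volume(cube_m)), 1e6)
  expect_equal(as.numeric(divergence_volume(mesh_cube(unit = "cm"))), 1)
})

test_that("XYZ text reading parses rows and rejects non-finite ones", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 0 0", "0 1 0"), f)
  pc <- read_point_cloud(f, unit = "cm")
  expect_equal(n_points(pc), 3L)
  expect_equal(attr(pc, "rejected_rows"), 0L)

  writeLines(c("0 0 0", "1 0 0", "2 nan 0", "0 1 0", "0 0 1"), f)
  expect_warning(pc2 <- read_point_cloud(f, unit = "cm"), "rejected")
  expect_equal(n_points(pc2), 4L)
  expect_equal(attr(pc2, "rejected_rows"), 1L)

  # extra columns ignored
  writeLines(c("0 0 0 17 4", "1 1 1 12 9"), f)
  expect_equal(n_points(read_point_cloud(f, unit = "cm")), 2L)

  expect_error(read_point_cloud(file.path(tempdir(), "absent.xyz")), "cannot read")
})

test_that("PLY round-trips coordinates (binary bit-for-bit)", {
  set.seed(42)
  pts <- matrix(runif(30000, -5, 5), ncol = 3)
  pc <- point_cloud(pts, unit = "cm", id = "rt")
  fb <- withr::local_tempfile(fileext = ".ply")
  fa <- withr::local_tempfile(fileext = ".ply")

  write_point_cloud(pc, fb, format = "ply_binary")
  back_b <- read_point_cloud(fb, unit = "cm")
  expect_identical(max(abs(back_b$points - pts)), 0)

  write_point_cloud(pc, fa, format = "ply_ascii")
  back_a <- read_point_cloud(fa, unit = "cm")
  expect_identical(max(abs(back_a$points - pts)), 0)

  # header contract
  hdr <- readLines(fa, n = 10)
  expect_true(any(grepl("^element vertex 10000$", hdr)))
  small <- point_cloud(diag(3), unit = "cm")
  write_point_cloud(small, fa, format = "ply_ascii")
  expect_true(any(grepl("^element vertex 3$", readLines(fa, n = 10))))
})

test_that("PLY preserves normals and extra vertex properties", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(1, 1, 1)), unit = "cm",
                    extra = data.frame(intensity = c(7, 9)))
  nrm <- rbind(c(0, 0, 1), c(1, 0, 0))
  pc <- disctls:::set_normals(pc, nrm)
  f <- withr::local_tempfile(fileext = ".ply")
  for (fmt in c("ply_ascii", "ply_binary")) {
    write_point_cloud(pc, f, format = fmt)
    back <- read_point_cloud(f, unit = "cm")
    expect_equal(unname(cloud_normals(back)), unname(nrm))
    expect_equal(back$extra$intensity, c(7, 9))
  }
})

test_that("mesh PLY round-trips vertices and faces", {
  mesh <- mesh_icosphere(1)
  f <- withr::local_tempfile(fileext = ".ply")
  for (fmt in c("ply_binary", "ply_ascii")) {
    write_mesh(mesh, f, format = fmt)
    back <- read_mesh(f, unit = "cm")
    expect_equal(back$vertices, mesh$vertices)
    expect_identical(back$faces, mesh$faces)
  }
})

test_that("sample tables compute replicate means and reject bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,species,estimated_volume,rep1,rep2,rep3",
               "d1,X,100,98,100,102",
               "d2,X,-5,100,100,100",
               "d3,Y,55,54,,"), f)
  expect_warning(tab <- read_samples_table(f), "rejected")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$reference_volume, c(100, 54))
  expect_equal(attr(tab, "rejected_rows"), 1L)

  writeLines(c("id,estimated_volume,rep1", "d1,1,1"), f)
  expect_error(read_samples_table(f), "species")
})

test_that("a four-species campaign table loads with all 123 samples", {
  tab <- generate_paired_dataset(seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_samples_table(tab, f)
  back <- read_samples_table(f)
  expect_equal(nrow(back), 123L)
  expect_equal(as.vector(table(back$species)[unique(back$species)]),
               c(69L, 25L, 12L, 17L))
  expect_equal(back$reference_volume,
               rowMeans(back[, c("rep1", "rep2", "rep3")]))
})
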