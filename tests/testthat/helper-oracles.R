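# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# enclosed volume as the sum of signed tetrahedra from the origin:
# V = sum det(v0, v1, v2) / 6 over faces (algebraically identical to the
# divergence-theorem sum for closed surfaces)
tetra_sum_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  p1 <- v[f[, 2], , drop = FALSE]
  p2 <- v[f[, 3], , drop = FALSE]
  dets <- p0[, 1] * (p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2]) -
    p0[, 2] * (p1[, 1] * p2[, 3] - p1[, 3] * p2[, 1]) +
    p0[, 3] * (p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1])
  sum(dets) / 6
}

# area of the 2D convex hull of (x, y) points
hull_area_xy <- function(xy) {
  h <- grDevices::chull(xy)
  x <- xy[h, 1]; y <- xy[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n1+n2, n1) group-1 assignments (no ties assumed)
mwu_enum_p <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  pooled <- c(g1, g2)
  r <- rank(pooled)
  u_of <- function(idx) {
    R1 <- sum(r[idx])
    U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
    min(U1, n1 * n2 - U1)
  }
  obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  stats <- apply(combos, 2, u_of)
  mean(stats <= obs)
}

# uniform sample of a cylinder wall (no caps), exact surface points
cylinder_wall_cloud <- function(n, radius = 1, height = 2) {
  th <- runif(n, 0, 2 * pi)
  point_cloud(cbind(radius * cos(th), radius * sin(th), runif(n, 0, height)),
              unit = "cm", id = "cylwall")
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected), rel_tol * abs(expected))
}
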