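## Analytic geometry fixtures: closed meshes and surface samplings with
## known volume, used to validate the volume integrator and the
## reconstruction backend.

#' Axis-aligned cube mesh
#' @param side edge length (default 1).
#' @param origin corner position (default the coordinate origin).
#' @param unit length unit.
#' @return a watertight [triangle_mesh()] of 12 outward-wound triangles.
#' @export
mesh_cube <- function(side = 1, origin = c(0, 0, 0), unit = "cm") {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  v <- sweep(v * side, 2, origin, `+`)
  # vertex order: (x fastest) 1:(000) 2:(100) 3:(010) 4:(110) 5:(001) 6:(101) 7:(011) 8:(111)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),  # z = 0, outward -z
    c(5, 6, 8), c(5, 8, 7),  # z = 1, outward +z
    c(1, 2, 6), c(1, 6, 5),  # y = 0, outward -y
    c(3, 7, 8), c(3, 8, 4),  # y = 1, outward +y
    c(1, 5, 7), c(1, 7, 3),  # x = 0, outward -x
    c(2, 4, 8), c(2, 8, 6))  # x = 1, outward +x
  triangle_mesh(v, f, unit = unit)
}

#' Unit right tetrahedron mesh
#'
#' Vertices (0,0,0), (1,0,0), (0,1,0), (0,0,1); enclosed volume 1/6.
#' @param unit length unit.
#' @return a watertight [triangle_mesh()].
#' @export
mesh_tetrahedron <- function(unit = "cm") {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f, unit = unit)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron with vertices projected onto the sphere of radius
#' `radius`; volume converges to 4/3 pi r^3 from below.
#'
#' @param subdiv number of 4-to-1 subdivision passes (default 4).
#' @param radius sphere radius (default 1).
#' @param unit length unit.
#' @return a watertight [triangle_mesh()].
#' @export
mesh_icosphere <- function(subdiv = 4L, radius = 1, unit = "cm") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      midcache[[key]] <- id
      id
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * k - 3, ] <- c(a, ab, ca)
      newf[4 * k - 2, ] <- c(b, bc, ab)
      newf[4 * k - 1, ] <- c(cc, ca, bc)
      newf[4 * k, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  triangle_mesh(v * radius, f, unit = unit)
}

#' Uniform sample of a sphere surface with outward normals
#' @param n number of points.
#' @param radius sphere radius.
#' @param center sphere center.
#' @param unit length unit.
#' @return an oriented [point_cloud()].
#' @export
sphere_cloud <- function(n = 20000L, radius = 1, center = c(0, 0, 0),
                         unit = "cm") {
  u <- matrix(rnorm(3 * n), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * radius, 2, center, `+`)
  set_normals(point_cloud(pts, unit = unit, id = "sphere"), u)
}

#' Uniform sample of a cube surface with outward normals
#' @param n number of points.
#' @param side edge length.
#' @param unit length unit.
#' @return an oriented [point_cloud()] of the cube `[0, side]^3`.
#' @export
cube_cloud <- function(n = 20000L, side = 1, unit = "cm") {
  face <- sample.int(6L, n, replace = TRUE)
  a <- runif(n, 0, side); b <- runif(n, 0, side)
  pts <- matrix(0, n, 3L)
  nrm <- matrix(0, n, 3L)
  axis <- (face - 1L) %/% 2L + 1L      # 1=x, 2=y, 3=z
  hi <- face %% 2L == 0L               # even faces at coordinate = side
  for (ax in 1:3) {
    sel <- axis == ax
    others <- setdiff(1:3, ax)
    pts[sel, others[1]] <- a[sel]
    pts[sel, others[2]] <- b[sel]
    pts[sel, ax] <- ifelse(hi[sel], side, 0)
    nrm[sel, ax] <- ifelse(hi[sel], 1, -1)
  }
  set_normals(point_cloud(pts, unit = unit, id = "cube"), nrm)
}
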