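#' Construct a triangle mesh
#'
#' An indexed triangle set: vertices (n x 3) and faces (m x 3 of 1-based
#' vertex indices) with a declared length unit. Per-face areas, centroids and
#' unit normals — the ingredients of the divergence-theorem volume — are
#' computed on demand by [face_geometry()]; face normals come from the
#' winding order (cross product), not from vertex normals.
#'
#' @param vertices numeric matrix with 3 columns.
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param unit length unit of the vertex coordinates.
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, unit = c("cm", "m", "mm")) {
  unit <- match.arg(unit)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, unit = unit),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces [%s]\n",
              nrow(x$vertices), nrow(x$faces), x$unit))
  invisible(x)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-face areas, centroids and unit normals
#'
#' @param mesh a [triangle_mesh()].
#' @return list with `area` (m-vector), `centroid` (m x 3), `normal`
#'   (m x 3 unit vectors from winding order; zero-area faces get a zero
#'   normal).
#' @export
face_geometry <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  p1 <- v[f[, 2], , drop = FALSE]
  p2 <- v[f[, 3], , drop = FALSE]
  cr <- cross3(p1 - p0, p2 - p0)
  nrm2 <- sqrt(rowSums(cr^2))
  area <- nrm2 / 2
  normal <- cr / ifelse(nrm2 > 0, nrm2, 1)
  centroid <- (p0 + p1 + p2) / 3
  list(area = area, centroid = centroid, normal = normal)
}

# undirected edge table: one row per face edge, with a canonical key and the
# traversal direction (TRUE if the face traverses the edge low->high index)
.mesh_edges <- function(mesh) {
  f <- mesh$faces
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- (as.numeric(lo) - 1) * nrow(mesh$vertices) + as.numeric(hi)
  list(key = key, forward = a < b)
}

# per-undirected-edge incidence count and forward-traversal count
# (sort + run-length encoding; avoids factor construction on large meshes)
.edge_stats <- function(ed) {
  o <- order(ed$key)
  k <- ed$key[o]
  fwd <- ed$forward[o]
  r <- rle(k)
  cnt <- r$lengths
  ends <- cumsum(cnt)
  cs <- cumsum(fwd)
  dirsum <- cs[ends] - c(0, cs[ends[-length(ends)]])
  list(count = cnt, dirsum = dirsum)
}

#' Watertightness diagnostics of a triangle mesh
#'
#' A mesh is watertight when every edge is shared by exactly two faces, the
#' two incident faces traverse each shared edge in opposite directions
#' (consistent orientation), and the face graph has a single connected
#' component. Volume must never be computed on an open mesh.
#'
#' @param mesh a [triangle_mesh()].
#' @return list with `is_watertight`, `open_edges`, `non_manifold_edges`,
#'   `components`, `consistent_orientation`.
#' @export
check_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L)
    return(list(is_watertight = FALSE, open_edges = 0L,
                non_manifold_edges = 0L, components = 0L,
                consistent_orientation = FALSE))
  es <- .edge_stats(.mesh_edges(mesh))
  open_edges <- sum(es$count == 1L)
  non_manifold <- sum(es$count > 2L)

  # orientation: each edge seen exactly twice must be traversed once
  # forward and once backward
  consistent <- open_edges == 0L && non_manifold == 0L &&
    all(es$dirsum[es$count == 2L] == 1L)

  used <- sort(unique(as.vector(mesh$faces)))
  g <- igraph::graph_from_edgelist(
    cbind(match(c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), used),
          match(c(mesh$faces[, 2], mesh$faces[, 3], mesh$faces[, 1]), used)),
    directed = FALSE)
  comps <- igraph::components(g)$no

  list(is_watertight = open_edges == 0L && non_manifold == 0L &&
         comps == 1L && consistent,
       open_edges = as.integer(open_edges),
       non_manifold_edges = as.integer(non_manifold),
       components = as.integer(comps),
       consistent_orientation = consistent)
}

# keep the component with the largest total face count; drops unreferenced
# vertices and reindexes faces
.largest_component <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(mesh)
  nv <- nrow(mesh$vertices)
  g <- igraph::graph_from_edgelist(
    cbind(c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
          c(mesh$faces[, 2], mesh$faces[, 3], mesh$faces[, 1])),
    directed = FALSE)
  if (igraph::vcount(g) < nv)
    g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  memb <- igraph::components(g)$membership
  fcomp <- memb[mesh$faces[, 1]]
  keep_comp <- as.integer(names(which.max(table(fcomp))))
  fkeep <- fcomp == keep_comp
  faces <- mesh$faces[fkeep, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nv)
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[faces], ncol = 3L), unit = mesh$unit)
}

# drop zero-area faces
.drop_degenerate <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(mesh)
  fg <- face_geometry(mesh)
  keep <- fg$area > 0
  if (all(keep)) return(mesh)
  triangle_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE], unit = mesh$unit)
}

#' Flip the winding order of every face
#' @param mesh a [triangle_mesh()].
#' @return mesh with reversed orientation.
#' @export
flip_faces <- function(mesh) {
  triangle_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2), drop = FALSE],
                unit = mesh$unit)
}
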