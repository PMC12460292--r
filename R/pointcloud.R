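#' Construct a point cloud
#'
#' A `point_cloud` is an n x 3 numeric matrix of coordinates with a declared
#' length unit and a free-text sample id. All downstream volume reporting is
#' in cm^3 regardless of the cloud unit; geometry is carried in the input unit
#' and converted only at the volume-reporting boundary.
#'
#' @param points numeric matrix (or coercible) with 3 columns (x, y, z).
#' @param unit length unit of the coordinates, one of `"m"`, `"cm"`, `"mm"`.
#' @param id sample label.
#' @param extra optional data.frame of additional per-point attributes
#'   (e.g. intensity, color) preserved through I/O but never required.
#' @return object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), unit = "cm")
#' n_points(pc)
#' @export
point_cloud <- function(points, unit = c("m", "cm", "mm"), id = "", extra = NULL) {
  unit <- match.arg(unit)
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) stop("points must have exactly 3 columns (x, y, z)")
  storage.mode(pts) <- "double"
  if (nrow(pts) < 1L) stop("empty point cloud: at least 1 point required")
  if (!all(is.finite(pts))) stop("all coordinates must be finite")
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    if (nrow(extra) != nrow(pts)) stop("extra attributes must match point count")
  }
  structure(list(points = pts, unit = unit, id = as.character(id)[1],
                 extra = extra),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud '%s': %d points [%s]\n", x$id, nrow(x$points), x$unit))
  rng <- apply(x$points, 2, range)
  cat(sprintf("  x: [%.6g, %.6g]  y: [%.6g, %.6g]  z: [%.6g, %.6g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  if (!is.null(x$extra))
    cat("  extra:", paste(names(x$extra), collapse = ", "), "\n")
  if (!is.null(attr(x, "normals"))) cat("  normals: present\n")
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

# length-unit factor to centimetres
unit_to_cm <- function(unit) {
  switch(unit, m = 100, cm = 1, mm = 0.1,
         stop("unknown unit: ", unit))
}

#' Convert a point cloud to another length unit
#'
#' Multiplies every coordinate by the exact ratio of unit factors
#' (m to cm is exactly 100); volumes scale with the cube of the factor.
#'
#' @param cloud a `point_cloud`.
#' @param unit target unit, one of `"m"`, `"cm"`, `"mm"`.
#' @return converted `point_cloud`.
#' @export
convert_unit <- function(cloud, unit = c("m", "cm", "mm")) {
  unit <- match.arg(unit)
  fac <- unit_to_cm(cloud$unit) / unit_to_cm(unit)
  out <- cloud
  out$points <- cloud$points * fac
  out$unit <- unit
  nrm <- attr(cloud, "normals")
  if (!is.null(nrm)) attr(out, "normals") <- nrm  # unit vectors, unchanged
  out
}

#' Per-point normals of an oriented cloud
#' @param cloud a `point_cloud` carrying normals (see [estimate_normals()]).
#' @return n x 3 matrix of unit normals, or `NULL` if absent.
#' @export
cloud_normals <- function(cloud) attr(cloud, "normals")

# internal: attach normals (n x 3, unit length) to a cloud
set_normals <- function(cloud, normals) {
  normals <- as.matrix(normals)
  stopifnot(nrow(normals) == n_points(cloud), ncol(normals) == 3L)
  dimnames(normals) <- list(NULL, c("nx", "ny", "nz"))
  attr(cloud, "normals") <- normals
  class(cloud) <- unique(c("oriented_point_cloud", class(cloud)))
  cloud
}
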