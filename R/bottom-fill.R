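## Bottom-surface repair of ground-occluded disc scans.
##
## A disc resting on the ground cannot be scanned from below, so its base is
## missing from the cloud. The repair duplicates every original point onto
## the horizontal plane through the cloud's minimum Z (the gravity axis is Z
## by convention), keeping X and Y unchanged, and merges the projected set
## with the original. Projecting *all* points (not just the rim) makes the
## base a dense filled plane, which is what the downstream normal estimation
## and reconstruction expect.

#' Minimum Z of a point cloud
#'
#' The reference height of the ground-contact plane: the global minimum of
#' the Z coordinates over all points.
#'
#' @param cloud a [point_cloud()].
#' @return the minimum z value, in the cloud unit.
#' @export
detect_lowest <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) < 1L) stop("empty point cloud")
  min(cloud$points[, 3])
}

#' Project a cloud vertically onto a base plane
#'
#' Returns a cloud of the same cardinality whose i-th point is
#' (x_i, y_i, z_min): X/Y positions are retained and Z is set to the base
#' height. `z_min` must not exceed the lowest point of the cloud (that would
#' create an interior plane).
#'
#' @param cloud a [point_cloud()].
#' @param z_min base plane height, in the cloud unit; defaults to
#'   [detect_lowest()].
#' @return projected [point_cloud()].
#' @export
project_to_base <- function(cloud, z_min = detect_lowest(cloud)) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (z_min > min(cloud$points[, 3]) + 1e-12 * max(1, abs(z_min)))
    stop("z_min lies above the lowest point; projection would create an interior plane")
  pts <- cloud$points
  pts[, 3] <- z_min
  point_cloud(pts, unit = cloud$unit, id = cloud$id)
}

#' Repair the missing bottom face of a disc cloud
#'
#' Duplicates all points onto the minimum-Z plane and merges the projection
#' with the original cloud. Projected points that coincide with an original
#' point within `dedupe_tol` (Euclidean XYZ distance) are dropped before the
#' union, so points already lying exactly on the base plane are not
#' duplicated; set `dedupe_tol = NULL` to keep the literal both-copies union.
#' Projected points carry no normals; normals are estimated afterwards on the
#' complete cloud.
#'
#' @param cloud a [point_cloud()].
#' @param dedupe_tol non-negative distance in the cloud unit (default 0:
#'   exact-duplicate removal), or `NULL` to disable deduplication.
#' @return a `filled_cloud` list with elements `original`, `projected`
#'   (after deduplication), `complete`, `z_min`, and counts for audit.
#' @export
fill_bottom <- function(cloud, dedupe_tol = 0) {
  stopifnot(inherits(cloud, "point_cloud"))
  z_min <- detect_lowest(cloud)
  proj <- project_to_base(cloud, z_min)
  keep <- rep(TRUE, n_points(proj))
  if (!is.null(dedupe_tol)) {
    if (dedupe_tol < 0) stop("dedupe_tol must be >= 0 or NULL")
    nn <- .knn_search_cpp(cloud$points, proj$points, 1L)
    keep <- nn$dist[, 1] > dedupe_tol
  }
  proj_kept <- proj$points[keep, , drop = FALSE]
  complete <- point_cloud(rbind(cloud$points, proj_kept),
                          unit = cloud$unit, id = cloud$id)
  structure(list(original = cloud,
                 projected = if (any(keep))
                   point_cloud(proj_kept, unit = cloud$unit, id = cloud$id)
                 else NULL,
                 complete = complete,
                 z_min = z_min,
                 n_original = n_points(cloud),
                 n_projected = sum(keep),
                 n_complete = n_points(complete)),
            class = "filled_cloud")
}

#' @export
print.filled_cloud <- function(x, ...) {
  cat(sprintf("filled_cloud: %d original + %d projected = %d points (z_min = %.6g %s)\n",
              x$n_original, x$n_projected, x$n_complete, x$z_min,
              x$original$unit))
  invisible(x)
}
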