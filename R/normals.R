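## Per-point normal estimation by local quadratic-patch least squares, with
## globally consistent orientation by sign propagation over a minimum
## spanning tree of the k-nearest-neighbour graph.

#' Least-squares quadratic patch fit
#'
#' Fits z = a x^2 + b y^2 + c xy + d x + e y + f to a neighbourhood given in
#' local coordinates (the frame is chosen by the caller; [estimate_normals()]
#' uses a per-point PCA frame whose least-variance axis is the local z). At
#' least 6 points are required for the 6 unknowns.
#'
#' @param xyz numeric matrix (>= 6 x 3) of local coordinates.
#' @return object of class `quadratic_patch`: list with `coef`
#'   (a, b, c, d, e, f) and `residual_rms`.
#' @export
fit_quadratic_patch <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 6L) stop("quadratic patch needs at least 6 points")
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  A <- cbind(x^2, y^2, x * y, x, y, 1)
  qrA <- qr(A)
  if (qrA$rank < 6L)
    stop("degenerate neighbourhood: quadratic design matrix is rank-deficient")
  coef <- qr.coef(qrA, z)
  names(coef) <- c("a", "b", "c", "d", "e", "f")
  res <- z - A %*% coef
  structure(list(coef = coef,
                 residual_rms = sqrt(mean(res^2))),
            class = "quadratic_patch")
}

#' Surface normal of a quadratic patch
#'
#' The gradient of z(x, y) gives the (unnormalised) normal
#' (-dz/dx, -dz/dy, 1) = (-(2ax + cy + d), -(2by + cx + e), 1); at the origin
#' this is (-d, -e, 1). The unit z-component guarantees a nonzero vector.
#'
#' @param patch a `quadratic_patch` (or its coefficient vector).
#' @param at evaluation point (x, y) in the local frame, default the origin.
#' @return unit 3-vector in the local frame.
#' @export
patch_normal <- function(patch, at = c(0, 0)) {
  cf <- if (inherits(patch, "quadratic_patch")) patch$coef else patch
  n <- c(-(2 * cf[[1]] * at[1] + cf[[3]] * at[2] + cf[[4]]),
         -(2 * cf[[2]] * at[2] + cf[[3]] * at[1] + cf[[5]]),
         1)
  n / sqrt(sum(n^2))
}

#' Estimate per-point normals (signs unoriented)
#'
#' For every point, the point and its `k` nearest neighbours are expressed in
#' a local PCA frame (least-variance axis as local z) and a quadratic patch is
#' fitted by least squares; the patch normal at the query point is rotated
#' back to the global frame. The default k = 6 makes the 6-unknown fit use 7
#' points. Degenerate neighbourhoods fall back to the covariance (PCA) normal
#' and are flagged in `attr(cloud, "normal_fallbacks")`.
#' `method = "covariance"` computes plain PCA normals (the k = 8 covariance
#' variant used by some reconstruction stages).
#'
#' Normal signs are arbitrary until [orient_normals_mst()] is applied.
#'
#' @param cloud a [point_cloud()] with at least k + 1 points.
#' @param k neighbour count (default 6).
#' @param method `"quadratic"` (default) or `"covariance"`.
#' @return the cloud with unit normals attached ([cloud_normals()]).
#' @export
estimate_normals <- function(cloud, k = 6L, method = c("quadratic", "covariance")) {
  stopifnot(inherits(cloud, "point_cloud"))
  method <- match.arg(method)
  k <- as.integer(k)
  if (method == "quadratic" && k < 6L)
    stop("quadratic patch fitting needs k >= 6 (6 unknowns)")
  if (n_points(cloud) < k + 1L) stop("cloud must have at least k + 1 points")
  res <- .estimate_normals_cpp(cloud$points, k,
                               if (method == "quadratic") 0L else 1L)
  out <- set_normals(cloud, res$normals)
  attr(out, "normal_fallbacks") <- which(res$fallback)
  attr(out, "normal_residual_rms") <- res$residual_rms
  out
}

#' Orient normals consistently via a minimum spanning tree
#'
#' Builds the k-nearest-neighbour graph, weights each edge (i, j) by
#' 1 - |n_i . n_j|, extracts the minimum spanning tree and propagates the
#' normal sign from a root by breadth-first traversal, flipping a normal
#' whenever it disagrees with its tree parent. Propagation across a sharp
#' crease (e.g. the 90-degree junction between a disc wall and its filled
#' base, where adjacent normals are orthogonal) carries no sign information,
#' so after propagation the outward convention is enforced regionally: a
#' point is flipped when its neighbourhood-averaged outwardness score
#' (p - centroid) . n is negative — exact for solids star-shaped about their
#' centroid, which stem discs are. Disconnected graphs are oriented per
#' component with a warning.
#'
#' @param cloud a cloud with normals (see [estimate_normals()]).
#' @param k_graph neighbour count for the propagation graph (default 10).
#' @return the cloud with consistently oriented outward normals; on every
#'   MST edge (i, j) away from creases, `n_i . n_j >= 0`.
#' @export
orient_normals_mst <- function(cloud, k_graph = 10L) {
  nrm <- cloud_normals(cloud)
  if (is.null(nrm)) stop("cloud has no normals; run estimate_normals() first")
  n <- n_points(cloud)
  if (n == 1L) {
    # root rule only: outward = away from centroid (of a single point this is
    # undefined; keep the normal as-is)
    return(cloud)
  }
  k_graph <- min(as.integer(k_graph), n - 1L)
  nn <- .knn_search_cpp(cloud$points, cloud$points, k_graph + 1L)
  from <- rep(seq_len(n), k_graph)
  to <- as.vector(nn$idx[, -1, drop = FALSE])
  dot <- abs(rowSums(nrm[from, , drop = FALSE] * nrm[to, , drop = FALSE]))
  w <- 1 - pmin(dot, 1)
  el <- cbind(pmin(from, to), pmax(from, to))
  keyed <- !duplicated(el)
  g <- igraph::graph_from_edgelist(el[keyed, , drop = FALSE], directed = FALSE)
  igraph::E(g)$weight <- w[keyed]
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))

  comps <- igraph::components(g)
  if (comps$no > 1L)
    warning(sprintf("kNN graph has %d components; orienting each independently",
                    comps$no))
  mstree <- igraph::mst(g)
  flip <- rep(FALSE, n)
  ctr <- colMeans(cloud$points)
  for (comp in seq_len(comps$no)) {
    members <- which(comps$membership == comp)
    # root: highest point of the component (deterministic tie-break by index)
    root <- members[order(-cloud$points[members, 3], members)[1]]
    bfs <- igraph::bfs(mstree, root = root, unreachable = FALSE,
                       father = TRUE, order = TRUE)
    ord <- as.integer(bfs$order)
    ord <- ord[!is.na(ord)]
    father <- as.integer(bfs$father)
    for (v in ord) {
      p <- father[v]
      if (is.na(p) || p == 0L) next
      np <- nrm[p, ] * (if (flip[p]) -1 else 1)
      nv <- nrm[v, ]
      if (sum(np * nv) < 0) flip[v] <- TRUE
    }
  }

  # outward convention, applied regionally: MST propagation makes smooth
  # regions internally consistent, but the relative sign across a sharp
  # crease (wall vs filled base: orthogonal normals) carries no pairwise
  # information and an entire region can come out inverted. For a solid that
  # is star-shaped about its centroid (any stem disc, including rough bark),
  # the outward normal satisfies (p - c) . n > 0, so each point's outwardness
  # score, averaged over its graph neighbourhood to be robust to single
  # noisy normals, decides the regional sign.
  signs <- ifelse(flip, -1, 1)
  score <- rowSums((cloud$points - matrix(ctr, n, 3, byrow = TRUE)) *
                     (nrm * signs))
  nbr <- matrix(score[nn$idx[, -1, drop = FALSE]], nrow = n)
  smoothed <- (score + rowSums(nbr)) / (k_graph + 1)
  flip <- xor(flip, smoothed < 0)
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  set_normals(cloud, nrm)
}
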