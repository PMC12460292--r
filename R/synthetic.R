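## Synthetic TLS disc scans with analytically known volume.
##
## The generator emulates the acquisition conditions the pipeline is meant
## for: ~5 cm thick stem discs scanned at >= 1000 points/dm^2 from three
## stations (northeast, southeast, west), resting on the ground so the bottom
## face is occluded, with millimetre-scale ranging noise and species-like
## bark roughness. Bark ridges run vertically: the radial roughness field
## depends on the azimuth only, so the solid is a prism and its true volume
## is the cross-section area times the height.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Specification of a synthetic disc scan
#'
#' @param radius_a,radius_b semi-axes of the elliptical cross-section, cm
#'   (default 15, a typical disc from a 15-45 cm DBH stem).
#' @param height disc thickness in cm (default 5: discs are cut to
#'   5 +/- 0.5 cm).
#' @param bark_amplitude standard deviation of the radial bark roughness, cm
#'   (default 0: smooth). Species-like values run to ~1 cm for coarse bark.
#' @param bark_correlation angular correlation length of the roughness field
#'   in degrees (default 15).
#' @param density areal sampling density in points per dm^2 (default 1000,
#'   the scanning floor).
#' @param stations scanner azimuths in degrees (default c(45, 135, 270):
#'   northeast, southeast, west).
#' @param station_fov angular half-aperture per station in degrees: a wall
#'   point is visible if some station lies within this azimuthal distance
#'   (default 100).
#' @param sensor_noise isotropic per-point Gaussian noise sd in cm
#'   (default 0.1, the +/- 1 mm ranging error class).
#' @param occlude_bottom drop the ground-contact bottom face (default TRUE).
#' @param seed integer seed making the disc reproducible.
#' @return list of class `disc_spec`.
#' @export
disc_spec <- function(radius_a = 15, radius_b = radius_a, height = 5,
                      bark_amplitude = 0, bark_correlation = 15,
                      density = 1000, stations = c(45, 135, 270),
                      station_fov = 100, sensor_noise = 0.1,
                      occlude_bottom = TRUE, seed = 1L) {
  if (radius_a <= 0 || radius_b <= 0 || height <= 0 || density <= 0)
    stop("radii, height and density must be positive")
  if (bark_amplitude < 0) stop("bark_amplitude must be >= 0")
  structure(list(radius_a = radius_a, radius_b = radius_b, height = height,
                 bark_amplitude = bark_amplitude,
                 bark_correlation = bark_correlation,
                 density = density, stations = stations,
                 station_fov = station_fov, sensor_noise = sensor_noise,
                 occlude_bottom = isTRUE(occlude_bottom),
                 seed = as.integer(seed)),
            class = "disc_spec")
}

# ellipse radius at azimuth theta
.ellipse_radius <- function(a, b, theta) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# smooth periodic zero-mean unit-variance random field on the circle:
# Fourier series with squared-exponential spectral decay at correlation
# length ell (radians)
.circle_gp <- function(ell, mmax = 180L) {
  m <- seq_len(mmax)
  sig <- exp(-(m * ell)^2 / 4)
  keep <- sig > 1e-8
  m <- m[keep]; sig <- sig[keep]
  if (!length(m)) { m <- 1L; sig <- 1 }
  a <- rnorm(length(m), 0, sig)
  b <- rnorm(length(m), 0, sig)
  norm <- sqrt(sum(sig^2))
  function(theta) {
    M <- outer(theta, m)
    as.vector(cos(M) %*% a + sin(M) %*% b) / norm
  }
}

# realized radius function of a disc spec (roughened ellipse)
.radius_fn <- function(spec, gp) {
  function(theta) {
    r <- .ellipse_radius(spec$radius_a, spec$radius_b, theta)
    if (spec$bark_amplitude > 0) r <- r + spec$bark_amplitude * gp(theta)
    pmax(r, 0.05 * min(spec$radius_a, spec$radius_b))
  }
}

#' True volume of a realized disc profile
#'
#' Cross-section area of the (roughened) radial profile by polygonal
#' integration, times the height. The polygon resolution converges quickly:
#' doubling `n_vertices` changes the value by well under 0.01%.
#'
#' @param spec a [disc_spec()].
#' @param realization the `realization` element of a [generate_disc()]
#'   result (or `NULL` for the smooth ellipse).
#' @param n_vertices polygon resolution (default 3600).
#' @return volume in cm^3.
#' @export
true_profile_volume <- function(spec, realization = NULL, n_vertices = 3600L) {
  rf <- if (is.null(realization)) {
    function(theta) .ellipse_radius(spec$radius_a, spec$radius_b, theta)
  } else realization$radius_fn
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- rf(theta)
  x <- r * cos(theta); y <- r * sin(theta)
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  area * spec$height
}

#' Generate a synthetic disc scan
#'
#' Samples the lateral wall, the top face and (unless occluded) the bottom
#' face at the requested areal density, applies the realized bark roughness
#' (identical at all heights: ridges run vertically), removes wall points not
#' visible from any station, and adds isotropic sensor noise. Rough bark also
#' degrades the returns themselves: ridge flanks scatter the beam diffusely
#' (inflated ranging noise), deep grooves shadow it (dropouts, uneven
#' density) and multiple reflections inside a groove lengthen the measured
#' range (returns displaced inward by a cavity-scale amount) — so estimation
#' error grows with bark amplitude, with an underestimation tendency, while a
#' smooth disc is unaffected. When the bottom is occluded the cloud is also
#' cropped at the ground plane (z = 0), emulating the separation of the disc
#' from the ground returns. The true volume is that of the realized roughened
#' solid — the quantity a water displacement measurement would return — not
#' of the nominal ellipse.
#'
#' @param spec a [disc_spec()].
#' @return list of class `synthetic_disc` with elements `cloud` (a
#'   [point_cloud()] in cm), `true_volume` (cm^3), `spec`, and `realization`
#'   (the realized radius function, for [true_profile_volume()]).
#' @export
generate_disc <- function(spec) {
  stopifnot(inherits(spec, "disc_spec"))
  .with_seed(spec$seed, {
    gp <- .circle_gp(spec$bark_correlation * pi / 180)
    rf <- .radius_fn(spec, gp)
    realization <- list(radius_fn = rf)

    M <- 3600L
    theta <- seq(0, 2 * pi, length.out = M + 1L)[-(M + 1L)]
    r <- rf(theta)
    px <- r * cos(theta); py <- r * sin(theta)
    seg <- sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2)
    perimeter <- sum(seg)
    area_top <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
    h <- spec$height
    dens_cm2 <- spec$density / 100  # points per cm^2

    # lateral wall: azimuth by arc length, height uniform
    n_wall <- max(1L, round(dens_cm2 * perimeter * h))
    segi <- sample.int(M, n_wall, replace = TRUE, prob = seg)
    frac <- runif(n_wall)
    th_w <- theta[segi] + frac * (2 * pi / M)
    r_w <- rf(th_w)
    wall <- cbind(r_w * cos(th_w), r_w * sin(th_w), runif(n_wall, 0, h))

    # bark-sensor coupling: rough bark degrades the returns, not just the
    # geometry. Ridge flanks (high local profile slope) scatter the beam
    # diffusely -> inflated ranging noise; deep grooves shadow the beam ->
    # dropouts ("voids", uneven density); and multiple reflections inside a
    # groove lengthen the measured range, displacing returns inward by a
    # cavity-scale amount. All three scale with the realized roughness
    # field, so a smooth disc is unaffected.
    wall_noise_mult <- rep(1, n_wall)
    if (spec$bark_amplitude > 0) {
      dth <- 1e-3
      slope <- abs(rf(th_w + dth) - rf(th_w - dth)) / (2 * dth) / pmax(r_w, 1e-6)
      depth <- pmax(0, .ellipse_radius(spec$radius_a, spec$radius_b, th_w) - r_w)
      shadow <- depth / (2 * spec$bark_amplitude)
      p_drop <- pmin(0.8, 1.5 * slope^2 + 0.6 * shadow * pmin(1, slope / 0.2))
      keep_ret <- runif(n_wall) > p_drop
      wall <- wall[keep_ret, , drop = FALSE]
      wall_noise_mult <- (1 + 4 * slope)[keep_ret]
      n_wall <- nrow(wall)
      th_w <- th_w[keep_ret]
      depth <- depth[keep_ret]
      shadow <- shadow[keep_ret]
      r_w <- r_w[keep_ret]
      mp <- runif(n_wall) < pmin(0.9, 1.2 * shadow)
      if (any(mp)) {
        disp <- abs(rnorm(sum(mp), 0, depth[mp]))
        wall[mp, 1:2] <- wall[mp, 1:2, drop = FALSE] *
          (1 - disp / pmax(r_w[mp], 1e-6))
      }
    }

    # visibility: azimuthal distance to the nearest station
    st <- spec$stations * pi / 180
    ang_dist <- sapply(st, function(s) {
      d <- abs((th_w - s) %% (2 * pi))
      pmin(d, 2 * pi - d)
    })
    vis <- apply(ang_dist, 1, min) <= spec$station_fov * pi / 180
    wall <- wall[vis, , drop = FALSE]
    wall_noise_mult <- wall_noise_mult[vis]

    sample_face <- function(z) {
      n_face <- max(1L, round(dens_cm2 * area_top))
      rmax <- max(r)
      out <- matrix(0, 0, 3)
      while (nrow(out) < n_face) {
        n_try <- ceiling((n_face - nrow(out)) * 4 * rmax^2 / area_top * 1.2) + 16L
        x <- runif(n_try, -rmax, rmax); y <- runif(n_try, -rmax, rmax)
        th <- atan2(y, x) %% (2 * pi)
        inside <- sqrt(x^2 + y^2) <= rf(th)
        out <- rbind(out, cbind(x[inside], y[inside], z))
      }
      out[seq_len(n_face), , drop = FALSE]
    }
    top <- sample_face(h)
    bottom <- if (!spec$occlude_bottom) sample_face(0) else NULL

    pts <- rbind(wall, top, bottom)
    if (nrow(pts) < 100L)
      stop("density too low: fewer than 100 points generated")
    if (spec$sensor_noise > 0) {
      sdv <- spec$sensor_noise *
        c(wall_noise_mult, rep(1, nrow(pts) - nrow(wall)))
      pts <- pts + matrix(rnorm(length(pts), 0, sdv), ncol = 3L)
    }
    # ground crop: a disc resting on the ground is separated from the ground
    # returns by cropping at the ground plane, so no point of the disc cloud
    # survives below z = 0 (the min-Z points end up on the wall rim)
    if (spec$occlude_bottom) pts <- pts[pts[, 3] >= 0, , drop = FALSE]
    cloud <- point_cloud(pts, unit = "cm",
                         id = sprintf("synthetic_disc_seed%d", spec$seed))
    structure(list(cloud = cloud,
                   true_volume = area_top * h,
                   spec = spec,
                   realization = realization),
              class = "synthetic_disc")
  })
}

#' @export
print.synthetic_disc <- function(x, ...) {
  cat(sprintf("synthetic_disc: %d points, true volume %.2f cm3 (seed %d)\n",
              n_points(x$cloud), x$true_volume, x$spec$seed))
  invisible(x)
}

#' Generate a paired-volume validation table
#'
#' Draws per-species reference volumes, simulates three replicate
#' water-displacement measurements around each true value, and produces the
#' TLS estimate as truth + bias + Gaussian noise. The default species mix
#' mirrors a four-species validation campaign (n = 69/25/12/17, species mean
#' volumes 146.78/205.99/148.62/236.68 cm^3). Non-positive draws are
#' resampled (capped).
#'
#' @param species_specs data.frame with columns `species`, `n`,
#'   `mean_volume` (cm^3), `volume_spread` (sd of the species volume
#'   distribution, cm^3), `bias` (cm^3, added to the estimate) and
#'   `noise_sd` (cm^3, estimate noise). Defaults described above with
#'   spread = 40% of the mean, bias 0 and noise_sd 25.
#' @param replicate_sd sd of the replicate measurement error, cm^3
#'   (default 2).
#' @param seed integer seed.
#' @return a `disc_samples` data.frame (see [read_samples_table()]).
#' @export
generate_paired_dataset <- function(species_specs = NULL, replicate_sd = 2,
                                    seed = 1L) {
  if (is.null(species_specs)) {
    species_specs <- data.frame(
      species = c("species_A", "species_B", "species_C", "species_D"),
      n = c(69L, 25L, 12L, 17L),
      mean_volume = c(146.78, 205.99, 148.62, 236.68),
      stringsAsFactors = FALSE)
  }
  if (is.null(species_specs$volume_spread))
    species_specs$volume_spread <- 0.4 * species_specs$mean_volume
  if (is.null(species_specs$bias)) species_specs$bias <- 0
  if (is.null(species_specs$noise_sd)) species_specs$noise_sd <- 25
  if (any(species_specs$n < 2L)) stop("need n >= 2 per species")

  draw_pos <- function(n, fn) {
    out <- fn(n)
    for (i in seq_len(100L)) {
      bad <- out <= 0
      if (!any(bad)) break
      out[bad] <- fn(sum(bad))
    }
    if (any(out <= 0)) stop("resample cap reached: distribution mass at <= 0 too large")
    out
  }

  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(species_specs)), function(i) {
      sp <- species_specs[i, ]
      truth <- draw_pos(sp$n, function(m) rnorm(m, sp$mean_volume, sp$volume_spread))
      reps <- vapply(truth, function(t)
        draw_pos(3L, function(m) rnorm(m, t, replicate_sd)), numeric(3))
      est <- truth + sp$bias + rnorm(sp$n, 0, sp$noise_sd)
      for (it in seq_len(100L)) {
        bad <- est <= 0
        if (!any(bad)) break
        est[bad] <- truth[bad] + sp$bias + rnorm(sum(bad), 0, sp$noise_sd)
      }
      if (any(est <= 0)) stop("resample cap reached for estimated volumes")
      data.frame(id = sprintf("%s_%03d", sp$species, seq_len(sp$n)),
                 species = sp$species,
                 estimated_volume = est,
                 rep1 = reps[1, ], rep2 = reps[2, ], rep3 = reps[3, ],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$reference_volume <- rowMeans(out[, c("rep1", "rep2", "rep3")])
    rownames(out) <- NULL
    class(out) <- c("disc_samples", "data.frame")
    out
  })
}
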