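## Rendering of the physical larva model.
##
## Images are stored as numeric matrices indexed [x + 1, y + 1] with 0-based
## pixel coordinates, pixel centres on integers, x right and y down
## (transpose before writing with png/tiff). A rendered view is a crop of the
## full sensor: crop_px = sensor_px - origin.

.render_cache <- new.env(parent = emptyenv())

## Organ means (rows: eye1, eye2, head, belly), sigmas and brightness in the
## fish frame (head at origin, X anterior->posterior, Y left, Z dorsal).
## Placements and dimensions scale linearly with L relative to a 4 mm larva.
anterior_organs <- function(fixed, length) {
  s <- length / 4.0
  mu <- rbind(
    c(fixed$eye_along, fixed$eye_dist, fixed$eye_perp),
    c(fixed$eye_along, -fixed$eye_dist, fixed$eye_perp),
    c(fixed$head_along, 0, fixed$head_perp),
    c(fixed$belly_along, 0, fixed$belly_perp)) * s
  sig <- rbind(fixed$eye_dims, fixed$eye_dims, fixed$head_dims,
               fixed$belly_dims) * s / 4
  bright <- c(fixed$brightness["eye"], fixed$brightness["eye"],
              fixed$brightness["head"], fixed$brightness["belly"]) / 255
  list(mu = mu, sigma = sig, bright = unname(bright))
}

## max over organs of brightness-scaled Gaussian densities at fish-frame pts
anterior_intensity <- function(pts, organs) {
  v <- rep(0, nrow(pts))
  for (k in seq_len(nrow(organs$mu))) {
    q <- ((pts[, 1L] - organs$mu[k, 1L]) / organs$sigma[k, 1L])^2 +
      ((pts[, 2L] - organs$mu[k, 2L]) / organs$sigma[k, 2L])^2 +
      ((pts[, 3L] - organs$mu[k, 3L]) / organs$sigma[k, 3L])^2
    v <- pmax(v, organs$bright[k] * exp(-0.5 * q))
  }
  v
}

## Fish-frame voxel cloud of the anterior (cached): positions (n x 3, mm
## relative to the head) and intensities. Voxels below `floor` of the peak
## are dropped.
anterior_cloud <- function(fixed, length, pitch, floor = 1e-3) {
  key <- paste(signif(unlist(fixed[sapply(fixed, is.numeric)]), 8),
               signif(length, 8), signif(pitch, 8), collapse = "_")
  hit <- .render_cache[[key]]
  if (!is.null(hit)) return(hit)
  org <- anterior_organs(fixed, length)
  lo <- apply(org$mu - 3.5 * org$sigma, 2L, min)
  hi <- apply(org$mu + 3.5 * org$sigma, 2L, max)
  ax <- lapply(1:3, function(j) seq(lo[j], hi[j], by = pitch))
  pts <- as.matrix(expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]]))
  val <- anterior_intensity(pts, org)
  keep <- val > floor * max(val)
  out <- list(pts = pts[keep, , drop = FALSE], val = val[keep], pitch = pitch)
  .render_cache[[key]] <- out
  out
}

#' Voxel intensity model of the larval anterior
#'
#' Evaluates the anterior intensity profile V = max over the four organ
#' Gaussians (two eyes, head, belly) on a regular lab-frame voxel grid
#' covering the anterior bounding box.
#'
#' @param pose a \code{fish_pose}.
#' @param fixed a \code{fish_body_params}.
#' @param pitch voxel pitch, mm (default 0.015).
#' @return list with \code{x, y, z} (grid axes, lab mm) and \code{values}
#'   (3-D array, unit intensity scale).
#' @export
render_anterior_voxels <- function(pose, fixed = fish_body_params(),
                                   pitch = 0.015) {
  stopifnot(pitch > 0)
  org <- anterior_organs(fixed, pose$length)
  if (pitch > min(org$sigma[1L, ]) * 2)
    warning("voxel pitch too coarse: eyes span fewer than 2 voxels")
  R <- rot_z(pose$theta0) %*% rot_y(-pose$phi0) %*% rot_x(pose$gamma0)
  head <- c(pose$x0, pose$y0, pose$z0)
  corners <- as.matrix(expand.grid(
    x = range(org$mu[, 1L] + c(-4, 4) * max(org$sigma[, 1L])),
    y = range(org$mu[, 2L] + c(-4, 4) * max(org$sigma[, 2L])),
    z = range(org$mu[, 3L] + c(-4, 4) * max(org$sigma[, 3L]))))
  lab_corners <- corners %*% t(R) +
    matrix(head, nrow(corners), 3L, byrow = TRUE)
  ax <- lapply(1:3, function(j)
    seq(min(lab_corners[, j]), max(lab_corners[, j]), by = pitch))
  pts <- as.matrix(expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]]))
  fish_pts <- (pts - matrix(head, nrow(pts), 3L, byrow = TRUE)) %*% R
  v <- anterior_intensity(fish_pts, org)
  list(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]],
       values = array(v, vapply(ax, length, integer(1L))))
}

## Project lab points into a view: k-th camera of either a fitted refractive
## projection or a list of linear cameras.
project_to_view <- function(proj, k, points) {
  if (is.null(dim(points))) points <- matrix(points, 1L)
  if (inherits(proj, "refractive_projection"))
    project_refractive(proj, points, cameras = k, check_domain = FALSE)[[1L]]
  else project_linear(proj[[k]], points)
}

n_views <- function(proj) {
  if (inherits(proj, "refractive_projection")) proj$n_cam else length(proj)
}

## Magnification (px per mm) of view k near a lab point, by finite difference
## along the two transverse axes.
view_magnification <- function(proj, k, at) {
  ax <- CAMERA_AXES[[k]]
  e <- matrix(0, 2L, 3L)
  e[1L, ax$u[1L]] <- 0.5
  e[2L, ax$v[1L]] <- 0.5
  p0 <- project_to_view(proj, k, at)
  p1 <- project_to_view(proj, k, at + e[1L, ])
  p2 <- project_to_view(proj, k, at + e[2L, ])
  (abs(p1[1L] - p0[1L]) + abs(p2[2L] - p0[2L]))  # mean of |du/dx|, |dv/dy| / 0.5mm *0.5
}

## Tail profile along backbone points 2..10: linear intensity 1.0 at the
## start of segment 2 down to 0.3 at the tail tip; transverse Gaussian sigma
## tapers to 0.6 of its base value (trapezoidal silhouette).
tail_profile <- function(fixed, length) {
  s_frac <- seq(0, 1, length.out = 9L)       # at backbone points 2..10
  list(intensity = 1.0 + (0.3 - 1.0) * s_frac,
       sigma_mm = fixed$tail_width_scale * length / 40 * (1 - 0.4 * s_frac))
}

## Intensity patch of one capsule segment (linear longitudinal profile,
## Gaussian transverse profile, disk end caps). Coordinates are 0-based crop
## pixels; returns NULL when the patch misses the image.
capsule_patch <- function(nx, ny, p_a, p_b, sig_a, sig_b, int_a, int_b) {
  len <- sqrt(sum((p_b - p_a)^2))
  pad <- ceiling(3 * max(sig_a, sig_b) + 1)
  x0 <- max(0L, floor(min(p_a[1L], p_b[1L])) - pad)
  x1 <- min(nx - 1L, ceiling(max(p_a[1L], p_b[1L])) + pad)
  y0 <- max(0L, floor(min(p_a[2L], p_b[2L])) - pad)
  y1 <- min(ny - 1L, ceiling(max(p_a[2L], p_b[2L])) + pad)
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(xs, length(xs), length(ys)) - p_a[1L]
  gy <- matrix(ys, length(xs), length(ys), byrow = TRUE) - p_a[2L]
  if (len < 1e-9) {
    s <- matrix(0, length(xs), length(ys))
    perp2 <- gx^2 + gy^2
  } else {
    u <- (p_b - p_a) / len
    t_ <- gx * u[1L] + gy * u[2L]
    s <- pmin(pmax(t_ / len, 0), 1)
    perp2 <- (gx - s * len * u[1L])^2 + (gy - s * len * u[2L])^2
  }
  sig <- sig_a + (sig_b - sig_a) * s
  list(xs = xs, ys = ys,
       val = (int_a + (int_b - int_a) * s) * exp(-perp2 / (2 * sig^2)))
}

draw_capsule <- function(img, p_a, p_b, sig_a, sig_b, int_a, int_b) {
  p <- capsule_patch(nrow(img), ncol(img), p_a, p_b, sig_a, sig_b,
                     int_a, int_b)
  if (is.null(p)) return(img)
  img[p$xs + 1L, p$ys + 1L] <- pmax(img[p$xs + 1L, p$ys + 1L], p$val)
  img
}

draw_tail <- function(img, pts2d, sigma_px, intensity) {
  nx <- nrow(img); ny <- ncol(img)
  for (i in 1:8) {
    p <- capsule_patch(nx, ny, pts2d[i, ], pts2d[i + 1L, ],
                       sigma_px[i], sigma_px[i + 1L],
                       intensity[i], intensity[i + 1L])
    if (is.null(p)) next
    img[p$xs + 1L, p$ys + 1L] <- pmax(img[p$xs + 1L, p$ys + 1L], p$val)
  }
  img
}

## Unnormalized accurate anterior projection: sum of voxel intensities per
## crop pixel (the voxel-sum projection contract).
project_anterior_raw <- function(pose, fixed, proj, k, origin, size,
                                 pitch = 0.03) {
  cloud <- anterior_cloud(fixed, pose$length, pitch)
  R <- rot_z(pose$theta0) %*% rot_y(-pose$phi0) %*% rot_x(pose$gamma0)
  head <- c(pose$x0, pose$y0, pose$z0)
  lab <- cloud$pts %*% t(R) + matrix(head, nrow(cloud$pts), 3L, byrow = TRUE)
  px <- project_to_view(proj, k, lab)
  ix <- round(px[, 1L] - origin[1L])
  iy <- round(px[, 2L] - origin[2L])
  keep <- ix >= 0 & ix < size & iy >= 0 & iy < size
  img <- matrix(0, size, size)
  if (!any(keep)) return(img)
  idx <- ix[keep] * size + iy[keep]
  acc <- rowsum(cloud$val[keep], idx)
  pos <- as.integer(rownames(acc))
  img[cbind(pos %/% size + 1L, pos %% size + 1L)] <- acc[, 1L]
  img
}

#' Render the camera views of a pose
#'
#' Renders the larva into per-camera crops. In \code{accurate} mode the
#' anterior is projected voxel-by-voxel through the projection function and
#' pixel intensities are the sums of voxel intensities; in \code{fast} mode
#' anterior and tail come from the sprite lookup table. The tail is drawn as
#' 8 trapezoid/disk capsule segments along the projected backbone with a
#' transverse Gaussian profile and a linear longitudinal intensity. Where
#' anterior and tail overlap the higher value wins, and each final view is
#' rescaled so its brightest pixel is 255 (8-bit).
#'
#' @param pose a \code{fish_pose}.
#' @param fixed a \code{fish_body_params}.
#' @param proj a \code{refractive_projection} or list of linear cameras.
#' @param mode \code{"accurate"} (voxel anterior) or \code{"fast"} (lookup
#'   sprites; requires \code{table}).
#' @param table a lookup table from [build_lookup_table_p()] (fast mode).
#' @param origins optional list of per-view crop origins (length-2, sensor
#'   px); defaults to centring the pose keypoints in each crop.
#' @param size crop side, px (default 141).
#' @param pitch voxel pitch for accurate anterior rendering, mm.
#' @param cameras which views to render.
#' @return an object of class \code{view_triplet}: \code{images} (list of
#'   size x size matrices, 0..255), \code{origins}, \code{keypoints} (list of
#'   12 x 2 crop-pixel matrices: 10 backbone then 2 eyes), \code{mode},
#'   \code{size}.
#' @export
render_views <- function(pose, fixed = fish_body_params(), proj,
                         mode = c("accurate", "fast"), table = NULL,
                         origins = NULL, size = 141L, pitch = 0.03,
                         cameras = seq_len(n_views(proj))) {
  mode <- match.arg(mode)
  if (mode == "fast" && is.null(table))
    stop("fast mode requires a lookup table (build_lookup_table_p)")
  coords <- pose_to_coordinates(pose, fixed)
  kp3d <- rbind(coords$backbone, coords$eyes)
  images <- vector("list", length(cameras))
  kps <- vector("list", length(cameras))
  orig_out <- vector("list", length(cameras))
  prof <- tail_profile(fixed, pose$length)
  bad <- integer(0)
  for (idx in seq_along(cameras)) {
    k <- cameras[idx]
    kp <- project_to_view(proj, k, kp3d)
    origin <- if (!is.null(origins)) origins[[idx]]
      else round(colMeans(kp)) - (size - 1) / 2
    kp_crop <- sweep(kp, 2L, origin)
    if (any(kp_crop < -0.5) || any(kp_crop > size - 0.5)) bad <- c(bad, k)
    mag <- view_magnification(proj, k, colMeans(kp3d))
    if (mode == "accurate") {
      ant <- project_anterior_raw(pose, fixed, proj, k, origin, size, pitch)
      if (max(ant) > 0) ant <- ant / max(ant)
      img <- draw_tail(ant, kp_crop[2:10, , drop = FALSE],
                       prof$sigma_mm * mag, prof$intensity)
    } else {
      img <- render_fast_view(table, k, pose, kp_crop, mag, size, size)
    }
    mx <- max(img)
    if (mx > 0) img <- img / mx
    images[[idx]] <- round(img * 255)
    kps[[idx]] <- kp_crop
    orig_out[[idx]] <- origin
  }
  if (length(bad) > 0)
    stop(sprintf("fish outside the field of view in camera(s) %s",
                 paste(sort(unique(bad)), collapse = ", ")))
  structure(list(images = images, origins = orig_out, keypoints = kps,
                 mode = mode, size = size, cameras = cameras),
            class = "view_triplet")
}

#' @export
print.view_triplet <- function(x, ...) {
  cat(sprintf("<view_triplet> %d view(s), %dx%d px, mode %s\n",
              length(x$images), x$size, x$size, x$mode))
  invisible(x)
}

#' Write the views of a triplet as PNG files
#'
#' @param triplet a \code{view_triplet}.
#' @param paths character vector of file paths, one per view.
#' @export
write_view_png <- function(triplet, paths) {
  stopifnot(length(paths) == length(triplet$images))
  for (i in seq_along(paths))
    png::writePNG(t(triplet$images[[i]]) / 255, paths[i])
  invisible(paths)
}
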