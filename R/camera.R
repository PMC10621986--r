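#' Pinhole camera model
#'
#' Linear (refraction-free) camera with intrinsics \code{fx, fy} (focal
#' lengths in pixels), principal point \code{(u0, v0)}, pixel skew, and
#' extrinsics \code{rotation} (3 x 3 orthonormal, lab to camera axes) and
#' \code{translation} (mm) so that \code{x_cam = R x_lab + t}. Pixels are
#' 0-based with centres at integer coordinates, x right, y down.
#'
#' @param fx,fy focal lengths, px; must be positive.
#' @param u0,v0 principal point, px.
#' @param skew pixel skew coefficient (default 0).
#' @param rotation 3 x 3 orthonormal matrix.
#' @param translation length-3 vector, mm.
#' @return an object of class \code{pinhole_camera}.
#' @export
pinhole_camera <- function(fx, fy, u0, v0, skew = 0,
                           rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(fx > 0, fy > 0)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal (R'R = I within 1e-9)")
  structure(list(fx = fx, fy = fy, u0 = u0, v0 = v0, skew = skew,
                 rotation = rotation, translation = as.numeric(translation)),
            class = "pinhole_camera")
}

intrinsic_matrix <- function(cam) {
  matrix(c(cam$fx, 0, 0,
           cam$skew, cam$fy, 0,
           cam$u0, cam$v0, 1), 3L, 3L)
}

#' 4 x 3 camera matrix (row-vector convention)
#'
#' Returns the matrix P such that \code{[u, v, 1] = [x, y, z, 1] P} (up to
#' scale), factorized as the product of the 4 x 3 extrinsic matrix and the
#' 3 x 3 intrinsic matrix.
#'
#' @param cam a \code{pinhole_camera}.
#' @return 4 x 3 numeric matrix.
#' @export
camera_matrix <- function(cam) {
  M <- rbind(t(cam$rotation), cam$translation)   # 4 x 3 extrinsic
  M %*% t(intrinsic_matrix(cam))
}

camera_center <- function(cam) drop(-crossprod(cam$rotation, cam$translation))

#' Orthographic camera model
#'
#' Affine projection at constant magnification: \code{u = mag * x_cam + u0},
#' used for telecentric-style views and for orthographic model rendering.
#'
#' @param mag magnification, px per mm.
#' @param u0,v0 image centre, px.
#' @param rotation 3 x 3 orthonormal matrix (lab to camera axes).
#' @param translation length-3 vector, mm.
#' @return an object of class \code{ortho_camera}.
#' @export
orthographic_camera <- function(mag, u0, v0, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(mag > 0)
  structure(list(mag = mag, u0 = u0, v0 = v0, rotation = rotation,
                 translation = as.numeric(translation)),
            class = "ortho_camera")
}

#' Project lab points through a linear camera
#'
#' @param cam a \code{pinhole_camera} or \code{ortho_camera}.
#' @param points numeric length-3 vector or n x 3 matrix, mm (lab frame).
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_linear <- function(cam, points) {
  if (is.null(dim(points))) points <- matrix(points, 1L)
  stopifnot_finite(points)
  xc <- points %*% t(cam$rotation) +
    matrix(cam$translation, nrow(points), 3L, byrow = TRUE)
  if (inherits(cam, "ortho_camera"))
    return(cbind(cam$mag * xc[, 1L] + cam$u0, cam$mag * xc[, 2L] + cam$v0))
  if (any(xc[, 3L] <= 0))
    stop("point behind the camera plane")
  u <- (cam$fx * xc[, 1L] + cam$skew * xc[, 2L]) / xc[, 3L] + cam$u0
  v <- cam$fy * xc[, 2L] / xc[, 3L] + cam$v0
  cbind(u, v)
}

#' Tank optics for the ray-tracing simulator
#'
#' Geometry and refractive indices of the cubic glass tank, used by
#' [simulate_refraction()] as an independent physical oracle for the empirical
#' projection fit. Each camera views the tank through one flat glass face
#' whose normal is the camera principal axis.
#'
#' @param side inner tank side length, mm.
#' @param glass glass wall thickness, mm.
#' @param n_air,n_glass,n_water refractive indices.
#' @param cam_distance camera centre to tank centre distance, mm.
#' @param focal_mm lens focal length, mm.
#' @param pixel_um sensor pixel pitch, micrometres.
#' @param sensor sensor size (width, height), px.
#' @return an object of class \code{tank_optics}.
#' @export
tank_optics <- function(side = 70, glass = 2.5,
                        n_air = 1.0, n_glass = 1.52, n_water = 1.33,
                        cam_distance = 250, focal_mm = 35, pixel_um = 7.4,
                        sensor = c(648, 488)) {
  stopifnot(side > 0, glass > 0, cam_distance > side / 2 + glass,
            n_air == 1.0 || n_air > 0, n_glass >= 1, n_water >= 1)
  structure(list(side = side, glass = glass, n_air = n_air,
                 n_glass = n_glass, n_water = n_water,
                 cam_distance = cam_distance, focal_mm = focal_mm,
                 pixel_um = pixel_um, sensor = sensor),
            class = "tank_optics")
}

## Axis bookkeeping for the canonical three-camera layout: camera k looks
## along lab axis +k; image x/y axes map to the listed transverse lab axes
## (sign included). depth = lab axis index along the principal axis.
CAMERA_AXES <- list(
  list(depth = 3L, u = c(1L, +1), v = c(2L, +1)),  # bottom, looks along +z
  list(depth = 1L, u = c(2L, +1), v = c(3L, +1)),  # side, looks along +x
  list(depth = 2L, u = c(1L, +1), v = c(3L, -1))   # side, looks along +y
)

#' Three orthogonal cameras around the tank
#'
#' Builds the canonical layout: camera 1 below the tank looking along +z,
#' cameras 2 and 3 looking along +x and +y. Principal axes intersect at the
#' tank centre (the lab origin).
#'
#' @param optics a \code{tank_optics}.
#' @return list of three \code{pinhole_camera}.
#' @export
make_tank_cameras <- function(optics = tank_optics()) {
  f <- optics$focal_mm * 1000 / optics$pixel_um
  u0 <- optics$sensor[1L] / 2
  v0 <- optics$sensor[2L] / 2
  lapply(1:3, function(k) {
    ax <- CAMERA_AXES[[k]]
    R <- matrix(0, 3L, 3L)
    R[1L, ax$u[1L]] <- ax$u[2L]
    R[2L, ax$v[1L]] <- ax$v[2L]
    R[3L, ax$depth] <- 1
    centre <- numeric(3L); centre[ax$depth] <- -optics$cam_distance
    pinhole_camera(fx = f, fy = f, u0 = u0, v0 = v0,
                   rotation = R, translation = drop(-R %*% centre))
  })
}

#' Ray-trace a point through the water-glass-air interfaces
#'
#' Physical projection oracle: applies Snell's law at the flat water-glass
#' and glass-air interfaces (both perpendicular to the camera principal
#' axis), then projects the emergent air ray through the pinhole camera.
#' With all indices equal to 1 this reduces exactly to [project_linear()].
#'
#' @param optics a \code{tank_optics}.
#' @param cam a \code{pinhole_camera} positioned per [make_tank_cameras()].
#' @param points length-3 vector or n x 3 matrix of lab points inside the
#'   water volume, mm.
#' @return n x 2 matrix of pixel coordinates.
#' @export
simulate_refraction <- function(optics, cam, points) {
  if (is.null(dim(points))) points <- matrix(points, 1L)
  centre <- camera_center(cam)
  axis <- drop(cam$rotation[3L, ])            # principal axis, lab frame
  h <- optics$side / 2
  D <- optics$cam_distance
  g1 <- D - h                                  # camera to inner (water) wall
  g2 <- D - h - optics$glass                   # camera to outer wall
  na <- optics$n_air; ng <- optics$n_glass; nw <- optics$n_water
  out <- matrix(NA_real_, nrow(points), 2L)
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    rel <- p - centre
    dp <- sum(rel * axis)
    if (dp <= g1) stop("point is not inside the water volume")
    tv <- rel - dp * axis
    rho <- vnorm(tv)
    if (rho < 1e-12) { out[i, ] <- project_linear(cam, p); next }
    et <- tv / rho
    reach <- function(th_a) {
      sa <- sin(th_a)
      sg <- na / ng * sa
      sw <- na / nw * sa
      if (sg >= 1 || sw >= 1) return(1e12)  # total internal reflection
      g2 * tan(th_a) + (g1 - g2) * sg / sqrt(1 - sg^2) +
        (dp - g1) * sw / sqrt(1 - sw^2) - rho
    }
    up <- pi / 2 - 1e-6
    if (reach(up) < 0)
      stop("no transmitted ray reaches the camera (total internal reflection)")
    th <- stats::uniroot(reach, c(1e-12, up), tol = 1e-14)$root
    q <- centre + g2 * axis + g2 * tan(th) * et  # emergent ray at outer wall
    out[i, ] <- project_linear(cam, q)
  }
  colnames(out) <- c("u", "v")
  out
}

## Bivariate cubic monomial exponents (10 terms, degree <= 3)
CUBIC_EXPONENTS <- {
  e <- expand.grid(a = 0:3, b = 0:3)
  e <- e[e$a + e$b <= 3, ]
  e[order(e$a + e$b, e$a), ]
}

## Columns follow CUBIC_EXPONENTS row order: 1, d, t, d^2, td, t^2, d^3,
## td^2, t^2 d, t^3.
cubic_design <- function(t_, d_) {
  t2 <- t_ * t_; d2 <- d_ * d_
  cbind(1, d_, t_, d2, t_ * d_, t2, d_ * d2, t_ * d2, t2 * d_, t_ * t2,
        deparse.level = 0)
}

#' Fit separable refraction-corrected projection functions
#'
#' For each camera, fits the two bivariate cubic polynomials
#' \code{u = f_u(t_u, d)} and \code{v = f_v(t_v, d)} mapping lab coordinates
#' to pixels, where d is the lab coordinate along the camera principal axis
#' and t_u, t_v the transverse lab coordinates carried by each pixel axis.
#' For flat interfaces perpendicular to orthogonal camera axes the true
#' refracted projection separates this way, which is the property the fit
#' exploits. Coordinates are centred and scaled before building the normal
#' equations, solved by QR.
#'
#' @param dots3d n x 3 matrix of lab dot positions, mm.
#' @param pixels list (one per camera) of n x 2 pixel matrices.
#' @param domain optional 3 x 2 matrix of valid lab bounds (min, max per
#'   axis); defaults to the bounding box of \code{dots3d} padded by 1 mm.
#' @return an object of class \code{refractive_projection} with per-camera
#'   coefficients and RMS fit residuals (px).
#' @export
fit_refractive_projection <- function(dots3d, pixels, domain = NULL) {
  stopifnot(is.matrix(dots3d), ncol(dots3d) == 3L)
  n_cam <- length(pixels)
  if (nrow(dots3d) < 10L)
    stop("need at least 10 dots to determine 10 cubic coefficients")
  if (is.null(domain)) {
    domain <- t(apply(dots3d, 2L, range)) +
      matrix(c(-1, 1), 3L, 2L, byrow = TRUE)
  }
  centre <- rowMeans(domain)
  scale <- pmax((domain[, 2L] - domain[, 1L]) / 2, 1e-6)
  cams <- vector("list", n_cam)
  for (k in seq_len(n_cam)) {
    ax <- CAMERA_AXES[[k]]
    px <- pixels[[k]]
    stopifnot(nrow(px) == nrow(dots3d))
    d_ <- (dots3d[, ax$depth] - centre[ax$depth]) / scale[ax$depth]
    fit_axis <- function(trans_axis, target, label) {
      t_ <- (dots3d[, trans_axis] - centre[trans_axis]) / scale[trans_axis]
      X <- cubic_design(t_, d_)
      qx <- qr(X)
      if (qx$rank < 10L)
        stop(sprintf(
          "rank-deficient dot layout for camera %d axis %s: dots must span the (transverse, depth) plane",
          k, label))
      beta <- qr.coef(qx, target)
      res <- target - X %*% beta
      list(coef = beta, rms = sqrt(mean(res^2)))
    }
    fu <- fit_axis(ax$u[1L], px[, 1L], "x")
    fv <- fit_axis(ax$v[1L], px[, 2L], "y")
    cams[[k]] <- list(coef_u = fu$coef, coef_v = fv$coef,
                      rms = c(u = fu$rms, v = fv$rms))
  }
  structure(list(cams = cams, n_cam = n_cam, centre = centre, scale = scale,
                 domain = domain,
                 rms_px = vapply(cams, function(cc) sqrt(mean(cc$rms^2)),
                                 numeric(1L))),
            class = "refractive_projection")
}

in_domain <- function(proj, points) {
  ok <- rep(TRUE, nrow(points))
  for (j in 1:3)
    ok <- ok & points[, j] >= proj$domain[j, 1L] &
      points[, j] <= proj$domain[j, 2L]
  ok
}

#' Evaluate a fitted refractive projection
#'
#' @param proj a \code{refractive_projection}.
#' @param points length-3 vector or n x 3 matrix of lab points, mm.
#' @param cameras which cameras to evaluate (default all).
#' @param check_domain error if any point falls outside the fitted domain.
#' @return list (per camera) of n x 2 pixel matrices.
#' @export
project_refractive <- function(proj, points, cameras = seq_len(proj$n_cam),
                               check_domain = TRUE) {
  if (is.null(dim(points))) points <- matrix(points, 1L)
  if (check_domain && !all(in_domain(proj, points)))
    stop("points outside the valid domain of the fitted projection")
  lapply(cameras, function(k) {
    ax <- CAMERA_AXES[[k]]
    cc <- proj$cams[[k]]
    d_ <- (points[, ax$depth] - proj$centre[ax$depth]) / proj$scale[ax$depth]
    tu <- (points[, ax$u[1L]] - proj$centre[ax$u[1L]]) / proj$scale[ax$u[1L]]
    tv <- (points[, ax$v[1L]] - proj$centre[ax$v[1L]]) / proj$scale[ax$v[1L]]
    cbind(cubic_design(tu, d_) %*% cc$coef_u,
          cubic_design(tv, d_) %*% cc$coef_v)
  })
}

## Derivatives of the cubic wrt (t, d), in scaled coordinates.
cubic_design_grad <- function(t_, d_) {
  z <- rep(0, length(t_)); o <- rep(1, length(t_))
  t2 <- t_ * t_; d2 <- d_ * d_
  list(dt = cbind(z, z, o, z, d_, 2 * t_, z, d2, 2 * t_ * d_, 3 * t2,
                  deparse.level = 0),
       dd = cbind(z, o, z, 2 * d_, t_, z, 3 * d2, 2 * t_ * d_, t2, z,
                  deparse.level = 0))
}

## Residuals and Jacobian of the stacked projection at a single lab point.
proj_residual_jac <- function(proj, x, pixels, cameras) {
  r <- numeric(0); J <- NULL
  for (idx in seq_along(cameras)) {
    k <- cameras[idx]
    ax <- CAMERA_AXES[[k]]
    cc <- proj$cams[[k]]
    d_ <- (x[ax$depth] - proj$centre[ax$depth]) / proj$scale[ax$depth]
    tu <- (x[ax$u[1L]] - proj$centre[ax$u[1L]]) / proj$scale[ax$u[1L]]
    tv <- (x[ax$v[1L]] - proj$centre[ax$v[1L]]) / proj$scale[ax$v[1L]]
    gu <- cubic_design_grad(tu, d_); gv <- cubic_design_grad(tv, d_)
    pu <- sum(cubic_design(tu, d_) * cc$coef_u)
    pv <- sum(cubic_design(tv, d_) * cc$coef_v)
    Jrow_u <- numeric(3L); Jrow_v <- numeric(3L)
    Jrow_u[ax$u[1L]] <- sum(gu$dt * cc$coef_u) / proj$scale[ax$u[1L]]
    Jrow_u[ax$depth] <- sum(gu$dd * cc$coef_u) / proj$scale[ax$depth]
    Jrow_v[ax$v[1L]] <- sum(gv$dt * cc$coef_v) / proj$scale[ax$v[1L]]
    Jrow_v[ax$depth] <- sum(gv$dd * cc$coef_v) / proj$scale[ax$depth]
    r <- c(r, pu - pixels[[idx]][1L], pv - pixels[[idx]][2L])
    J <- rbind(J, Jrow_u, Jrow_v)
  }
  list(r = r, J = J)
}

#' Triangulate a lab point from refraction-corrected pixel observations
#'
#' Nonlinear least squares on the fitted projection functions, started from
#' the tank centre. Requires observations from at least two cameras.
#'
#' @param proj a \code{refractive_projection}.
#' @param pixels list of length-2 pixel vectors, one per entry of
#'   \code{cameras}.
#' @param cameras camera indices corresponding to \code{pixels}.
#' @param init initial guess (default tank centre, the lab origin).
#' @param max_iter,tol Gauss-Newton iteration cap and step tolerance.
#' @return list with \code{point} (lab mm), \code{residual} (RMS px),
#'   \code{converged}, \code{iterations}.
#' @export
triangulate_point <- function(proj, pixels, cameras = seq_along(pixels),
                              init = c(0, 0, 0), max_iter = 50L, tol = 1e-10) {
  if (length(pixels) < 2L) stop("need observations from at least 2 cameras")
  x <- init
  lambda <- 1e-8
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    rj <- proj_residual_jac(proj, x, pixels, cameras)
    A <- crossprod(rj$J) + lambda * diag(3L)
    step <- tryCatch(drop(solve(A, crossprod(rj$J, rj$r))),
                     error = function(e) rep(0, 3L))
    x_new <- x - step
    if (max(abs(step)) < tol) { x <- x_new; converged <- TRUE; break }
    x <- x_new
    if (it >= max_iter) break
  }
  rj <- proj_residual_jac(proj, x, pixels, cameras)
  list(point = x, residual = sqrt(mean(rj$r^2)),
       converged = converged, iterations = it)
}

#' Reconstruct 3-D dot positions from unrefracted (in-air) images
#'
#' Least-squares triangulation through the linear camera matrices: per dot,
#' minimizes the summed squared reprojection residual over all cameras that
#' saw it. Dots visible in fewer than two cameras are skipped with a warning.
#'
#' @param pixels list (per camera) of n x 2 pixel matrices; rows may be NA
#'   where a dot was not detected.
#' @param cams list of \code{pinhole_camera}.
#' @return n x 3 matrix of reconstructed lab positions (NA rows for skipped
#'   dots).
#' @export
reconstruct_dots_air <- function(pixels, cams) {
  n <- nrow(pixels[[1L]])
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    seen <- which(vapply(pixels, function(p) all(is.finite(p[i, ])),
                         logical(1L)))
    if (length(seen) < 2L) {
      warning(sprintf("dot %d seen in fewer than 2 cameras; skipped", i))
      next
    }
    ## linear (DLT) initialization
    A <- NULL; b <- NULL
    for (k in seen) {
      cam <- cams[[k]]
      K <- intrinsic_matrix(cam)
      P <- K %*% cbind(cam$rotation, cam$translation)   # 3 x 4, column conv.
      u <- pixels[[k]][i, 1L]; v <- pixels[[k]][i, 2L]
      A <- rbind(A, u * P[3L, 1:3] - P[1L, 1:3], v * P[3L, 1:3] - P[2L, 1:3])
      b <- c(b, P[1L, 4L] - u * P[3L, 4L], P[2L, 4L] - v * P[3L, 4L])
    }
    x <- drop(qr.solve(A, b))
    ## Gauss-Newton refinement of the geometric objective
    for (it in 1:20) {
      r <- NULL; J <- NULL
      for (k in seen) {
        cam <- cams[[k]]
        xc <- drop(cam$rotation %*% x + cam$translation)
        u <- (cam$fx * xc[1L] + cam$skew * xc[2L]) / xc[3L] + cam$u0
        v <- cam$fy * xc[2L] / xc[3L] + cam$v0
        r <- c(r, u - pixels[[k]][i, 1L], v - pixels[[k]][i, 2L])
        du <- (cam$fx * cam$rotation[1L, ] + cam$skew * cam$rotation[2L, ]) /
          xc[3L] -
          (cam$fx * xc[1L] + cam$skew * xc[2L]) / xc[3L]^2 * cam$rotation[3L, ]
        dv <- cam$fy * cam$rotation[2L, ] / xc[3L] -
          cam$fy * xc[2L] / xc[3L]^2 * cam$rotation[3L, ]
        J <- rbind(J, du, dv)
      }
      step <- drop(solve(crossprod(J) + 1e-10 * diag(3L), crossprod(J, r)))
      x <- x - step
      if (max(abs(step)) < 1e-12) break
    }
    out[i, ] <- x
  }
  out
}

#' Minimum distance between two rays
#'
#' Closed-form skew-line distance; parallel rays fall back to the
#' point-to-line distance.
#'
#' @param a1,r1 origin and direction of ray 1.
#' @param a2,r2 origin and direction of ray 2.
#' @return scalar distance, mm.
#' @export
ray_distance <- function(a1, r1, a2, r2) {
  n <- c(r1[2L] * r2[3L] - r1[3L] * r2[2L],
         r1[3L] * r2[1L] - r1[1L] * r2[3L],
         r1[1L] * r2[2L] - r1[2L] * r2[1L])
  nn <- vnorm(n)
  d <- a2 - a1
  if (nn < 1e-12) {                      # parallel: point-to-line distance
    proj <- d - sum(d * r1) / sum(r1 * r1) * r1
    return(vnorm(proj))
  }
  abs(sum(d * n)) / nn
}

## Invert the separable projection at a fixed depth: 1-D root solve per axis.
pixel_to_point_at_depth <- function(proj, cam_idx, px, depth) {
  ax <- CAMERA_AXES[[cam_idx]]
  cc <- proj$cams[[cam_idx]]
  d_ <- (depth - proj$centre[ax$depth]) / proj$scale[ax$depth]
  solve_axis <- function(coef, target, trans_axis) {
    f <- function(t_raw) {
      t_ <- (t_raw - proj$centre[trans_axis]) / proj$scale[trans_axis]
      sum(cubic_design(t_, d_) * coef) - target
    }
    lo <- proj$domain[trans_axis, 1L] - 5
    hi <- proj$domain[trans_axis, 2L] + 5
    if (f(lo) * f(hi) > 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  tu <- solve_axis(cc$coef_u, px[1L], ax$u[1L])
  tv <- solve_axis(cc$coef_v, px[2L], ax$v[1L])
  if (is.na(tu) || is.na(tv)) return(rep(NA_real_, 3L))
  p <- numeric(3L)
  p[ax$depth] <- depth
  p[ax$u[1L]] <- tu
  p[ax$v[1L]] <- tv
  p
}

default_probe_depths <- function(proj, cam_idx) {
  rng <- proj$domain[CAMERA_AXES[[cam_idx]]$depth, ]
  lo <- rng[1L] + 0.05 * diff(rng)
  hi <- rng[2L] - 0.05 * diff(rng)
  c(lo, (lo + hi) / 2, hi)
}

#' Ray through a pixel (reverse mapping)
#'
#' For a fitted \code{refractive_projection}: finds three lab points at
#' different depths that project onto the pixel and fits a line through them.
#' For a linear \code{pinhole_camera}: the exact back-projected ray through
#' the optical centre. The returned ray is \code{a + lambda r}, with \code{a}
#' on the plane through the tank centre perpendicular to the camera principal
#' axis and \code{r} a unit vector.
#'
#' @param proj a \code{refractive_projection} or \code{pinhole_camera}.
#' @param cam_idx camera index (identifies the camera axis layout).
#' @param px length-2 pixel coordinate.
#' @param depths three probe depths along the principal axis, mm relative to
#'   the tank centre (refractive path only); defaults to the central 90
#'   percent of the fitted depth domain.
#' @return list with \code{a}, \code{r}, and \code{valid}.
#' @export
pixel_to_ray <- function(proj, cam_idx, px, depths = NULL) {
  if (inherits(proj, "pinhole_camera")) {
    cam <- proj
    dir_cam <- c((px[1L] - cam$u0) / cam$fx -
                   cam$skew * (px[2L] - cam$v0) / (cam$fx * cam$fy),
                 (px[2L] - cam$v0) / cam$fy, 1)
    r <- unit(drop(crossprod(cam$rotation, dir_cam)))
    centre <- camera_center(cam)
    depth_axis <- CAMERA_AXES[[cam_idx]]$depth
    a <- centre + (0 - centre[depth_axis]) / r[depth_axis] * r
    return(list(a = a, r = r, valid = TRUE))
  }
  if (is.null(depths)) depths <- default_probe_depths(proj, cam_idx)
  pts <- t(vapply(depths, function(d)
    pixel_to_point_at_depth(proj, cam_idx, px, d), numeric(3L)))
  if (any(!is.finite(pts)))
    return(list(a = rep(NA_real_, 3L), r = rep(NA_real_, 3L), valid = FALSE))
  r <- unit(pts[nrow(pts), ] - pts[1L, ])
  depth_axis <- CAMERA_AXES[[cam_idx]]$depth
  mid <- colMeans(pts)
  a <- mid + (0 - mid[depth_axis]) / r[depth_axis] * r
  list(a = a, r = r, valid = TRUE)
}

#' Per-pixel ray lookup table
#'
#' Precomputes [pixel_to_ray()] over a pixel grid. With \code{mode =
#' "deterministic"} the three probe points sit at fixed depths (-30, 0, +30
#' mm); \code{mode = "random"} draws three depths uniformly in that range per
#' pixel (seeded), mirroring random probe placement.
#'
#' @param proj a \code{refractive_projection}.
#' @param cam_idx camera index.
#' @param px_x,px_y pixel coordinates defining the grid.
#' @param mode probe placement mode.
#' @param seed RNG seed for \code{mode = "random"}.
#' @return object of class \code{ray_table}: arrays \code{a}, \code{r} of dim
#'   (length(px_x), length(px_y), 3) and logical \code{valid}.
#' @export
build_ray_table <- function(proj, cam_idx, px_x, px_y,
                            mode = c("deterministic", "random"), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "random") set.seed(seed)
  nx <- length(px_x); ny <- length(px_y)
  a <- array(NA_real_, c(nx, ny, 3L))
  r <- array(NA_real_, c(nx, ny, 3L))
  valid <- matrix(FALSE, nx, ny)
  base_depths <- default_probe_depths(proj, cam_idx)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    depths <- if (mode == "random")
      sort(stats::runif(3L, base_depths[1L], base_depths[3L]))
    else base_depths
    ray <- pixel_to_ray(proj, cam_idx, c(px_x[i], px_y[j]), depths)
    a[i, j, ] <- ray$a; r[i, j, ] <- ray$r; valid[i, j] <- ray$valid
  }
  structure(list(a = a, r = r, valid = valid, cam_idx = cam_idx,
                 px_x = px_x, px_y = px_y),
            class = "ray_table")
}

## Ray for an arbitrary (fractional) pixel: exact inversion when given a
## refractive_projection; nearest-entry lookup when given a ray_table.
centroid_ray <- function(geom, cam_idx, px) {
  if (inherits(geom, c("refractive_projection", "pinhole_camera")))
    return(pixel_to_ray(geom, cam_idx, px))
  stopifnot(inherits(geom, "ray_table"), geom$cam_idx == cam_idx)
  i <- which.min(abs(geom$px_x - px[1L]))
  j <- which.min(abs(geom$px_y - px[2L]))
  list(a = geom$a[i, j, ], r = geom$r[i, j, ], valid = geom$valid[i, j])
}

#' Match larva detections across the three camera views
#'
#' For every index triple (i, j, k) of per-camera centroids, computes the
#' back-projected rays and delta = max of the three pairwise minimum
#' ray-ray distances; triples with delta < eps are matched greedily in order
#' of ascending delta, each centroid used at most once.
#'
#' @param centroids list of three n_i x 2 pixel matrices.
#' @param geom a \code{refractive_projection} (exact rays) or a list of three
#'   \code{ray_table}s (one per camera).
#' @param eps match threshold, mm (heuristic; default 1).
#' @return data.frame with columns i, j, k, delta (mm), and the matched 3-D
#'   midpoint coordinates x, y, z.
#' @export
match_larvae_across_views <- function(centroids, geom, eps = 1.0) {
  stopifnot(eps > 0, length(centroids) == 3L)
  empty <- data.frame(i = integer(), j = integer(), k = integer(),
                      delta = numeric(), x = numeric(), y = numeric(),
                      z = numeric())
  if (any(vapply(centroids, nrow, integer(1L)) == 0L)) return(empty)
  rays <- lapply(1:3, function(cam) {
    g <- if (is.list(geom) && !inherits(geom, "refractive_projection"))
      geom[[cam]] else geom
    lapply(seq_len(nrow(centroids[[cam]])), function(m)
      centroid_ray(g, cam, centroids[[cam]][m, ]))
  })
  cand <- expand.grid(i = seq_along(rays[[1L]]), j = seq_along(rays[[2L]]),
                      k = seq_along(rays[[3L]]))
  cand$delta <- NA_real_
  mids <- matrix(NA_real_, nrow(cand), 3L)
  for (t_ in seq_len(nrow(cand))) {
    R1 <- rays[[1L]][[cand$i[t_]]]
    R2 <- rays[[2L]][[cand$j[t_]]]
    R3 <- rays[[3L]][[cand$k[t_]]]
    if (!R1$valid || !R2$valid || !R3$valid) next
    cand$delta[t_] <- max(ray_distance(R1$a, R1$r, R2$a, R2$r),
                          ray_distance(R2$a, R2$r, R3$a, R3$r),
                          ray_distance(R1$a, R1$r, R3$a, R3$r))
    mids[t_, ] <- (ray_closest_point(R1, R2) + ray_closest_point(R2, R3) +
                     ray_closest_point(R1, R3)) / 3
  }
  ord <- order(cand$delta)
  used <- lapply(1:3, function(cam) logical(nrow(centroids[[cam]])))
  keep <- integer(0)
  for (t_ in ord) {
    if (!is.finite(cand$delta[t_]) || cand$delta[t_] >= eps) break
    ii <- cand$i[t_]; jj <- cand$j[t_]; kk <- cand$k[t_]
    if (used[[1L]][ii] || used[[2L]][jj] || used[[3L]][kk]) next
    used[[1L]][ii] <- used[[2L]][jj] <- used[[3L]][kk] <- TRUE
    keep <- c(keep, t_)
  }
  cbind(cand[keep, , drop = FALSE],
        data.frame(x = mids[keep, 1L], y = mids[keep, 2L], z = mids[keep, 3L]))
}

## midpoint of the shortest segment between two rays
ray_closest_point <- function(R1, R2) {
  r1 <- R1$r; r2 <- R2$r; d <- R2$a - R1$a
  a11 <- sum(r1 * r1); a12 <- -sum(r1 * r2); a22 <- sum(r2 * r2)
  b1 <- sum(d * r1); b2 <- -sum(d * r2)
  det <- a11 * a22 - a12 * a12
  if (abs(det) < 1e-12) return((R1$a + R2$a) / 2)
  l1 <- (b1 * a22 - b2 * a12) / det
  l2 <- (a11 * b2 - a12 * b1) / det
  ((R1$a + l1 * r1) + (R2$a + l2 * r2)) / 2
}

#' Simulate dot-grid calibration imagery
#'
#' Places a planar dot grid at several orientations inside the tank and
#' projects every dot to all three cameras both with refraction (ray-traced
#' through the tank walls) and without (linear pinhole projection),
#' emulating the with-tank / without-tank calibration image pairs.
#'
#' @param optics a \code{tank_optics}.
#' @param cams cameras from [make_tank_cameras()].
#' @param nx,ny dots per grid row / column.
#' @param pitch dot spacing, mm.
#' @param orientations matrix with one row per target placement and columns
#'   (tilt about lab x in deg, tilt about lab y in deg, offset along lab z in
#'   mm). Compound tilts make every camera see dots spanning a genuine 2-D
#'   (transverse, depth) region; single-axis tilts leave the design
#'   rank-deficient.
#' @param margin dots closer than this to a tank wall are dropped, mm.
#' @return list with \code{dots} (n x 3 lab mm), \code{pixels_water} and
#'   \code{pixels_air} (lists of n x 2 per camera).
#' @export
simulate_dot_grid <- function(optics = tank_optics(),
                              cams = make_tank_cameras(optics),
                              nx = 15, ny = 15, pitch = 5,
                              orientations = cbind(c(-15, 0, 15),
                                                   c(-20, 0, 20),
                                                   c(-6, 0, 6)),
                              margin = 2) {
  gx <- (seq_len(nx) - (nx + 1) / 2) * pitch
  gy <- (seq_len(ny) - (ny + 1) / 2) * pitch
  base <- as.matrix(expand.grid(x = gx, y = gy))
  dots <- NULL
  for (m in seq_len(nrow(orientations))) {
    R <- rot_y(orientations[m, 2L] * pi / 180) %*%
      rot_x(orientations[m, 1L] * pi / 180)
    plane <- cbind(base, 0) %*% t(R)
    plane[, 3L] <- plane[, 3L] + orientations[m, 3L]
    dots <- rbind(dots, plane)
  }
  h <- optics$side / 2 - margin
  dots <- dots[apply(abs(dots) < h, 1L, all), , drop = FALSE]
  list(dots = dots,
       pixels_water = lapply(cams, function(cam)
         simulate_refraction(optics, cam, dots)),
       pixels_air = lapply(cams, function(cam) project_linear(cam, dots)))
}
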