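#' Construct a larval pose
#'
#' A pose holds the 22 adjustable parameters of the physical larva model plus
#' the body length \code{L}. The six rigid-body parameters are the head
#' position \code{(x0, y0, z0)} (mm, lab frame) and the head Euler angles
#' \code{theta0} (yaw), \code{phi0} (inclination) and \code{gamma0} (roll),
#' all in radians. The backbone shape is given by eight lateral bending
#' angles \code{dtheta} and eight dorso-ventral bending angles \code{dphi},
#' one pair per joint of the 9-segment scaffold, measured in the fish frame.
#'
#' Conventions: the fish X axis points from the head into the body
#' (anterior to posterior), positive \code{dtheta} bends toward the fish left
#' (+Y), positive \code{dphi} bends dorsally (+Z), and positive \code{phi0}
#' inclines the body axis upward in the lab frame.
#'
#' @param x0,y0,z0 head position, mm (lab frame, origin at tank centre).
#' @param theta0 yaw, rad, wrapped to (-pi, pi].
#' @param phi0 inclination, rad.
#' @param gamma0 roll, rad.
#' @param dtheta,dphi numeric length 8; per-joint bending angles, rad,
#'   each strictly inside (-pi/2, pi/2).
#' @param length body length L in mm (head tip to tail tip along the chain).
#' @return an object of class \code{fish_pose}.
#' @export
fish_pose <- function(x0 = 0, y0 = 0, z0 = 0,
                      theta0 = 0, phi0 = 0, gamma0 = 0,
                      dtheta = numeric(8), dphi = numeric(8),
                      length = 4.0) {
  stopifnot(length(dtheta) == 8L, length(dphi) == 8L)
  stopifnot_finite(c(x0, y0, z0, theta0, phi0, gamma0, dtheta, dphi, length))
  if (length <= 0) stop("body length must be positive")
  if (any(abs(dtheta) >= pi / 2) || any(abs(dphi) >= pi / 2))
    stop("bending angles must lie strictly inside (-pi/2, pi/2)")
  structure(list(x0 = x0, y0 = y0, z0 = z0,
                 theta0 = wrap_angle(theta0), phi0 = phi0, gamma0 = gamma0,
                 dtheta = as.numeric(dtheta), dphi = as.numeric(dphi),
                 length = length),
            class = "fish_pose")
}

#' @export
print.fish_pose <- function(x, ...) {
  cat(sprintf("<fish_pose> L = %.2f mm, head (%.2f, %.2f, %.2f) mm\n",
              x$length, x$x0, x$y0, x$z0))
  cat(sprintf("  yaw %.1f deg, inclination %.1f deg, roll %.1f deg\n",
              x$theta0 * 180 / pi, x$phi0 * 180 / pi, x$gamma0 * 180 / pi))
  cat(sprintf("  <|dtheta|> %.3f rad, <|dphi|> %.3f rad\n",
              mean(abs(x$dtheta)), mean(abs(x$dphi))))
  invisible(x)
}

#' Flatten a pose into the 22-parameter vector
#'
#' Order: \code{(x0, y0, z0, theta0, dtheta1..8, phi0, dphi1..8, gamma0)}.
#'
#' @param pose a \code{fish_pose}.
#' @return numeric vector of length 22 (the body length is not included).
#' @export
pose_to_vector <- function(pose) {
  c(pose$x0, pose$y0, pose$z0, pose$theta0, pose$dtheta,
    pose$phi0, pose$dphi, pose$gamma0)
}

#' Rebuild a pose from a 22-parameter vector
#'
#' @param p numeric length 22, ordered as in [pose_to_vector()].
#' @param length body length L, mm.
#' @return a \code{fish_pose}.
#' @export
pose_from_vector <- function(p, length = 4.0) {
  stopifnot(length(p) == 22L)
  fish_pose(x0 = p[1L], y0 = p[2L], z0 = p[3L], theta0 = p[4L],
            dtheta = p[5:12], phi0 = p[13L], dphi = p[14:21],
            gamma0 = p[22L], length = length)
}

## Unvalidated constructor for optimizer hot loops: pattern-search polls may
## transiently step outside the valid angle ranges, which the forward chain
## tolerates.
pose_from_vector_fast <- function(p, length) {
  structure(list(x0 = p[1L], y0 = p[2L], z0 = p[3L], theta0 = p[4L],
                 phi0 = p[13L], gamma0 = p[22L], dtheta = p[5:12],
                 dphi = p[14:21], length = length),
            class = "fish_pose")
}

#' Fixed body parameters of the physical larva model
#'
#' The non-adjustable parameters describing the larval anterior (eyes, head,
#' belly as anisotropic Gaussian ellipsoids) and the tail width. Dimensions
#' are full extents in mm ordered (length along the body axis, width, height);
#' the Gaussian standard deviation of each organ axis is dimension / 4, so
#' the 2-sigma ellipsoid matches the stated extents. These defaults are
#' plausible for a 4 mm larva but are placeholders estimated by eye, not
#' published values; all are overridable and the test-suite depends only on
#' self-consistency of the renderer, never on particular defaults.
#'
#' @param eye_dist lateral distance of each eye centroid from the midline, mm.
#' @param eye_dims,head_dims,belly_dims full extents (length, width, height), mm.
#' @param eye_along,head_along,belly_along position of each organ centre along
#'   the first scaffold segment, mm from the head point.
#' @param eye_perp,head_perp,belly_perp dorso-ventral offset of each organ
#'   centre from the scaffold, mm (positive dorsal).
#' @param brightness named numeric: peak brightness of eye, head, belly on the
#'   8-bit scale.
#' @param tail_width_scale dimensionless scale of the tail transverse Gaussian
#'   width; sigma = tail_width_scale * L / 40.
#' @return an object of class \code{fish_body_params}.
#' @export
fish_body_params <- function(eye_dist = 0.2,
                             eye_dims = c(0.25, 0.20, 0.20),
                             head_dims = c(0.60, 0.40, 0.40),
                             belly_dims = c(0.70, 0.40, 0.40),
                             eye_along = 0.35, eye_perp = 0.05,
                             head_along = 0.45, head_perp = 0,
                             belly_along = 0.80, belly_perp = -0.08,
                             brightness = c(eye = 255, head = 180, belly = 200),
                             tail_width_scale = 1) {
  p <- list(eye_dist = eye_dist, eye_dims = eye_dims, head_dims = head_dims,
            belly_dims = belly_dims, eye_along = eye_along,
            eye_perp = eye_perp, head_along = head_along,
            head_perp = head_perp, belly_along = belly_along,
            belly_perp = belly_perp,
            brightness = brightness, tail_width_scale = tail_width_scale)
  if (any(unlist(p[c("eye_dist", "eye_dims", "head_dims", "belly_dims",
                     "brightness", "tail_width_scale")]) <= 0))
    stop("dimensions, eye distance and brightness must be positive")
  structure(p, class = "fish_body_params")
}

#' Randomly jitter the fixed body parameters
#'
#' Each numeric entry is varied uniformly at random by a relative fraction
#' (default +/- 5 percent), emulating the between-individual variability
#' injected into synthetic training images.
#'
#' @param fixed a \code{fish_body_params}.
#' @param frac maximum relative perturbation (0.05 = +/- 5 percent).
#' @return a new \code{fish_body_params}.
#' @export
jitter_body_params <- function(fixed, frac = 0.05) {
  out <- fixed
  for (nm in names(out)) {
    v <- out[[nm]]
    if (is.numeric(v))
      out[[nm]] <- v * stats::runif(length(v), 1 - frac, 1 + frac)
  }
  out
}

## Moving-frame chain shared by the forward and inverse maps. Frame i+1 is
## frame i rotated by dtheta about its z (dorsal) axis and dphi about its
## (negated) y axis so that positive dphi bends dorsally.
joint_rotation <- function(dtheta, dphi) rot_z(dtheta) %*% rot_y(-dphi)

#' Backbone and eye coordinates of a pose
#'
#' Converts the 22-parameter pose into the equivalent 3-D coordinate
#' representation: 10 equally spaced backbone points (consecutive chord
#' length L/9, starting at the head point) and the two eye centroids. The
#' chain places segment i+1 by rotating segment i by (dtheta_i, dphi_i) in
#' the moving fish frame; the eyes sit on a segment perpendicular to the
#' first scaffold segment, rolled with gamma0.
#'
#' @param pose a \code{fish_pose}.
#' @param fixed a \code{fish_body_params} (eye placement).
#' @return list with \code{backbone} (10 x 3 matrix, mm), \code{eyes}
#'   (2 x 3 matrix, mm; row 1 is the fish-left eye) and \code{length}.
#' @export
pose_to_coordinates <- function(pose, fixed = fish_body_params()) {
  seg <- pose$length / 9
  frame <- rot_z(pose$theta0) %*% rot_y(-pose$phi0) %*% rot_x(pose$gamma0)
  backbone <- matrix(0, 10L, 3L)
  backbone[1L, ] <- c(pose$x0, pose$y0, pose$z0)
  f <- frame
  for (i in 1:9) {
    d <- f[, 1L]
    backbone[i + 1L, ] <- backbone[i, ] + seg * d
    if (i <= 8L)
      f <- f %*% joint_rotation(pose$dtheta[i], pose$dphi[i])
  }
  scale <- pose$length / 4.0  # organ placements specified for a 4 mm larva
  centre <- backbone[1L, ] +
    fixed$eye_along * scale * frame[, 1L] +
    fixed$eye_perp * scale * frame[, 3L]
  lat <- fixed$eye_dist * scale * frame[, 2L]
  eyes <- rbind(centre + lat, centre - lat)
  list(backbone = backbone, eyes = eyes, length = pose$length)
}

#' Recover the 22-parameter pose from 3-D coordinates
#'
#' Exact inverse of [pose_to_coordinates()] for backbone points with equal
#' consecutive chord lengths (run [resample_spline()] first otherwise). The
#' roll angle is taken from the eye axis under the never-belly-up convention:
#' the eye labelling is chosen so that gamma0 lies in (-pi/2, pi/2].
#'
#' @param coords list with \code{backbone} (10 x 3) and \code{eyes} (2 x 3),
#'   as returned by [pose_to_coordinates()].
#' @param tol relative tolerance on chord-length equality (warning only;
#'   equal-arc resampled points on a bent spline have chord spreads up to
#'   about a percent).
#' @return a \code{fish_pose}.
#' @export
coordinates_to_pose <- function(coords, tol = 0.02) {
  b <- coords$backbone
  stopifnot(is.matrix(b), nrow(b) == 10L, ncol(b) == 3L)
  segs <- diff(b)
  lens <- sqrt(rowSums(segs^2))
  if (any(lens == 0)) stop("degenerate backbone: coincident points")
  if (diff(range(lens)) > tol * mean(lens))
    warning("backbone points are not equidistant; angles will be inconsistent")
  L <- 9 * mean(lens)
  d1 <- segs[1L, ] / lens[1L]
  theta0 <- atan2(d1[2L], d1[1L])
  phi0 <- asin(max(-1, min(1, d1[3L])))
  frame0 <- rot_z(theta0) %*% rot_y(-phi0)
  gamma0 <- 0
  if (!is.null(coords$eyes)) {
    u <- coords$eyes[1L, ] - coords$eyes[2L, ]
    if (vnorm(u) == 0) stop("degenerate eyes: coincident points")
    gy <- sum(u * frame0[, 2L]); gz <- sum(u * frame0[, 3L])
    if (gy == 0 && gz == 0) stop("eye axis parallel to the heading")
    gamma0 <- atan2(gz, gy)
    if (gamma0 <= -pi / 2 || gamma0 > pi / 2)  # never belly-up: relabel eyes
      gamma0 <- wrap_angle(gamma0 + pi)
  }
  f <- frame0 %*% rot_x(gamma0)
  dtheta <- dphi <- numeric(8L)
  for (i in 1:8) {
    w <- segs[i + 1L, ] / lens[i + 1L]
    wf <- drop(crossprod(f, w))
    dtheta[i] <- atan2(wf[2L], wf[1L])
    dphi[i] <- asin(max(-1, min(1, wf[3L])))
    f <- f %*% joint_rotation(dtheta[i], dphi[i])
  }
  fish_pose(x0 = b[1L, 1L], y0 = b[1L, 2L], z0 = b[1L, 3L],
            theta0 = theta0, phi0 = phi0, gamma0 = gamma0,
            dtheta = dtheta, dphi = dphi, length = L)
}

#' Write / read pose tables
#'
#' Poses are stored as CSV with 23 columns: the 22 adjustable parameters in
#' vector order (\code{x0, y0, z0, theta0, dtheta1..8, phi0, dphi1..8,
#' gamma0}; mm and radians) plus the body length \code{L} (mm).
#'
#' @param poses list of \code{fish_pose}.
#' @param path file path.
#' @return \code{read_pose_csv} returns a list of \code{fish_pose}.
#' @export
write_pose_csv <- function(poses, path) {
  m <- t(vapply(poses, function(p) c(pose_to_vector(p), p$length),
                numeric(23L)))
  colnames(m) <- c("x0", "y0", "z0", "theta0", paste0("dtheta", 1:8),
                   "phi0", paste0("dphi", 1:8), "gamma0", "L")
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
read_pose_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(seq_len(nrow(d)), function(i)
    pose_from_vector(as.numeric(d[i, 1:22]), length = d$L[i]))
}
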