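## From per-view 2-D keypoints to a 3-D pose, and prediction scoring.

#' Triangulate the 10 backbone points from per-view keypoints
#'
#' Each backbone point is triangulated independently by nonlinear least
#' squares against the projection functions, starting from the tank centre.
#'
#' @param keypoints list (per camera) of 10 x 2 matrices of sensor-pixel
#'   coordinates (add the crop origin to crop coordinates first).
#' @param proj a \code{refractive_projection}.
#' @param cameras camera indices (default all views supplied).
#' @param flag_px points with RMS reprojection residual above this are
#'   flagged.
#' @return list with \code{points} (10 x 3, mm), \code{residuals} (px),
#'   \code{flagged} (logical).
#' @export
triangulate_backbone <- function(keypoints, proj,
                                 cameras = seq_along(keypoints),
                                 flag_px = 2) {
  pts <- matrix(NA_real_, 10L, 3L)
  res <- numeric(10L)
  for (j in 1:10) {
    tr <- triangulate_point(proj, lapply(keypoints, function(kp) kp[j, ]),
                            cameras = cameras)
    pts[j, ] <- tr$point
    res[j] <- tr$residual
  }
  list(points = pts, residuals = res, flagged = res > flag_px)
}

#' Resolve the eye correspondence across views and triangulate the eyes
#'
#' The network output does not carry a consistent left/right eye labelling
#' across views, so all 8 combinations of per-view eye indices are
#' enumerated; each assignment triangulates both eyes and the assignment
#' with the least total residual is accepted (ties break to the lowest
#' lexicographic assignment, flagged).
#'
#' @param eye_keypoints list (per camera) of 2 x 2 matrices (rows: the two
#'   eye points, sensor px).
#' @param proj a \code{refractive_projection}.
#' @param cameras camera indices.
#' @param tie_tol residual tie tolerance (px).
#' @return list with \code{eyes} (2 x 3, mm), \code{assignment} (per-view
#'   index of the point used for eye 1), \code{residual}, \code{tie}, and
#'   \code{n_assignments} (the number of enumerated labelings, 2^views).
#' @export
resolve_eyes <- function(eye_keypoints, proj,
                         cameras = seq_along(eye_keypoints), tie_tol = 1e-9) {
  nv <- length(eye_keypoints)
  combos <- as.matrix(expand.grid(rep(list(1:2), nv)))
  total <- numeric(nrow(combos))
  sols <- vector("list", nrow(combos))
  for (a in seq_len(nrow(combos))) {
    pick <- combos[a, ]
    e1 <- triangulate_point(proj, lapply(seq_len(nv), function(k)
      eye_keypoints[[k]][pick[k], ]), cameras = cameras)
    e2 <- triangulate_point(proj, lapply(seq_len(nv), function(k)
      eye_keypoints[[k]][3L - pick[k], ]), cameras = cameras)
    total[a] <- e1$residual + e2$residual
    sols[[a]] <- rbind(e1$point, e2$point)
  }
  best <- which.min(total)
  tie <- sum(total <= total[best] + tie_tol) > 1L
  if (tie) best <- which(total <= total[best] + tie_tol)[1L]
  list(eyes = sols[[best]], assignment = combos[best, ],
       residual = total[best], tie = tie, n_assignments = nrow(combos))
}

#' Roll angle from the eye axis
#'
#' Computes gamma0 from the triangulated eye pair and the backbone heading
#' under the never-belly-up convention: the eye labelling is chosen so the
#' roll lies in (-pi/2, pi/2].
#'
#' @param eyes 2 x 3 matrix of eye positions, mm.
#' @param backbone 10 x 3 backbone points, mm.
#' @return roll angle, rad.
#' @export
assign_roll <- function(eyes, backbone) {
  pose <- coordinates_to_pose(list(backbone = backbone, eyes = eyes))
  pose$gamma0
}

#' Resample a backbone to 10 equally spaced points along the arc
#'
#' Fits a parametric cubic spline (chord-length parameterization) through
#' the points and returns 10 points equally spaced in arc length; the
#' endpoints are preserved.
#'
#' @param backbone n x 3 matrix of points, mm.
#' @param n_out number of output points (default 10).
#' @param n_dense dense samples used for the arc-length table.
#' @return n_out x 3 matrix.
#' @export
resample_spline <- function(backbone, n_out = 10L, n_dense = 4001L) {
  stopifnot(is.matrix(backbone), ncol(backbone) == 3L)
  ch <- sqrt(rowSums(diff(backbone)^2))
  if (any(ch == 0)) stop("degenerate backbone: coincident points")
  u <- c(0, cumsum(ch))
  uu <- seq(0, u[length(u)], length.out = n_dense)
  dense <- vapply(1:3, function(j)
    stats::spline(u, backbone[, j], xout = uu, method = "fmm")$y,
    numeric(n_dense))
  seg <- sqrt(rowSums(diff(dense)^2))
  arc <- c(0, cumsum(seg))
  targets <- seq(0, arc[n_dense], length.out = n_out)
  out <- vapply(1:3, function(j)
    stats::approx(arc, dense[, j], xout = targets)$y, numeric(n_out))
  out[1L, ] <- backbone[1L, ]
  out[n_out, ] <- backbone[nrow(backbone), ]
  out
}

#' Reconstruct a 3-D pose from per-view keypoint predictions
#'
#' Full post-processing chain: triangulate the backbone points, resolve the
#' eye assignment, resample the backbone by arc length, and convert the
#' coordinates to the 22-parameter pose (roll from the eye axis).
#'
#' @param keypoints list (per camera) of 12 x 2 matrices (10 backbone + 2
#'   eye rows, crop px).
#' @param origins list of per-view crop origins (sensor px).
#' @param proj a \code{refractive_projection}.
#' @param cameras camera indices.
#' @return list with \code{pose} (a \code{fish_pose}), \code{backbone},
#'   \code{eyes}, \code{residuals}, \code{eye_assignment}, \code{flagged}.
#' @export
reconstruct_pose <- function(keypoints, origins, proj,
                             cameras = seq_along(keypoints)) {
  sensor <- lapply(seq_along(keypoints), function(k)
    sweep(keypoints[[k]], 2L, -as.numeric(origins[[k]])))
  bb <- triangulate_backbone(lapply(sensor, function(m) m[1:10, ]), proj,
                             cameras = cameras)
  ey <- resolve_eyes(lapply(sensor, function(m) m[11:12, ]), proj,
                     cameras = cameras)
  backbone <- resample_spline(bb$points)
  pose <- coordinates_to_pose(list(backbone = backbone, eyes = ey$eyes))
  list(pose = pose, backbone = backbone, eyes = ey$eyes,
       residuals = bb$residuals, eye_assignment = ey$assignment,
       flagged = bb$flagged)
}

#' Masked-correlation prediction score
#'
#' Renders the candidate pose into the observed crop windows and computes,
#' per view, Pearson's correlation between observed and rendered pixels over
#' the mask of non-zero rendered pixels (the rendered background is exactly
#' zero). The frame score is the minimum over the views: 1 corresponds to a
#' perfect pose prediction.
#'
#' @param obs observed views: a \code{view_triplet}, \code{training_example}
#'   or images/origins list.
#' @param pose a \code{fish_pose}.
#' @param proj projection.
#' @param fixed a \code{fish_body_params}.
#' @param mode render mode.
#' @param table lookup table (fast mode).
#' @param pitch voxel pitch (accurate mode), mm.
#' @return list with \code{score} (min over views; NA if any mask is empty),
#'   \code{per_view}, \code{flag}.
#' @export
prediction_score <- function(obs, pose, proj, fixed = fish_body_params(),
                             mode = "accurate", table = NULL, pitch = 0.03) {
  if (inherits(obs, c("view_triplet", "training_example")))
    obs <- list(images = obs$images, origins = obs$origins,
                size = nrow(obs$images[[1L]]))
  tr <- render_views(pose, fixed, proj, mode = mode, table = table,
                     origins = obs$origins, size = obs$size)
  per_view <- vapply(seq_along(obs$images), function(k) {
    ren <- tr$images[[k]]
    mask <- ren > 0
    if (!any(mask)) return(NA_real_)
    a <- obs$images[[k]][mask]; b <- ren[mask]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1L))
  if (any(is.na(per_view)))
    return(list(score = NA_real_, per_view = per_view, flag = "empty-mask"))
  list(score = min(per_view), per_view = per_view, flag = "ok")
}

#' Accept or reject bouts on per-frame prediction scores
#'
#' A bout is accepted iff its minimum frame score is at or above the
#' threshold. Frames with missing (NA) scores are excluded from the minimum
#' with a warning.
#'
#' @param scores list of numeric vectors (per-bout frame scores), or a
#'   single \code{swim_bout} with scores.
#' @param threshold acceptance threshold (default 0.85).
#' @return logical vector of acceptances.
#' @export
filter_bouts <- function(scores, threshold = 0.85) {
  if (inherits(scores, "swim_bout")) scores <- list(scores$scores)
  vapply(scores, function(s) {
    if (any(is.na(s))) {
      warning("missing frame scores excluded from the bout minimum")
      s <- s[!is.na(s)]
    }
    length(s) > 0 && min(s) >= threshold
  }, logical(1L))
}
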