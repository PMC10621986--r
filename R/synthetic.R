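## Pose ensembles and synthetic training data.

#' Mean absolute curvature of a pose
#'
#' The arithmetic means of |dtheta_i| and |dphi_i| over the 8 joints: the
#' 2-D summary in which pose ensembles are uniformized.
#'
#' @param pose a \code{fish_pose}.
#' @return named numeric: \code{mean_abs_dtheta}, \code{mean_abs_dphi} (rad).
#' @export
curvature_summary <- function(pose) {
  c(mean_abs_dtheta = mean(abs(pose$dtheta)),
    mean_abs_dphi = mean(abs(pose$dphi)))
}

curvature_matrix <- function(poses) {
  t(vapply(poses, curvature_summary, numeric(2L)))
}

#' 18-D bending-angle matrix of a pose ensemble
#'
#' Columns: dtheta1..8, dphi1..8, phi0, gamma0 (the space in which the
#' angle KDE is built).
#'
#' @param poses list of \code{fish_pose}.
#' @return n x 18 matrix, radians.
#' @export
angle_matrix <- function(poses) {
  t(vapply(poses, function(p) c(p$dtheta, p$dphi, p$phi0, p$gamma0),
           numeric(18L)))
}

#' Prior ensemble of plausible larval poses
#'
#' Bootstraps a pose ensemble from a generative prior rather than from
#' recordings: most poses are nearly straight and a minority carry strong
#' C-bend-like lateral curvature, emulating the straight-pose bias of real
#' swim data. Bend profiles ramp smoothly along the tail; dorso-ventral
#' bending and the head inclination/roll are smaller, as in real larvae.
#'
#' @param n ensemble size.
#' @param length body length, mm.
#' @param bend_sd scale of the lateral bend amplitude distribution, rad.
#' @param volume 3 x 2 matrix of position bounds, mm (default the central
#'   3 x 3 x 3 cm imaging volume).
#' @return list of \code{fish_pose}.
#' @export
pose_prior_ensemble <- function(n, length = 4.0, bend_sd = 0.25,
                                volume = cbind(rep(-15, 3), rep(15, 3))) {
  ramp <- seq(0.3, 1, length.out = 8L)
  lapply(seq_len(n), function(i) {
    amp_t <- stats::rnorm(1L, 0, bend_sd)
    amp_p <- stats::rnorm(1L, 0, bend_sd / 3)
    dtheta <- amp_t * ramp + stats::rnorm(8L, 0, 0.03)
    dphi <- amp_p * ramp + stats::rnorm(8L, 0, 0.015)
    clamp <- function(a) pmin(pmax(a, -1.45), 1.45)
    fish_pose(
      x0 = stats::runif(1L, volume[1L, 1L], volume[1L, 2L]),
      y0 = stats::runif(1L, volume[2L, 1L], volume[2L, 2L]),
      z0 = stats::runif(1L, volume[3L, 1L], volume[3L, 2L]),
      theta0 = stats::runif(1L, -pi, pi),
      phi0 = stats::rnorm(1L, 0, 0.25),
      gamma0 = stats::rnorm(1L, 0, 0.15),
      dtheta = clamp(dtheta), dphi = clamp(dphi), length = length)
  })
}

#' Resample a pose ensemble uniformly in curvature space
#'
#' Fits a 2-D Gaussian KDE to the (mean |dtheta|, mean |dphi|) summaries of
#' the ensemble and draws a subset with selection weights inversely
#' proportional to the estimated density, flattening the straight-pose bias.
#' Densities are clipped from below at the \code{clip_quantile} quantile
#' before inversion to avoid runaway weights at density tails.
#'
#' @param poses list of \code{fish_pose}.
#' @param n subset size (default 2500).
#' @param bandwidth KDE bandwidth, rad; \code{NULL} selects it by
#'   cross-validation ([select_bandwidth()]).
#' @param clip_quantile lower clipping quantile for the density.
#' @param replace sample with replacement (required, with a flag, when
#'   n exceeds the ensemble size).
#' @return list with \code{poses} (the subset), \code{weights}, and
#'   \code{bandwidth}.
#' @export
resample_uniform <- function(poses, n = 2500L, bandwidth = NULL,
                             clip_quantile = 0.001, replace = FALSE) {
  cv <- curvature_matrix(poses)
  if (is.null(bandwidth)) bandwidth <- select_bandwidth(cv)
  kde <- gaussian_kde(cv, bandwidth)
  dens <- kde_density(kde, cv)
  dens <- pmax(dens, stats::quantile(dens, clip_quantile))
  w <- 1 / dens
  w <- w / sum(w)
  if (n > length(poses) && !replace) {
    warning("n exceeds ensemble size; sampling with replacement")
    replace <- TRUE
  }
  idx <- sample.int(length(poses), n, replace = replace, prob = w)
  list(poses = poses[idx], weights = w, bandwidth = bandwidth)
}

#' Fit the 18-D bending-angle KDE of an ensemble
#'
#' @param poses list of \code{fish_pose}.
#' @param bandwidth kernel bandwidth, rad; \code{NULL} selects it by
#'   cross-validation.
#' @return a \code{gaussian_kde} over (dtheta1..8, dphi1..8, phi0, gamma0).
#' @export
fit_angle_kde <- function(poses, bandwidth = NULL) {
  am <- angle_matrix(poses)
  if (is.null(bandwidth)) bandwidth <- select_bandwidth(am)
  gaussian_kde(am, bandwidth)
}

#' Sample a synthetic pose ensemble from the angle KDE
#'
#' Draws bending-angle vectors from the KDE and assigns positions uniformly
#' inside the imaging volume and yaw uniformly in (-pi, pi].
#'
#' @param kde an 18-D \code{gaussian_kde} from [fit_angle_kde()].
#' @param n number of poses.
#' @param volume 3 x 2 position bounds, mm (default central 3 x 3 x 3 cm).
#' @param length body length, mm.
#' @return list of \code{fish_pose}.
#' @export
sample_pose_ensemble <- function(kde, n,
                                 volume = cbind(rep(-15, 3), rep(15, 3)),
                                 length = 4.0) {
  stopifnot(kde$d == 18L)
  ang <- kde_sample(kde, n)
  ang[, 1:16] <- pmin(pmax(ang[, 1:16], -1.5), 1.5)
  pos <- cbind(stats::runif(n, volume[1L, 1L], volume[1L, 2L]),
               stats::runif(n, volume[2L, 1L], volume[2L, 2L]),
               stats::runif(n, volume[3L, 1L], volume[3L, 2L]))
  theta0 <- stats::runif(n, -pi, pi)
  lapply(seq_len(n), function(i)
    fish_pose(x0 = pos[i, 1L], y0 = pos[i, 2L], z0 = pos[i, 3L],
              theta0 = theta0[i], phi0 = ang[i, 17L], gamma0 = ang[i, 18L],
              dtheta = ang[i, 1:8], dphi = ang[i, 9:16], length = length))
}

#' Hierarchical background-noise model for synthetic images
#'
#' Per camera class, background pixel values (unit intensity scale) are
#' Gaussian with a random mean and variance per image: the mean is the
#' product of X_mu ~ U(x_mu_range) and Y_mu ~ N(y_mu_mean, y_mu_sd), and the
#' variance is uniform on var_range.
#'
#' @param bottom,side lists with elements \code{x_mu_range}, \code{y_mu_mean},
#'   \code{y_mu_sd}, \code{var_range}.
#' @return an object of class \code{noise_model}.
#' @export
noise_model <- function(
    bottom = list(x_mu_range = c(0, 1 / 255), y_mu_mean = 50, y_mu_sd = 10,
                  var_range = c(20, 70) / 255^2),
    side = list(x_mu_range = c(0, 1 / 255), y_mu_mean = 20, y_mu_sd = 10,
                var_range = c(10, 60) / 255^2)) {
  for (cl in list(bottom, side))
    if (any(cl$var_range < 0) || any(cl$x_mu_range < 0))
      stop("noise ranges must be non-negative")
  structure(list(bottom = bottom, side = side), class = "noise_model")
}

#' @rdname noise_model
#' @param noise a \code{noise_model}.
#' @param class \code{"bottom"} or \code{"side"}.
#' @param n number of images to draw parameters for.
#' @return \code{sample_noise_params} returns a data.frame with per-image
#'   \code{mean} and \code{sd} on the unit intensity scale.
#' @export
sample_noise_params <- function(noise, class = c("bottom", "side"), n = 1L) {
  cl <- noise[[match.arg(class)]]
  x_mu <- stats::runif(n, cl$x_mu_range[1L], cl$x_mu_range[2L])
  y_mu <- stats::rnorm(n, cl$y_mu_mean, cl$y_mu_sd)
  v <- stats::runif(n, cl$var_range[1L], cl$var_range[2L])
  data.frame(mean = x_mu * y_mu, sd = sqrt(v))
}

camera_class <- function(k) if (k == 1L) "bottom" else "side"

#' Generate one annotated training example
#'
#' Renders the pose into the camera views with jittered fixed body
#' parameters, displaces the larva at random by 0-20 whole pixels per axis
#' within each 141 x 141 crop, adds the per-camera-class Gaussian background
#' noise on the unit intensity scale, and rescales to unsigned 8-bit. The
#' 2-D keypoint annotation is displaced identically and is untouched by
#' pixel noise.
#'
#' @param pose a \code{fish_pose}.
#' @param fixed a \code{fish_body_params} (jittered internally by
#'   \code{jitter_frac}).
#' @param proj a \code{refractive_projection} or list of linear cameras.
#' @param noise a \code{noise_model}, or \code{NULL} to disable noise.
#' @param table lookup table for fast-mode rendering (optional).
#' @param mode render mode passed to [render_views()].
#' @param max_displace maximum displacement per axis, px.
#' @param jitter_frac relative jitter of the fixed parameters (0 disables).
#' @param size crop side, px.
#' @return an object of class \code{training_example}: \code{images} (list of
#'   8-bit matrices), \code{annotation} (list of 12 x 2 crop-px keypoints),
#'   \code{origins}, \code{pose}, \code{displacement}.
#' @export
generate_training_example <- function(pose, fixed = fish_body_params(), proj,
                                      noise = noise_model(), table = NULL,
                                      mode = "accurate", max_displace = 20L,
                                      jitter_frac = 0.05, size = 141L) {
  fx <- if (jitter_frac > 0) jitter_body_params(fixed, jitter_frac) else fixed
  coords <- pose_to_coordinates(pose, fx)
  kp3d <- rbind(coords$backbone, coords$eyes)
  nv <- n_views(proj)
  origins <- vector("list", nv)
  disp <- matrix(0L, nv, 2L)
  for (k in seq_len(nv)) {
    kp <- project_to_view(proj, k, kp3d)
    centre_origin <- round(colMeans(kp)) - (size - 1) / 2
    ok <- FALSE
    for (try in seq_len(10L)) {
      d <- sample.int(2L * max_displace + 1L, 2L, replace = TRUE) -
        (max_displace + 1L)
      o <- centre_origin - d
      kc <- sweep(kp, 2L, o)
      if (all(kc >= 0) && all(kc <= size - 1)) { ok <- TRUE; break }
    }
    if (!ok) stop(sprintf(
      "camera %d: displacement keeps pushing keypoints outside the frame", k))
    origins[[k]] <- o
    disp[k, ] <- d
  }
  tr <- render_views(pose, fx, proj, mode = mode, table = table,
                     origins = origins, size = size)
  images <- tr$images
  if (!is.null(noise)) {
    for (k in seq_len(nv)) {
      par <- sample_noise_params(noise, camera_class(k), 1L)
      img <- images[[k]] / 255 +
        matrix(stats::rnorm(size * size, par$mean, par$sd), size, size)
      img[img < 0] <- 0
      images[[k]] <- round(img / max(img) * 255)
    }
  }
  structure(list(images = images, annotation = tr$keypoints,
                 origins = origins, pose = pose, displacement = disp,
                 size = size),
            class = "training_example")
}

#' Generate a smooth synthetic swim bout
#'
#' Temporally correlated fixture for tracking and kinematics tests: bending
#' angles are sampled from the angle KDE at sparse control points and
#' interpolated smoothly across frames, while the centroid follows a smooth
#' random path with bounded speed. Real recordings are not emulated beyond
#' smoothness and speed limits.
#'
#' @param kde an 18-D \code{gaussian_kde}.
#' @param n_frames number of frames (>= 2).
#' @param smoothness frames between angle control points; \code{Inf} gives a
#'   constant pose.
#' @param fps frame rate, Hz (default 500).
#' @param max_speed centroid speed cap, mm/s.
#' @param length body length, mm.
#' @param start optional starting position (default origin).
#' @return an object of class \code{swim_bout} (see [swim_bout()]), with the
#'   generating poses as ground truth.
#' @export
generate_synthetic_bout <- function(kde, n_frames, smoothness = 5, fps = 500,
                                    max_speed = 150, length = 4.0,
                                    start = c(0, 0, 0)) {
  stopifnot(n_frames >= 2L)
  if (!is.finite(smoothness)) {
    ang <- matrix(kde_sample(kde, 1L), n_frames, 18L, byrow = TRUE)
  } else {
    n_ctrl <- max(2L, ceiling(n_frames / smoothness) + 1L)
    ctrl <- kde_sample(kde, n_ctrl)
    tt <- seq(0, 1, length.out = n_frames)
    tc <- seq(0, 1, length.out = n_ctrl)
    ang <- vapply(1:18, function(j)
      stats::spline(tc, ctrl[, j], xout = tt)$y, numeric(n_frames))
  }
  ang[, 1:16] <- pmin(pmax(ang[, 1:16], -1.5), 1.5)
  dt <- 1 / fps
  step_max <- max_speed * dt
  vel <- vapply(1:3, function(j)
    stats::filter(stats::rnorm(n_frames, 0, step_max / 2), rep(1 / 5, 5),
                  circular = TRUE), numeric(n_frames))
  vel <- matrix(vel, n_frames, 3L)
  spd <- sqrt(rowSums(vel^2))
  scl <- pmin(1, step_max / pmax(spd, 1e-12))
  vel <- vel * scl
  pos <- apply(vel, 2L, cumsum)
  pos <- sweep(pos, 2L, pos[1L, ]) +
    matrix(start, n_frames, 3L, byrow = TRUE)
  theta0 <- cumsum(c(stats::runif(1L, -pi, pi),
                     stats::rnorm(n_frames - 1L, 0, 0.01)))
  poses <- lapply(seq_len(n_frames), function(i)
    fish_pose(x0 = pos[i, 1L], y0 = pos[i, 2L], z0 = pos[i, 3L],
              theta0 = wrap_angle(theta0[i]), phi0 = ang[i, 17L],
              gamma0 = ang[i, 18L], dtheta = ang[i, 1:8],
              dphi = ang[i, 9:16], length = length))
  swim_bout(poses, fps = fps, context = "synthetic")
}

#' Swim bout container
#'
#' A time series of poses with optional per-frame prediction scores.
#'
#' @param poses list of \code{fish_pose}.
#' @param fps frame rate, Hz.
#' @param scores optional numeric vector of per-frame prediction scores.
#' @param context experimental context label.
#' @return an object of class \code{swim_bout}.
#' @export
swim_bout <- function(poses, fps = 500, scores = NULL,
                      context = c("synthetic", "free", "startle",
                                  "darkflash")) {
  context <- match.arg(context)
  stopifnot(length(poses) >= 1L)
  if (!is.null(scores)) stopifnot(length(scores) == length(poses))
  structure(list(poses = poses, times = (seq_along(poses) - 1L) / fps,
                 fps = fps, scores = scores, context = context),
            class = "swim_bout")
}

#' Write / read a training dataset
#'
#' Per-example PNG images plus a JSON annotation, with a manifest CSV
#' (example_id, camera, image, annotation).
#'
#' @param examples list of \code{training_example}.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV.
#' @export
write_training_dataset <- function(examples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(examples)) {
    ex <- examples[[i]]
    ann_path <- file.path(dir, sprintf("example_%05d.json", i))
    jsonlite::write_json(
      list(keypoints = lapply(ex$annotation, function(m) unname(as.matrix(m))),
           origins = lapply(ex$origins, as.numeric),
           pose = pose_to_vector(ex$pose), length = ex$pose$length),
      ann_path, auto_unbox = TRUE, digits = NA)
    for (k in seq_along(ex$images)) {
      img_path <- file.path(dir, sprintf("example_%05d_cam%d.png", i, k))
      png::writePNG(t(ex$images[[k]]) / 255, img_path)
      rows[[length(rows) + 1L]] <- data.frame(
        example_id = i, camera = k, image = basename(img_path),
        annotation = basename(ann_path))
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  manifest
}
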