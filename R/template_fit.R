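## Two-round template-based pose optimization.

#' Derivative-free pattern search
#'
#' Coordinate-wise opportunistic polling with mesh expansion (x2) on success
#' and contraction (x0.5) on failure; converges when the mesh size drops
#' below \code{mesh_tol}. Parameters are scaled per coordinate so mixed
#' mm/radian spaces poll sensibly. The accepted-cost sequence is
#' monotonically non-increasing by construction.
#'
#' @param fn objective function of a numeric vector.
#' @param x0 start point.
#' @param scale per-coordinate scale (poll step = mesh * scale).
#' @param mesh0 initial mesh size.
#' @param mesh_tol convergence threshold on the mesh size.
#' @param max_eval evaluation budget.
#' @param mesh_max largest allowed mesh size.
#' @param directions optional matrix of extra poll directions (one per
#'   column, in parameter units, already scaled); polled as +/- mesh times
#'   the column after the coordinate sweep. Lets the poll set span known
#'   coupled (sloppy) modes that coordinate steps cannot follow.
#' @return list with \code{par}, \code{value}, \code{evals},
#'   \code{iterations}, \code{trace} (accepted costs), \code{converged}.
#' @export
pattern_search <- function(fn, x0, scale = rep(1, length(x0)), mesh0 = 1,
                           mesh_tol = 1e-3, max_eval = 20000L, mesh_max = 4,
                           directions = NULL) {
  x <- x0
  f <- fn(x)
  mesh <- mesh0
  evals <- 1L
  iters <- 0L
  trace <- f
  n <- length(x0)
  converged <- FALSE
  repeat {
    iters <- iters + 1L
    improved <- FALSE
    x_base <- x
    for (i in seq_len(n)) {
      for (s in c(1, -1)) {
        xt <- x
        xt[i] <- xt[i] + s * mesh * scale[i]
        ft <- fn(xt)
        evals <- evals + 1L
        if (ft < f) {
          x <- xt; f <- ft
          improved <- TRUE
          trace <- c(trace, f)
          break
        }
      }
      if (evals >= max_eval) break
    }
    if (!is.null(directions) && evals < max_eval) {
      for (j in seq_len(ncol(directions))) {
        for (s in c(1, -1)) {
          xt <- x + s * mesh * directions[, j]
          ft <- fn(xt)
          evals <- evals + 1L
          if (ft < f) {
            x <- xt; f <- ft
            improved <- TRUE
            trace <- c(trace, f)
            break
          }
        }
        if (evals >= max_eval) break
      }
    }
    if (improved) {
      ## pattern moves: extrapolate the net displacement of the sweep so
      ## diagonal valleys are followed at full speed (Hooke-Jeeves)
      repeat {
        xt <- x + (x - x_base)
        ft <- fn(xt)
        evals <- evals + 1L
        if (ft < f) {
          x_base <- x
          x <- xt; f <- ft
          trace <- c(trace, f)
        } else break
        if (evals >= max_eval) break
      }
    }
    mesh <- if (improved) min(mesh * 2, mesh_max) else mesh * 0.5
    if (mesh < mesh_tol) { converged <- TRUE; break }
    if (evals >= max_eval) break
  }
  list(par = x, value = f, evals = evals, iterations = iters,
       trace = trace, converged = converged)
}

## Observation container used by the cost function: per-view preprocessed
## crops with their sensor origins.
as_observation <- function(images, origins, size = nrow(images[[1L]])) {
  list(images = images, origins = origins, size = size)
}

observation_from_triplet <- function(triplet) {
  as_observation(triplet$images, triplet$origins, triplet$size)
}

## Region of interest around the observed fish: pixels above a fraction of
## the image maximum (background noise sits well below it), padded.
obs_roi <- function(obs, pad = 14L, thresh_frac = 0.15) {
  lapply(seq_along(obs$images), function(k) {
    img <- obs$images[[k]]
    nz <- which(img > thresh_frac * max(img), arr.ind = TRUE)
    if (nrow(nz) == 0L) nz <- cbind(1L, 1L)
    x0 <- max(1L, min(nz[, 1L]) - pad); x1 <- min(nrow(img), max(nz[, 1L]) + pad)
    y0 <- max(1L, min(nz[, 2L]) - pad); y1 <- min(ncol(img), max(nz[, 2L]) + pad)
    list(img = img[x0:x1, y0:y1],
         origin = obs$origins[[k]] + c(x0 - 1L, y0 - 1L),
         nx = x1 - x0 + 1L, ny = y1 - y0 + 1L)
  })
}

## Build a fast cost closure: render the pose into each observed ROI and sum
## squared pixel differences over the views. Keypoints far outside the ROI
## are penalized smoothly so the optimizer is pulled back toward the image.
make_cost <- function(obs, proj, fixed, mode = c("fast", "accurate"),
                      table = NULL, pitch = 0.04, pad = 10L,
                      digitize = FALSE) {
  mode <- match.arg(mode)
  if (mode == "fast" && is.null(table))
    stop("fast mode requires a lookup table")
  rois <- obs_roi(obs, pad)
  nv <- length(obs$images)
  base <- sum(vapply(rois, function(r) sum(r$img^2), numeric(1L)))
  ## flattened per-view projection parameters for the inlined hot path
  refr <- inherits(proj, "refractive_projection")
  vp <- if (refr) lapply(seq_len(nv), function(k) {
    ax <- CAMERA_AXES[[k]]
    list(ua = ax$u[1L], va = ax$v[1L], da = ax$depth,
         cu = proj$cams[[k]]$coef_u, cv = proj$cams[[k]]$coef_v)
  })
  ## anterior projections depend only on the rigid-body parameters and L;
  ## cache them so posterior-only polls pay for the tail redraw alone
  ant_key <- NULL
  ant_imgs <- vector("list", nv)
  last_at <- NULL
  last_mags <- NULL
  function(pose) {
    coords <- pose_to_coordinates(pose, fixed)
    kp3d <- rbind(coords$backbone, coords$eyes)
    at <- colMeans(kp3d)                  # magnification reference point,
    prof <- tail_profile(fixed, pose$length)  # matching render_views
    if (is.null(last_at) || !identical(at, last_at)) {
      last_mags <<- vapply(seq_len(nv), function(k)
        view_magnification(proj, k, at), numeric(1L))
      last_at <<- at
    }
    cost <- 0
    for (k in seq_len(nv)) {
      roi <- rois[[k]]
      mag_k <- last_mags[k]
      if (refr) {
        v <- vp[[k]]
        d_ <- (kp3d[, v$da] - proj$centre[v$da]) / proj$scale[v$da]
        tu <- (kp3d[, v$ua] - proj$centre[v$ua]) / proj$scale[v$ua]
        tv <- (kp3d[, v$va] - proj$centre[v$va]) / proj$scale[v$va]
        kc <- cbind(cubic_design(tu, d_) %*% v$cu - roi$origin[1L],
                    cubic_design(tv, d_) %*% v$cv - roi$origin[2L])
      } else {
        kp <- project_to_view(proj, k, kp3d)
        kc <- cbind(kp[, 1L] - roi$origin[1L], kp[, 2L] - roi$origin[2L])
      }
      over <- pmax(kc[, 1L] - (roi$nx - 1L), -kc[, 1L], 0) +
        pmax(kc[, 2L] - (roi$ny - 1L), -kc[, 2L], 0)
      if (any(over > 0)) {
        cost <- cost + base * (1 + sum(over))
        next
      }
      if (mode == "fast") {
        img <- render_fast_view(table, k, pose, kc, mag_k, roi$nx, roi$ny)
      } else {
        key <- c(pose$x0, pose$y0, pose$z0, pose$theta0, pose$phi0,
                 pose$gamma0, pose$length)
        if (is.null(ant_key) || !identical(key, ant_key)) {
          ant_imgs <<- vector("list", nv)
          ant_key <<- key
        }
        if (is.null(ant_imgs[[k]])) {
          img <- project_anterior_raw(pose, fixed, proj, k, rois[[k]]$origin,
                                      max(roi$nx, roi$ny), pitch)
          img <- img[seq_len(roi$nx), seq_len(roi$ny), drop = FALSE]
          if (max(img) > 0) img <- img / max(img)
          ant_imgs[[k]] <<- img
        } else img <- ant_imgs[[k]]
        img <- draw_tail(img, kc[2:10, , drop = FALSE],
                         prof$sigma_mm * mag_k, prof$intensity)
      }
      mx <- max(img)
      if (mx > 0) img <- img * (255 / mx)
      if (digitize) img <- round(img)             # 8-bit like the views
      cost <- cost + sum((roi$img - img)^2)
    }
    cost
  }
}

#' Template-matching cost of a pose against observed views
#'
#' Sum over camera views of the squared pixel differences between the
#' preprocessed observation crops and the rendered model projection.
#'
#' @param pose a \code{fish_pose}.
#' @param obs observation: a \code{view_triplet} or a list with
#'   \code{images}, \code{origins}, \code{size}.
#' @param proj projection (fitted \code{refractive_projection} or camera
#'   list).
#' @param fixed a \code{fish_body_params}.
#' @param mode \code{"fast"} (lookup sprites) or \code{"accurate"} (voxel
#'   anterior).
#' @param table lookup table (fast mode).
#' @param pitch voxel pitch for accurate mode, mm.
#' @param digitize round the rendered model to 8-bit before differencing
#'   (matches the digitized views, so a self-rendered pose costs exactly 0;
#'   the optimizers keep the un-digitized surface to avoid plateaus).
#' @return scalar cost (>= 0).
#' @export
cost_function <- function(pose, obs, proj, fixed = fish_body_params(),
                          mode = "accurate", table = NULL, pitch = 0.04,
                          digitize = TRUE) {
  if (inherits(obs, "view_triplet")) obs <- observation_from_triplet(obs)
  make_cost(obs, proj, fixed, mode = mode, table = table, pitch = pitch,
            pad = 8L, digitize = digitize)(pose)
}

default_param_scale <- function() {
  c(0.5, 0.5, 0.5, 0.2, rep(0.1, 8L), 0.2, rep(0.1, 8L), 0.2)
}

fit_result <- function(pose, cost, round, evals, converged, flag = "ok",
                       cost_pitch = NA_real_) {
  structure(list(pose = pose, cost = cost, round = round, evals = evals,
                 converged = converged, flag = flag,
                 cost_pitch = cost_pitch), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> round %s, cost %.4g, %d evaluations (%s)\n",
              x$round, x$cost, x$evals, x$flag))
  invisible(x)
}

## Weighted centroid of the bright (fish) pixels of a view crop, in sensor
## px; pixels below a fraction of the maximum are treated as background.
view_centroid <- function(img, origin, thresh_frac = 0.2) {
  nz <- which(img > thresh_frac * max(img), arr.ind = TRUE)
  w <- img[nz]
  c(sum((nz[, 1L] - 1L) * w), sum((nz[, 2L] - 1L) * w)) / sum(w) + origin
}

## First-frame brute force: straight backbone, orientation grid.
first_frame_search <- function(obs, proj, fixed, table, length,
                               theta_step = 10, phi_step = 10, gamma_step = 15,
                               phi_range = 60) {
  cents <- lapply(seq_along(obs$images), function(k)
    view_centroid(obs$images[[k]], obs$origins[[k]]))
  centre <- triangulate_point(proj, cents)$point
  fn <- make_cost(obs, proj, fixed, mode = "fast", table = table)
  thetas <- seq(-180, 180 - theta_step, by = theta_step) * pi / 180
  phis <- seq(-phi_range, phi_range, by = phi_step) * pi / 180
  gammas <- seq(-180, 180 - gamma_step, by = gamma_step) * pi / 180
  best <- NULL; best_cost <- Inf
  for (th in thetas) for (ph in phis) for (ga in gammas) {
    d <- c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
    head <- centre - 0.4 * length * d
    pose <- fish_pose(head[1L], head[2L], head[3L], theta0 = th, phi0 = ph,
                      gamma0 = ga, length = length)
    cst <- fn(pose)
    if (cst < best_cost) { best <- pose; best_cost <- cst }
  }
  best
}

#' Coarse pose optimization with the lookup-table renderer
#'
#' Pattern search over the 22 adjustable parameters using fast sprite
#' rendering. Without an initial guess, the first-frame protocol is used:
#' the larva centroid is triangulated from the view centroids and a brute
#' force scan over head orientations (straight backbone; yaw every 10 deg,
#' inclination every 10 deg in [-60, 60], roll every 15 deg) seeds the
#' search.
#'
#' @param obs observation (\code{view_triplet} or images/origins list).
#' @param proj projection.
#' @param table lookup table from [build_lookup_table_p()].
#' @param init optional initial \code{fish_pose} (e.g. the previous frame's
#'   fit).
#' @param fixed a \code{fish_body_params}.
#' @param length body length used when \code{init} is NULL, mm.
#' @param scale per-parameter poll scales (mm / rad).
#' @param mesh0,mesh_tol,max_eval pattern-search controls.
#' @param cost_ceiling converged costs above this are flagged
#'   \code{"low-confidence"}.
#' @return a \code{fit_result} with \code{round = "coarse"}.
#' @export
coarse_optimize <- function(obs, proj, table, init = NULL,
                            fixed = fish_body_params(), length = 4.0,
                            scale = default_param_scale(), mesh0 = 0.5,
                            mesh_tol = 5e-3, max_eval = 8000L,
                            cost_ceiling = Inf) {
  if (inherits(obs, "view_triplet")) obs <- observation_from_triplet(obs)
  if (is.null(init))
    init <- first_frame_search(obs, proj, fixed, table, length)
  fn <- make_cost(obs, proj, fixed, mode = "fast", table = table)
  L <- init$length
  obj <- function(p) fn(pose_from_vector_fast(p, length = L))
  ps <- pattern_search(obj, pose_to_vector(init), scale = scale,
                       mesh0 = mesh0, mesh_tol = mesh_tol,
                       max_eval = max_eval)
  flag <- if (ps$converged && ps$value > cost_ceiling) "low-confidence"
          else "ok"
  fit_result(pose_from_vector(ps$par, length = L), ps$value, "coarse",
             ps$evals, ps$converged, flag)
}

#' Fine pose optimization with accurate rendering
#'
#' Refines a coarse estimate in three phases -- anterior rigid-body
#' parameters only, posterior bending angles only, then all 22 parameters
#' jointly -- using voxel-projection rendering of the anterior at every
#' evaluation. If no improvement is found the coarse result is returned
#' flagged.
#'
#' @param obs observation.
#' @param proj projection.
#' @param init a \code{fit_result} from [coarse_optimize()] (or any pose in
#'   a \code{fit_result}).
#' @param fixed a \code{fish_body_params}.
#' @param pitch voxel pitch for the accurate anterior during the three
#'   phases, mm.
#' @param scale per-parameter scales.
#' @param mesh0,mesh_tol pattern-search controls per phase.
#' @param max_eval_phase evaluation budgets, recycled over the three phases.
#' @param polish_pitch voxel pitch of the final rigid-parameter polish, mm
#'   (the renderer's native pitch removes the residual discretization bias
#'   of the coarser working pitch); NULL disables the polish.
#' @param polish_eval evaluation budget of the polish stage.
#' @return a \code{fit_result} with \code{round = "fine"}; its cost (on
#'   the polish-pitch surface) is never above the accurate-render cost of
#'   the initialization on that same surface.
#' @export
fine_optimize <- function(obs, proj, init, fixed = fish_body_params(),
                          pitch = 0.06, scale = default_param_scale() * 0.4,
                          mesh0 = 0.5, mesh_tol = 8e-3,
                          max_eval_phase = c(250L, 350L, 850L),
                          polish_pitch = 0.03, polish_eval = 120L) {
  if (inherits(obs, "view_triplet")) obs <- observation_from_triplet(obs)
  fn <- make_cost(obs, proj, fixed, mode = "accurate", pitch = pitch)
  L <- init$pose$length
  p <- pose_to_vector(init$pose)
  f0 <- fn(init$pose)
  anterior_idx <- c(1:4, 13L, 22L)
  posterior_idx <- c(5:12, 14:21)
  phases <- list(anterior_idx, posterior_idx, seq_len(22L))
  budgets <- rep_len(max_eval_phase, 3L)
  total_evals <- 0L
  conv <- TRUE
  for (ph in seq_along(phases)) {
    idx <- phases[[ph]]
    obj <- function(sub) {
      q <- p; q[idx] <- sub
      fn(pose_from_vector_fast(q, length = L))
    }
    ## coupled poll directions for the joint phase: yaw-vs-lateral-bend and
    ## inclination-vs-dorsal-bend compensation (the sloppy modes of a chain
    ## rooted at the head), plus a slide along the current heading
    dirs <- NULL
    if (ph == 3L) {
      dirs <- matrix(0, 22L, 3L)
      dirs[4L, 1L] <- 0.08; dirs[5:12, 1L] <- -0.08
      dirs[13L, 2L] <- 0.08; dirs[14:21, 2L] <- -0.08
      h0 <- c(cos(p[13L]) * cos(p[4L]), cos(p[13L]) * sin(p[4L]),
              sin(p[13L]))
      dirs[1:3, 3L] <- 0.12 * h0
    }
    ps <- pattern_search(obj, p[idx], scale = scale[idx], mesh0 = mesh0,
                         mesh_tol = mesh_tol, max_eval = budgets[ph],
                         directions = dirs)
    p[idx] <- ps$par
    total_evals <- total_evals + ps$evals
    conv <- conv && ps$converged
  }
  ## translation polish: the residual after pattern search is often a small
  ## rigid shift; align rendered and observed intensity centroids per view
  ## and solve the stacked linear system for the lab translation, accepting
  ## steps only when they lower the cost
  p <- centroid_polish(p, L, obs, proj, fixed, fn, pitch)
  ## final rigid polish at the renderer's native voxel pitch: the coarser
  ## working pitch biases the optimum by a fraction of a pixel, which the
  ## matched-pitch surface removes
  cost_pitch <- pitch
  if (!is.null(polish_pitch) && polish_eval > 0L) {
    fn_p <- make_cost(obs, proj, fixed, mode = "accurate",
                      pitch = polish_pitch)
    idx <- anterior_idx
    obj_p <- function(sub) {
      q <- p; q[idx] <- sub
      fn_p(pose_from_vector_fast(q, length = L))
    }
    ps <- pattern_search(obj_p, p[idx], scale = scale[idx] * 0.625,
                         mesh0 = 0.25, mesh_tol = 0.02,
                         max_eval = polish_eval)
    p[idx] <- ps$par
    total_evals <- total_evals + ps$evals
    fn <- fn_p
    cost_pitch <- polish_pitch
  }
  f0p <- fn(init$pose)
  f1 <- fn(pose_from_vector(p, length = L))
  if (f1 > f0p)
    return(fit_result(init$pose, f0p, "fine", total_evals, conv,
                      "no-improvement", cost_pitch = cost_pitch))
  fit_result(pose_from_vector(p, length = L), f1, "fine", total_evals, conv,
             cost_pitch = cost_pitch)
}

## Closed-form rigid-translation refinement. For each view the difference
## between observed and rendered intensity centroids (bright pixels only)
## constrains the two transverse lab coordinates of that view; three views
## overdetermine the 3-D translation, solved by least squares.
centroid_polish <- function(p, L, obs, proj, fixed, fn, pitch,
                            iters = 3L, thresh_frac = 0.15) {
  rois <- obs_roi(obs, pad = 10L)
  wcent <- function(img) {
    m <- img > thresh_frac * max(img)
    if (!any(m)) return(c(NA_real_, NA_real_))
    nz <- which(m, arr.ind = TRUE)
    w <- img[nz]
    c(sum((nz[, 1L] - 1L) * w), sum((nz[, 2L] - 1L) * w)) / sum(w)
  }
  f_cur <- fn(pose_from_vector_fast(p, L))
  for (it in seq_len(iters)) {
    pose <- pose_from_vector_fast(p, L)
    tr <- tryCatch(render_views(pose, fixed, proj, mode = "accurate",
                                origins = lapply(rois, `[[`, "origin"),
                                size = max(vapply(rois, function(r)
                                  max(r$nx, r$ny), numeric(1L))),
                                pitch = pitch),
                   error = function(e) NULL)
    if (is.null(tr)) break
    A <- NULL; b <- NULL
    at <- c(pose$x0, pose$y0, pose$z0)
    for (k in seq_along(rois)) {
      roi <- rois[[k]]
      ren <- tr$images[[k]][seq_len(roi$nx), seq_len(roi$ny)]
      c_obs <- wcent(roi$img); c_ren <- wcent(ren)
      if (any(is.na(c_obs)) || any(is.na(c_ren))) next
      ax <- CAMERA_AXES[[k]]
      mag <- view_magnification(proj, k, at)
      ru <- numeric(3L); rv <- numeric(3L)
      ru[ax$u[1L]] <- ax$u[2L] * mag
      rv[ax$v[1L]] <- ax$v[2L] * mag
      A <- rbind(A, ru, rv)
      b <- c(b, c_obs - c_ren)
    }
    if (is.null(A)) break
    step <- tryCatch(drop(qr.solve(A, b)), error = function(e) NULL)
    if (is.null(step)) break
    q <- p
    q[1:3] <- q[1:3] + step
    f_new <- fn(pose_from_vector_fast(q, L))
    if (f_new < f_cur) { p <- q; f_cur <- f_new }
    ## longitudinal line search: sliding a tube-like body along its own
    ## axis moves the intensity centroids very little, so probe that
    ## direction explicitly
    d1 <- c(cos(p[13L]) * cos(p[4L]), cos(p[13L]) * sin(p[4L]), sin(p[13L]))
    ts <- seq(-0.12, 0.12, by = 0.04)
    fs <- vapply(ts, function(t_) {
      q <- p; q[1:3] <- q[1:3] + t_ * d1
      fn(pose_from_vector_fast(q, L))
    }, numeric(1L))
    jb <- which.min(fs)
    if (fs[jb] < f_cur) {
      ## parabolic refinement around the best grid point
      t_best <- ts[jb]
      if (jb > 1L && jb < length(ts)) {
        den <- fs[jb - 1L] - 2 * fs[jb] + fs[jb + 1L]
        if (den > 0)
          t_best <- ts[jb] + 0.04 * (fs[jb - 1L] - fs[jb + 1L]) / (2 * den)
      }
      q <- p; q[1:3] <- q[1:3] + t_best * d1
      f_ref <- fn(pose_from_vector_fast(q, L))
      if (f_ref < fs[jb]) { p <- q; f_cur <- f_ref }
      else { p[1:3] <- p[1:3] + ts[jb] * d1; f_cur <- fs[jb] }
    }
    if (max(abs(step)) < 1e-4 && jb == (length(ts) + 1L) %/% 2L) break
  }
  p
}

#' Estimate the body length from straight-pose frames
#'
#' For each of the supplied frames (in real use the first and last 5 frames
#' of a bout, where the backbone is expected straight), triangulates the
#' larva centroid, fits the best straight-pose orientation starting from a
#' 4.5 mm model (position and orientation pattern search against the fast
#' renderer), and converts the segmented image extent along the projected
#' body axis into a metric length per view. The estimate is averaged over
#' views and frames; a per-frame spread above 10 percent flags the result.
#'
#' @param obs_frames list of observations (one per frame).
#' @param proj projection.
#' @param table lookup table.
#' @param fixed a \code{fish_body_params}.
#' @param init_length initial model length, mm (default 4.5).
#' @return list with \code{length} (mm), \code{per_frame}, \code{flag}.
#' @export
estimate_length <- function(obs_frames, proj, table,
                            fixed = fish_body_params(), init_length = 4.5) {
  if (length(obs_frames) < 10L)
    warning("fewer than 10 frames supplied; averaging over available frames")
  per_frame <- vapply(obs_frames, function(obs) {
    if (inherits(obs, "view_triplet")) obs <- observation_from_triplet(obs)
    pose0 <- first_frame_search(obs, proj, fixed, table, init_length,
                                theta_step = 20, phi_step = 15,
                                gamma_step = 90)
    fn <- make_cost(obs, proj, fixed, mode = "fast", table = table)
    idx <- c(1:4, 13L)
    p <- pose_to_vector(pose0)
    obj <- function(sub) {
      q <- p; q[idx] <- sub
      fn(pose_from_vector_fast(q, length = init_length))
    }
    ps <- pattern_search(obj, p[idx], scale = c(0.5, 0.5, 0.5, 0.15, 0.15),
                         mesh0 = 1, mesh_tol = 0.02, max_eval = 1500L)
    p[idx] <- ps$par
    pose <- pose_from_vector(p, length = init_length)
    d <- c(cos(pose$phi0) * cos(pose$theta0),
           cos(pose$phi0) * sin(pose$theta0), sin(pose$phi0))
    ests <- numeric(0)
    for (k in seq_along(obs$images)) {
      img <- obs$images[[k]]
      ## largest connected component above threshold: isolated bright noise
      ## pixels would otherwise stretch the extent
      lab <- EBImage::imageData(EBImage::bwlabel(
        EBImage::Image(img > 0.2 * max(img))))
      if (max(lab) == 0) next
      comp <- which.max(tabulate(lab[lab > 0]))
      nz <- which(lab == comp, arr.ind = TRUE)
      if (nrow(nz) < 10L) next
      ax <- CAMERA_AXES[[k]]
      w_img <- c(ax$u[2L] * d[ax$u[1L]], ax$v[2L] * d[ax$v[1L]])
      fr <- sqrt(sum(w_img^2))
      if (fr < 0.5) next
      u <- w_img / fr
      s <- (nz[, 1L] - 1L) * u[1L] + (nz[, 2L] - 1L) * u[2L]
      mag <- view_magnification(proj, k, c(pose$x0, pose$y0, pose$z0))
      ests <- c(ests, diff(range(s)) / mag / fr)
    }
    if (length(ests) == 0) NA_real_ else mean(ests)
  }, numeric(1L))
  per_frame <- per_frame[is.finite(per_frame)]
  est <- mean(per_frame)
  spread <- if (length(per_frame) > 1L) diff(range(per_frame)) / est else 0
  list(length = est, per_frame = per_frame,
       flag = if (spread > 0.1) "high-spread" else "ok")
}
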