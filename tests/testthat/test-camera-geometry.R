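test_that("linear projection reproduces hand-computed pinhole geometry", {
  cam <- pinhole_camera(fx = 1000, fy = 1000, u0 = 320, v0 = 240,
                        rotation = diag(3), translation = c(0, 0, 100))
  ## point on the principal axis lands on the principal point
  expect_equal(drop(project_linear(cam, c(0, 0, 0))), c(u = 320, v = 240))
  ## 1 mm lateral offset at 100 mm with f = 1000 px gives 10 px
  expect_equal(drop(project_linear(cam, c(1, 0, 0))), c(u = 330, v = 240))
  ## a point behind the camera is rejected
  expect_error(project_linear(cam, c(0, 0, -150)), "behind")
})

test_that("camera matrix factorizes as extrinsic times intrinsic", {
  cam <- fixture_cams()[[2]]
  P <- camera_matrix(cam)
  pts <- rbind(c(3, -4, 5), c(-10, 2, 7), c(0, 0, 0))
  hom <- cbind(pts, 1) %*% P
  px_via_P <- hom[, 1:2] / hom[, 3]
  expect_equal(unname(px_via_P), unname(project_linear(cam, pts)),
               tolerance = 1e-12)
})

test_that("ray-traced refraction reduces to the pinhole limit", {
  cams <- fixture_cams()
  opt1 <- tank_optics(n_glass = 1, n_water = 1)
  pts <- rbind(c(5, -7, 3), c(-12, 8, -10), c(0.3, 0.3, 20))
  for (k in 1:3)
    expect_equal(simulate_refraction(opt1, cams[[k]], pts),
                 project_linear(cams[[k]], pts), tolerance = 1e-6)
  ## normal incidence: a point on the principal axis is undeviated
  opt <- fixture_optics()
  expect_equal(drop(simulate_refraction(opt, cams[[1]], c(0, 0, 4))),
               drop(project_linear(cams[[1]], c(0, 0, 4))),
               tolerance = 1e-9)
})

test_that("refraction displacement matches an independent Snell bisection", {
  opt <- fixture_optics()
  cam <- fixture_cams()[[1]]            # bottom camera, axis +z
  p <- c(9, 0, 6)                       # off-axis in x only
  ## independent oracle: bisect over the radial crossing point at the inner
  ## wall; Snell's law written via angles on either side of each interface
  D <- opt$cam_distance
  h <- opt$side / 2
  cam_z <- -D                           # camera centre on the z axis
  z_in <- -h                            # inner wall
  z_out <- -h - opt$glass               # outer wall
  snell_mismatch <- function(r_in) {
    ## water path: from p to (r_in, z_in); angle wrt interface normal (z)
    th_w <- atan2(p[1] - r_in, p[3] - z_in)
    sin_g <- opt$n_water * sin(th_w) / opt$n_glass
    th_g <- asin(sin_g)
    r_out <- r_in - tan(th_g) * opt$glass
    sin_a <- opt$n_glass * sin_g / opt$n_air
    th_a <- asin(min(sin_a, 1))
    ## air path must aim at the camera centre
    r_cam <- r_out - tan(th_a) * (z_out - cam_z)
    r_cam - 0
  }
  r_in <- uniroot(snell_mismatch, c(0, p[1]), tol = 1e-13)$root
  th_w <- atan2(p[1] - r_in, p[3] - z_in)
  sin_a <- opt$n_water * sin(th_w) / opt$n_air
  th_a <- asin(sin_a)
  f <- opt$focal_mm * 1000 / opt$pixel_um
  u_expected <- opt$sensor[1] / 2 + f * tan(th_a)
  got <- unname(drop(simulate_refraction(opt, cam, p)))
  expect_equal(got[1], u_expected, tolerance = 1e-6)
  expect_equal(got[2], opt$sensor[2] / 2, tolerance = 1e-9)
  ## and the displacement from the pinhole projection is substantial
  expect_gt(abs(got[1] - project_linear(cam, p)[1]), 5)
})

test_that("cubic fit contains the affine projection exactly", {
  cams <- fixture_cams()
  ocams <- lapply(1:3, function(k)
    orthographic_camera(19, 70, 70, rotation = cams[[k]]$rotation))
  g <- fixture_grid()
  px <- lapply(ocams, function(cam) project_linear(cam, g$dots))
  fit <- fit_refractive_projection(g$dots, px)
  expect_lt(max(fit$rms_px), 1e-6)
})

test_that("projection functions are separable per pixel axis", {
  proj <- fixture_proj()
  ## moving the lab coordinate a pixel axis does not depend on leaves that
  ## pixel coordinate unchanged: for camera 1, u depends on (x, z) only
  p0 <- c(3, -5, 7)
  p1 <- c(3, 10, 7)                      # y changed only
  px0 <- project_refractive(proj, p0, cameras = 1)[[1]]
  px1 <- project_refractive(proj, p1, cameras = 1)[[1]]
  expect_equal(px0[1], px1[1], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(px0[2], px1[2])))
})

test_that("cubic fit residual decreases with polynomial degree", {
  g <- fixture_grid()
  px <- g$pixels_water[[1]][, 1]
  t_ <- g$dots[, 1] / 35; d_ <- g$dots[, 3] / 35
  rms_for_degree <- function(deg) {
    terms <- list()
    for (a in 0:deg) for (b in 0:(deg - a))
      terms[[length(terms) + 1]] <- t_^a * d_^b
    X <- do.call(cbind, terms)
    sqrt(mean(lm.fit(X, px)$residuals^2))
  }
  r <- vapply(1:3, rms_for_degree, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("degenerate single-axis-tilt dot layouts are rejected by name", {
  opt <- fixture_optics(); cams <- fixture_cams()
  ## tilts about y only: for camera 1, z is a linear function of x on every
  ## plane, so the (transverse, depth) design is rank-deficient
  g <- simulate_dot_grid(opt, cams, nx = 9, ny = 9, pitch = 7,
                         orientations = cbind(0, c(-20, 0, 20), 0))
  expect_error(fit_refractive_projection(g$dots, g$pixels_water),
               "camera 1")
})

test_that("in-air dot reconstruction minimizes summed reprojection error", {
  g <- fixture_grid(); cams <- fixture_cams()
  sub <- 1:25
  px <- lapply(g$pixels_air, function(m) m[sub, , drop = FALSE])
  rec <- reconstruct_dots_air(px, cams)
  expect_lt(max(abs(rec - g$dots[sub, ])), 1e-6)

  ## with pixel noise, matches a brute-force local grid search within 10%
  set.seed(4)
  noisy <- lapply(px, function(m) m + matrix(rnorm(length(m), 0, 0.5),
                                             nrow(m)))
  rec_n <- reconstruct_dots_air(noisy, cams)
  offs <- as.matrix(expand.grid(dx = seq(-0.2, 0.2, by = 0.01),
                                dy = seq(-0.2, 0.2, by = 0.01),
                                dz = seq(-0.2, 0.2, by = 0.01)))
  grid_err <- vapply(1:10, function(i) {
    cand <- sweep(offs, 2, g$dots[i, ], "+")
    sse <- numeric(nrow(cand))
    for (k in 1:3) {
      pp <- project_linear(cams[[k]], cand)
      sse <- sse + (pp[, 1] - noisy[[k]][i, 1])^2 +
        (pp[, 2] - noisy[[k]][i, 2])^2
    }
    sqrt(sum((cand[which.min(sse), ] - g$dots[i, ])^2))
  }, numeric(1))
  gn_err <- sqrt(rowSums((rec_n[1:10, ] - g$dots[1:10, ])^2))
  expect_lt(abs(mean(gn_err) - mean(grid_err)), 0.1 * mean(grid_err) + 0.02)
})

test_that("refraction-corrected triangulation round-trips exactly", {
  proj <- fixture_proj()
  pts <- rbind(c(2, 3, -4), c(-10, 5, 12), c(0, 0, 0))
  for (i in seq_len(nrow(pts))) {
    px <- project_refractive(proj, pts[i, ])
    tr <- triangulate_point(proj, lapply(px, drop))
    expect_lt(sqrt(sum((tr$point - pts[i, ])^2)), 1e-6)
    expect_true(tr$converged)
  }
})

test_that("pixel perturbations propagate per the projection Jacobian", {
  proj <- fixture_proj()
  x0 <- c(4, -3, 6)
  px <- lapply(project_refractive(proj, x0), drop)
  ## numeric Jacobian of the stacked 6-vector projection wrt the 3 lab coords
  J <- matrix(0, 6, 3)
  eps <- 1e-4
  for (j in 1:3) {
    e <- numeric(3); e[j] <- eps
    pp <- unlist(lapply(project_refractive(proj, x0 + e), drop))
    pm <- unlist(lapply(project_refractive(proj, x0 - e), drop))
    J[, j] <- (pp - pm) / (2 * eps)
  }
  dpix <- rep(c(0.5, -0.5), 3)
  pred_shift <- drop(solve(crossprod(J), crossprod(J, dpix)))
  px_pert <- lapply(seq_along(px), function(k) px[[k]] + dpix[(2 * k - 1):(2 * k)])
  tr <- triangulate_point(proj, px_pert)
  expect_equal(tr$point - x0, pred_shift, tolerance = 0.05)
})

test_that("ray table rays agree with the physical refracted rays", {
  proj <- fixture_proj()
  opt <- fixture_optics(); cams <- fixture_cams()
  set.seed(9)
  for (rep in 1:5) {
    p <- runif(3, -15, 15)
    px <- drop(simulate_refraction(opt, cams[[1]], matrix(p, 1)))
    ray <- pixel_to_ray(proj, 1, px)
    expect_true(ray$valid)
    d <- p - ray$a
    miss <- sqrt(sum((d - sum(d * ray$r) * ray$r)^2))
    expect_lt(miss, 0.01)              # < 10 um inside the tank
    ## origin sits on the central plane perpendicular to the camera axis
    expect_equal(ray$a[3], 0, tolerance = 1e-9)
  }
})

test_that("three collinear probe points define the stored ray", {
  proj <- fixture_proj()
  ray <- pixel_to_ray(proj, 2, c(350, 230))
  probes <- t(vapply(c(-20, 0, 20), function(d)
    larvapose:::pixel_to_point_at_depth(proj, 2, c(350, 230), d),
    numeric(3)))
  for (i in 1:3) {
    d <- probes[i, ] - ray$a
    expect_lt(sqrt(sum((d - sum(d * ray$r) * ray$r)^2)), 1e-3)
  }
})

test_that("pinhole ray tables pass through the optical centre", {
  cams <- fixture_cams()
  tab <- build_ray_table(cams[[1]], 1, px_x = c(300, 330), px_y = c(220, 260))
  cc <- larvapose:::camera_center(cams[[1]])
  for (i in 1:2) for (j in 1:2) {
    a <- tab$a[i, j, ]; r <- tab$r[i, j, ]
    d <- cc - a
    expect_lt(sqrt(sum((d - sum(d * r) * r)^2)), 1e-6)
  }
})

test_that("larvae are matched across views by ray proximity", {
  proj <- fixture_proj()
  opt <- fixture_optics(); cams <- fixture_cams()
  fish <- rbind(c(3, 2, 1), c(-5, -4, -6))    # 10+ mm apart
  cents <- lapply(1:3, function(k) simulate_refraction(opt, cams[[k]], fish))
  ## single larva, noiseless, exact pinhole geometry: delta is numerically 0
  lin <- lapply(1:3, function(k) project_linear(cams[[k]], fish[1, ]))
  m0 <- match_larvae_across_views(lin, cams, eps = 1)
  expect_equal(nrow(m0), 1L)
  expect_lt(m0$delta, 1e-6)
  ## single larva through the fitted refractive projection: delta stays at
  ## the few-micrometre scale of the cubic fit residual
  one <- lapply(cents, function(m) m[1, , drop = FALSE])
  m1 <- match_larvae_across_views(one, proj, eps = 1)
  expect_equal(nrow(m1), 1L)
  expect_lt(m1$delta, 0.02)
  ## two larvae: exactly the two true pairings survive at eps = 1 mm
  m2 <- match_larvae_across_views(cents, proj, eps = 1)
  expect_equal(nrow(m2), 2L)
  expect_setequal(paste(m2$i, m2$j, m2$k), c("1 1 1", "2 2 2"))
  ## oracle: enumerate all 8 triples with the closed-form skew distance
  rays <- lapply(1:3, function(k) lapply(1:2, function(i)
    pixel_to_ray(proj, k, cents[[k]][i, ])))
  deltas <- sapply(1:2, function(i) sapply(1:2, function(j) sapply(1:2,
    function(l) {
      R1 <- rays[[1]][[i]]; R2 <- rays[[2]][[j]]; R3 <- rays[[3]][[l]]
      max(ray_distance(R1$a, R1$r, R2$a, R2$r),
          ray_distance(R2$a, R2$r, R3$a, R3$r),
          ray_distance(R1$a, R1$r, R3$a, R3$r))
    })))
  expect_equal(sum(deltas < 1), 2L)
  ## permutation invariance of the matching
  perm <- lapply(cents, function(m) m[2:1, , drop = FALSE])
  m3 <- match_larvae_across_views(perm, proj, eps = 1)
  expect_equal(sort(m3$delta), sort(m2$delta), tolerance = 1e-9)
  ## empty centroid list in any camera gives an empty result
  expect_equal(nrow(match_larvae_across_views(
    list(cents[[1]], cents[[2]][0, , drop = FALSE], cents[[3]]), proj)), 0L)
})

test_that("calibration and dot files round-trip", {
  proj <- fixture_proj()
  g <- fixture_grid()
  f <- tempfile(fileext = ".json")
  write_calibration(proj, f)
  proj2 <- read_calibration(f)
  pts <- rbind(c(1, 2, 3), c(-5, 4, -8))
  expect_equal(project_refractive(proj2, pts), project_refractive(proj, pts),
               tolerance = 1e-10)
  fc <- tempfile(fileext = ".csv")
  write_dot_csv(g, fc)
  back <- read_dot_csv(fc)
  expect_equal(back$pixels_water[[2]], unname(g$pixels_water[[2]]),
               tolerance = 1e-9)
  expect_equal(back$pixels_air[[3]], unname(g$pixels_air[[3]]),
               tolerance = 1e-9)
})
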