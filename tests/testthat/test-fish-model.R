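test_that("a straight pose yields collinear equally spaced backbone points", {
  pose <- fish_pose(length = 4.5)
  co <- pose_to_coordinates(pose)
  expect_equal(dim(co$backbone), c(10L, 3L))
  ## 10 points spaced L/9 = 0.5 mm along the heading axis
  expect_equal(co$backbone[, 1], seq(0, 4.5, by = 0.5))
  expect_equal(co$backbone[, 2], rep(0, 10))
  expect_equal(co$backbone[, 3], rep(0, 10))
})

test_that("segment chords all equal L/9 for arbitrary poses", {
  set.seed(1)
  for (rep in 1:20) {
    pose <- random_pose(bend = 0.6)
    b <- pose_to_coordinates(pose)$backbone
    lens <- sqrt(rowSums(diff(b)^2))
    expect_equal(lens, rep(pose$length / 9, 9), tolerance = 1e-9)
  }
})

test_that("planar constant-curvature chain matches a 2-D rotation oracle", {
  c_ <- 0.25
  pose <- fish_pose(dtheta = rep(c_, 8), dphi = rep(0, 8), length = 4.5)
  b <- pose_to_coordinates(pose)$backbone
  expect_equal(max(abs(b[, 3])), 0, tolerance = 1e-12)   # planar
  ## oracle: cumulative 2-D rotations of the segment vector
  seg <- 0.5
  p <- c(0, 0); ang <- 0
  oracle <- matrix(0, 10, 2)
  for (i in 1:9) {
    p <- p + seg * c(cos(ang), sin(ang))
    oracle[i + 1, ] <- p
    if (i <= 8) ang <- ang + c_
  }
  expect_equal(b[, 1:2], oracle, tolerance = 1e-9)
})

test_that("coordinates_to_pose inverts the forward chain", {
  set.seed(2)
  for (rep in 1:25) {
    pose <- random_pose(bend = 0.5)
    co <- pose_to_coordinates(pose)
    back <- coordinates_to_pose(co)
    expect_equal(pose_to_vector(back), pose_to_vector(pose),
                 tolerance = 1e-6)
    expect_equal(back$length, pose$length, tolerance = 1e-9)
  }
})

test_that("rigid rotations change only the head Euler angles", {
  set.seed(3)
  pose <- random_pose(bend = 0.4)
  co <- pose_to_coordinates(pose)
  R <- larvapose:::rot_z(0.6) %*% larvapose:::rot_y(-0.3) %*%
    larvapose:::rot_x(0.2)
  rot <- list(backbone = co$backbone %*% t(R), eyes = co$eyes %*% t(R))
  back <- coordinates_to_pose(rot)
  expect_equal(back$dtheta, pose$dtheta, tolerance = 1e-6)
  expect_equal(back$dphi, pose$dphi, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(back$theta0, pose$theta0)))
})

test_that("straight collinear coordinates give zero bending angles", {
  b <- cbind(seq(0, 4.5, by = 0.5), 1, -2)
  pose <- coordinates_to_pose(list(backbone = b))
  expect_equal(pose$dtheta, rep(0, 8), tolerance = 1e-9)
  expect_equal(pose$dphi, rep(0, 8), tolerance = 1e-9)
})

test_that("anterior voxel intensity is the max over organ Gaussians", {
  fixed <- fish_body_params()
  pose <- fish_pose()
  ## silencing head, belly and one eye leaves a single Gaussian
  solo <- fish_body_params(brightness = c(eye = 255, head = 1e-9,
                                          belly = 1e-9))
  v <- render_anterior_voxels(pose, solo, pitch = 0.03)
  org <- larvapose:::anterior_organs(solo, pose$length)
  grid <- as.matrix(expand.grid(x = v$x, y = v$y, z = v$z))
  gauss <- function(p, mu, sig) exp(-0.5 * sum(((p - mu) / sig)^2))
  idx <- sample(nrow(grid), 50)
  for (i in idx) {
    expected <- max(gauss(grid[i, ], org$mu[1, ], org$sigma[1, ]),
                    gauss(grid[i, ], org$mu[2, ], org$sigma[2, ]))
    expect_equal(v$values[i], expected, tolerance = 1e-9)
  }

  ## analytic max of two overlapping Gaussians at a midpoint
  v2 <- render_anterior_voxels(pose, fixed, pitch = 0.03)
  org2 <- larvapose:::anterior_organs(fixed, pose$length)
  mid <- (org2$mu[3, ] + org2$mu[4, ]) / 2      # between head and belly
  vals <- vapply(1:4, function(k)
    org2$bright[k] * gauss(mid, org2$mu[k, ], org2$sigma[k, ]), numeric(1))
  direct <- larvapose:::anterior_intensity(matrix(mid, 1), org2)
  expect_equal(direct, max(vals), tolerance = 1e-12)
})

test_that("voxel intensity is invariant to the eye index ordering", {
  fixed <- fish_body_params()
  org <- larvapose:::anterior_organs(fixed, 4)
  swapped <- org
  swapped$mu <- org$mu[c(2, 1, 3, 4), ]
  swapped$sigma <- org$sigma[c(2, 1, 3, 4), ]
  pts <- matrix(runif(60, -0.2, 1), 20, 3)
  expect_equal(larvapose:::anterior_intensity(pts, org),
               larvapose:::anterior_intensity(pts, swapped))
})

test_that("orthographic bottom-view pixels are voxel column sums", {
  fixed <- fish_body_params()
  pose <- fish_pose(theta0 = 0.4, gamma0 = 0.3,
                    dtheta = rep(0.1, 8), length = 4)
  pitch <- 0.05
  mag <- 1 / pitch                       # one pixel per voxel column
  ocam <- list(orthographic_camera(mag, 70, 70))
  img <- larvapose:::project_anterior_raw(pose, fixed, ocam, 1,
                                          origin = c(0, 0), size = 141,
                                          pitch = pitch)
  ## voxel model on a grid aligned with the pixel raster
  v <- render_anterior_voxels(pose, fixed, pitch = pitch)
  sums <- apply(v$values, c(1, 2), sum)
  ## compare the totals and the brightest column (binning alignment differs
  ## by at most one voxel at the crop edges)
  expect_equal(sum(img), sum(sums), tolerance = 0.02)
  expect_equal(max(img), max(sums), tolerance = 0.05)
})

test_that("every rendered view is rescaled to a 255 maximum", {
  proj <- fixture_proj()
  tr <- render_views(fixture_pose(), proj = proj, mode = "accurate")
  for (img in tr$images) {
    expect_equal(max(img), 255)
    expect_true(all(img >= 0 & img <= 255))
  }
  expect_equal(length(tr$images), 3L)
  expect_equal(dim(tr$images[[1]]), c(141L, 141L))
})

test_that("fast and accurate renders of one pose agree within sprite error", {
  proj <- fixture_proj()
  tab <- fixture_table()
  ## self-comparison oracle: the accurate render probed against itself under
  ## a one-bin orientation shift bounds the lookup discretization error
  pose <- fixture_pose()
  acc <- render_views(pose, proj = proj, mode = "accurate")
  pose_shift <- pose
  pose_shift$theta0 <- pose$theta0 + 5 * pi / 180
  acc_shift <- render_views(pose_shift, proj = proj, mode = "accurate",
                            origins = acc$origins)
  mcor <- function(a, b) {
    m <- a > 0 | b > 0
    cor(a[m], b[m])
  }
  bound <- min(vapply(1:3, function(k)
    mcor(acc$images[[k]], acc_shift$images[[k]]), numeric(1)))
  fast <- render_views(pose, proj = proj, mode = "fast", table = tab,
                       origins = acc$origins)
  fast_cor <- min(vapply(1:3, function(k)
    mcor(acc$images[[k]], fast$images[[k]]), numeric(1)))
  expect_gt(fast_cor, bound)
  expect_gt(fast_cor, 0.9)
})

test_that("orthographic renders are translation-equivariant", {
  fixed <- fish_body_params()
  mag <- 20
  ocams <- list(orthographic_camera(mag, 70, 70))
  pose <- fish_pose(theta0 = 0.5, dtheta = rep(0.15, 8))
  origin <- c(20, 10)
  tr1 <- render_views(pose, fixed, ocams, mode = "accurate",
                      origins = list(origin))
  pose2 <- pose
  pose2$x0 <- pose$x0 + 1 / mag          # exactly one pixel
  tr2 <- render_views(pose2, fixed, ocams, mode = "accurate",
                      origins = list(origin + c(0, 0)))
  shifted <- tr2$images[[1]][2:141, ]
  expect_lt(max(abs(shifted - tr1$images[[1]][1:140, ])), 1 + 1e-9)
})

test_that("accurate renders converge as the voxel pitch shrinks", {
  proj <- fixture_proj()
  pose <- fixture_pose()
  base <- render_views(pose, proj = proj, mode = "accurate", pitch = 0.015)
  imgs <- lapply(c(0.06, 0.03), function(p)
    render_views(pose, proj = proj, mode = "accurate", pitch = p,
                 origins = base$origins))
  dev <- vapply(imgs, function(tr)
    mean(abs(tr$images[[1]] - base$images[[1]])), numeric(1))
  expect_lt(dev[2], dev[1])              # halving the pitch halves the error
})

test_that("a pose outside the field of view names the offending cameras", {
  proj <- fixture_proj()
  pose <- fixture_pose()
  origins <- lapply(1:3, function(k) c(1e4, 1e4))
  expect_error(render_views(pose, proj = proj, mode = "accurate",
                            origins = origins), "camera")
})

test_that("pose tables round-trip through CSV", {
  set.seed(8)
  poses <- replicate(5, random_pose(), simplify = FALSE)
  f <- tempfile(fileext = ".csv")
  write_pose_csv(poses, f)
  back <- read_pose_csv(f)
  for (i in 1:5)
    expect_equal(pose_to_vector(back[[i]]), pose_to_vector(poses[[i]]),
                 tolerance = 1e-9)
})
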