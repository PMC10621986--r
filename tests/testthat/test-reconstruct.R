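test_that("backbone triangulation round-trips noise-free keypoints", {
  proj <- fixture_proj()
  pose <- fixture_pose()
  kps <- pose_keypoints(pose, proj)
  bb <- triangulate_backbone(lapply(kps, function(m) m[1:10, ]), proj)
  truth <- pose_to_coordinates(pose)$backbone
  expect_lt(max(sqrt(rowSums((bb$points - truth)^2))), 1e-3)
  expect_true(all(!bb$flagged))
})

test_that("keypoint noise propagates like the projection Jacobian predicts", {
  proj <- fixture_proj()
  pose <- fixture_pose()
  kps <- pose_keypoints(pose, proj)
  truth <- pose_to_coordinates(pose)$backbone
  ## covariance-propagation oracle for point 5: J+ sigma^2 (J+)' with the
  ## numeric Jacobian of the stacked projection
  x0 <- truth[5, ]
  J <- matrix(0, 6, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- 1e-4
    pp <- unlist(lapply(project_refractive(proj, x0 + e), drop))
    pm <- unlist(lapply(project_refractive(proj, x0 - e), drop))
    J[, j] <- (pp - pm) / 2e-4
  }
  sig <- 1
  cov3d <- solve(crossprod(J)) * sig^2
  pred_rms <- sqrt(sum(diag(cov3d)))
  set.seed(50)
  errs <- replicate(60, {
    noisy <- lapply(kps, function(m) m + matrix(rnorm(24, 0, sig), 12, 2))
    bb <- triangulate_backbone(lapply(noisy, function(m) m[1:10, ]), proj,
                               flag_px = Inf)
    sqrt(sum((bb$points[5, ] - truth[5, ])^2))
  })
  obs_rms <- sqrt(mean(errs^2))
  expect_gt(obs_rms, pred_rms / 2)
  expect_lt(obs_rms, pred_rms * 2)
})

test_that("eye resolution enumerates all 8 assignments and fixes swaps", {
  proj <- fixture_proj()
  pose <- fixture_pose()
  co <- pose_to_coordinates(pose)
  eye_px <- lapply(1:3, function(k) project_to_view_test(proj, k, co$eyes))
  ## consistent labelling: identity assignment wins with near-zero residual
  r0 <- resolve_eyes(eye_px, proj)
  expect_equal(unname(r0$assignment), c(1, 1, 1))
  expect_lt(r0$residual, 0.1)
  expect_lt(max(abs(r0$eyes - co$eyes)), 1e-3)
  ## eyes swapped in exactly one view: the correct 3-D eyes are still found
  swapped <- eye_px
  swapped[[2]] <- swapped[[2]][2:1, ]
  r1 <- resolve_eyes(swapped, proj)
  expect_equal(unname(r1$assignment), c(1, 2, 1))
  expect_lt(max(abs(r1$eyes - co$eyes)), 1e-3)
  ## global swap equivalence: only the labelling flips, the pair is equal
  allsw <- lapply(eye_px, function(m) m[2:1, ])
  r2 <- resolve_eyes(allsw, proj)
  expect_lt(max(abs(r2$eyes[2:1, ] - co$eyes)), 1e-3)
})

test_that("roll follows the eye axis under the never-belly-up convention", {
  ## horizontal eye axis, dorsal up: zero roll
  p0 <- fish_pose(theta0 = 0.9, phi0 = 0.2, gamma0 = 0)
  co <- pose_to_coordinates(p0)
  expect_equal(assign_roll(co$eyes, co$backbone), 0, tolerance = 1e-9)
  ## a known 20 degree rotation about the heading is recovered exactly
  p20 <- fish_pose(theta0 = 0.9, phi0 = 0.2, gamma0 = 20 * pi / 180)
  co20 <- pose_to_coordinates(p20)
  expect_equal(assign_roll(co20$eyes, co20$backbone), 20 * pi / 180,
               tolerance = 1e-9)
  ## a belly-up labelling is folded back into (-pi/2, pi/2]
  expect_equal(assign_roll(co20$eyes[2:1, ], co20$backbone), 20 * pi / 180,
               tolerance = 1e-9)
})

test_that("arc-length resampling equalizes spacing and preserves endpoints", {
  ## already equidistant collinear points pass through unchanged
  line <- cbind(seq(0, 4.5, by = 0.5), 2, -1)
  out <- resample_spline(line)
  expect_equal(out, line, tolerance = 1e-9)
  ## unevenly spaced points on a quarter circle: output chords equalize
  t_ <- sort(c(0, runif(8, 0, pi / 2), pi / 2))
  circ <- cbind(10 * cos(t_), 10 * sin(t_), 0)
  res <- resample_spline(circ)
  chords <- sqrt(rowSums(diff(res)^2))
  expect_lt(diff(range(chords)) / mean(chords), 1e-3)
  expect_equal(res[1, ], circ[1, ])
  expect_equal(res[10, ], circ[10, ])
  ## dense-sampling oracle: equal arc spacing on the spline itself
  dense_t <- seq(0, pi / 2, length.out = 20001)
  dense <- cbind(10 * cos(dense_t), 10 * sin(dense_t), 0)
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  marks <- sapply(seq(0, max(arc), length.out = 10), function(a)
    dense[which.min(abs(arc - a)), ])
  expect_lt(max(abs(res - t(marks))), 0.02)
  expect_error(resample_spline(rbind(line[1:9, ], line[9, ])), "degenerate")
})

test_that("full loop closure recovers poses from noise-free keypoints", {
  proj <- fixture_proj()
  set.seed(51)
  worst_bb <- 0; worst_ang <- 0
  for (rep in 1:15) {
    pose <- random_pose(bend = 0.35)
    kps <- pose_keypoints(pose, proj)
    rec <- reconstruct_pose(lapply(kps, identity),
                            lapply(1:3, function(k) c(0, 0)), proj)
    co <- pose_to_coordinates(pose)
    worst_bb <- max(worst_bb,
                    mean(sqrt(rowSums((rec$backbone - co$backbone)^2))))
    dang <- abs(wrap_angle(pose_to_vector(rec$pose)[4:22] -
                             pose_to_vector(pose)[4:22]))
    worst_ang <- max(worst_ang, max(dang))
  }
  expect_lt(worst_bb, 0.02)
  expect_lt(worst_ang, 1 * pi / 180)
})

test_that("the prediction score is a masked minimum-correlation", {
  proj <- fixture_proj()
  pose <- fixture_pose()
  tr <- render_views(pose, proj = proj, mode = "accurate")
  ## self-comparison is a perfect prediction
  sc <- prediction_score(tr, pose, proj, mode = "accurate")
  expect_equal(sc$score, 1, tolerance = 1e-12)
  expect_equal(sc$flag, "ok")
  ## the photometric negative anticorrelates exactly
  neg <- list(images = lapply(tr$images, function(m) 255 - m),
              origins = tr$origins, size = tr$size)
  expect_equal(prediction_score(neg, pose, proj, mode = "accurate")$score,
               -1, tolerance = 1e-12)
  ## independent two-pass correlation oracle on a perturbed pose
  pert <- pose
  pert$x0 <- pose$x0 + 0.06
  sc2 <- prediction_score(tr, pert, proj, mode = "accurate")
  ren <- render_views(pert, proj = proj, mode = "accurate",
                      origins = tr$origins)
  oracle <- vapply(1:3, function(k) {
    m <- ren$images[[k]] > 0
    a <- tr$images[[k]][m]; b <- ren$images[[k]][m]
    ma <- mean(a); mb <- mean(b)
    sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  }, numeric(1))
  expect_equal(sc2$per_view, oracle, tolerance = 1e-12)
  expect_equal(sc2$score, min(oracle))
  expect_lt(sc2$score, 1)
})

test_that("bout filtering thresholds the per-bout minimum score", {
  expect_true(filter_bouts(list(rep(0.9, 20)))[1])
  scores <- c(rep(0.95, 100), 0.84)
  expect_false(filter_bouts(list(scores))[1])
  ## threshold sweep monotonicity on a synthetic 20-bout set
  set.seed(52)
  bouts <- lapply(1:20, function(i) runif(30, 0.5, 1))
  ths <- seq(0.5, 1, by = 0.05)
  n_acc <- vapply(ths, function(th) sum(filter_bouts(bouts, th)),
                  numeric(1))
  expect_true(all(diff(n_acc) <= 0))
  ## missing scores are excluded with a warning, not treated as failures
  expect_warning(ok <- filter_bouts(list(c(0.9, NA, 0.92))), "missing")
  expect_true(ok[1])
  expect_equal(eval(formals(filter_bouts)$threshold), 0.85)
})
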