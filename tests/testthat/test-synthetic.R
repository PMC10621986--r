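test_that("curvature summaries average absolute bending angles", {
  expect_equal(unname(curvature_summary(fish_pose())), c(0, 0))
  alt <- fish_pose(dtheta = rep(c(0.1, -0.1), 4))
  expect_equal(unname(curvature_summary(alt)), c(0.1, 0))
  cbend <- fish_pose(dtheta = rep(0.3, 8))
  expect_equal(unname(curvature_summary(cbend)), c(0.3, 0))
})

test_that("bandwidth selection uses the configured grid and handles degeneracy", {
  ## default candidate grid: 50 values spanning [0.01, 0.1]
  f <- formals(select_bandwidth)
  cand <- eval(f$candidates)
  expect_length(cand, 50L)
  expect_equal(range(cand), c(0.01, 0.1))
  set.seed(1)
  dup <- matrix(0.2, 50, 2)
  expect_warning(bw <- select_bandwidth(dup), "degenerate")
  expect_equal(bw, 0.01)
})

test_that("cross-validated bandwidth is near the quadrature optimum", {
  set.seed(7)
  sigma <- 0.04
  x <- matrix(rnorm(500, 0, sigma), ncol = 1)
  bw <- select_bandwidth(x)
  ## oracle: expected log-likelihood of a KDE under the true density, by
  ## numeric integration over a fine grid
  grid <- seq(-4 * sigma, 4 * sigma, length.out = 2001)
  w <- dnorm(grid, 0, sigma)
  expected_ll <- vapply(seq(0.005, 0.12, by = 0.0025), function(h) {
    kde <- gaussian_kde(x, h)
    sum(w * kde_log_density(kde, matrix(grid, ncol = 1))) / sum(w)
  }, numeric(1))
  h_star <- seq(0.005, 0.12, by = 0.0025)[which.max(expected_ll)]
  expect_gt(bw, h_star / 2)
  expect_lt(bw, h_star * 2)
})

test_that("inverse-density resampling flattens the curvature distribution", {
  set.seed(11)
  ens <- pose_prior_ensemble(1200)
  cv <- larvapose:::curvature_matrix(ens)
  ru <- resample_uniform(ens, n = 500, bandwidth = 0.02)
  cv_out <- larvapose:::curvature_matrix(ru$poses)
  chi2 <- function(m) {
    bx <- seq(0, max(cv[, 1]) + 1e-9, length.out = 11)
    by <- seq(0, max(cv[, 2]) + 1e-9, length.out = 11)
    h <- table(cut(m[, 1], bx), cut(m[, 2], by))
    e <- mean(h)
    sum((h - e)^2 / max(e, 1e-9))
  }
  expect_lt(chi2(cv_out), chi2(cv[sample(nrow(cv), 500), ]))

  ## an already-uniform ensemble gets near-equal weights away from the
  ## support boundary (within the kernel's edge-bias zone weights rise)
  set.seed(12)
  flat <- lapply(1:800, function(i)
    fish_pose(dtheta = (2 * rbinom(8, 1, 0.5) - 1) * runif(1, 0.05, 0.85),
              dphi = (2 * rbinom(8, 1, 0.5) - 1) * runif(1, 0.02, 0.45)))
  rf <- resample_uniform(flat, n = 100, bandwidth = 0.1)
  cvf <- larvapose:::curvature_matrix(flat)
  interior <- cvf[, 1] > 0.25 & cvf[, 1] < 0.65 &
    cvf[, 2] > 0.22 & cvf[, 2] < 0.25
  core <- range(rf$weights[interior])
  expect_lt(core[2] / core[1], 1.4)
})

test_that("two-cluster ensembles rebalance toward 50/50", {
  set.seed(13)
  straight <- lapply(1:900, function(i)
    fish_pose(dtheta = rnorm(8, 0, 0.02), dphi = rnorm(8, 0, 0.01)))
  bent <- lapply(1:100, function(i)
    fish_pose(dtheta = 0.5 + rnorm(8, 0, 0.02), dphi = rnorm(8, 0, 0.01)))
  ru <- resample_uniform(c(straight, bent), n = 200, bandwidth = 0.05)
  frac_bent <- mean(vapply(ru$poses, function(p) mean(p$dtheta) > 0.25,
                           logical(1)))
  ## binomial 3-sigma band around 0.5 at n = 200
  expect_lt(abs(frac_bent - 0.5), 3 * sqrt(0.25 / 200) + 0.05)
})

test_that("sampled ensembles have uniform yaw and stay inside the volume", {
  set.seed(14)
  ens <- pose_prior_ensemble(300)
  kde <- fit_angle_kde(ens, bandwidth = 0.05)
  expect_equal(kde$d, 18L)
  poses <- sample_pose_ensemble(kde, 10000)
  th <- vapply(poses, `[[`, numeric(1), "theta0")
  ks <- suppressWarnings(ks.test(th, "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
  pos <- t(vapply(poses, function(p) c(p$x0, p$y0, p$z0), numeric(3)))
  expect_true(all(abs(pos) <= 15))
})

test_that("the zero-bandwidth limit reproduces training vectors", {
  set.seed(15)
  ens <- pose_prior_ensemble(50)
  am <- angle_matrix(ens)
  kde <- gaussian_kde(am, bandwidth = 1e-12)
  draws <- kde_sample(kde, 200)
  d2 <- as.matrix(dist(rbind(draws, am)))[1:200, 201:250]
  expect_lt(max(apply(d2, 1, min)), 1e-9)
})

test_that("noise-free zero-displacement examples equal the plain render", {
  proj <- fixture_proj()
  pose <- fixture_pose()
  set.seed(16)
  ex <- generate_training_example(pose, proj = proj, noise = NULL,
                                  max_displace = 0L, jitter_frac = 0)
  tr <- render_views(pose, proj = proj, mode = "accurate")
  expect_identical(ex$images, tr$images)
  expect_equal(ex$annotation, tr$keypoints, tolerance = 1e-9)
  expect_equal(ex$displacement, matrix(0L, 3, 2))
})

test_that("background noise follows the hierarchical product model", {
  set.seed(17)
  nm <- noise_model()
  par_b <- sample_noise_params(nm, "bottom", 10000)
  ## E[m] = E[X] E[Y] = (1/510) * 50; check within 3 standard errors
  expect_lt(abs(mean(par_b$mean) - 50 / 510),
            3 * sd(par_b$mean) / sqrt(10000))
  expect_true(all(par_b$sd >= sqrt(20) / 255 & par_b$sd <= sqrt(70) / 255))
  par_s <- sample_noise_params(nm, "side", 10000)
  expect_lt(abs(mean(par_s$mean) - 20 / 510),
            3 * sd(par_s$mean) / sqrt(10000))
  expect_error(noise_model(bottom = list(x_mu_range = c(-1, 0),
                                         y_mu_mean = 1, y_mu_sd = 1,
                                         var_range = c(0, 1))),
               "non-negative")
})

test_that("displacements are bounded and annotations stay in frame", {
  proj <- fixture_proj()
  tab <- fixture_table()
  set.seed(18)
  for (rep in 1:5) {
    pose <- random_pose(bend = 0.25)
    ex <- generate_training_example(pose, proj = proj, table = tab,
                                    mode = "fast")
    expect_true(all(abs(ex$displacement) <= 20))
    for (k in 1:3)
      expect_true(all(ex$annotation[[k]] >= 0 & ex$annotation[[k]] <= 140))
  }
})

test_that("annotations reproject onto the generating 3-D keypoints", {
  proj <- fixture_proj()
  tab <- fixture_table()
  set.seed(19)
  pose <- random_pose(bend = 0.25)
  ex <- generate_training_example(pose, proj = proj, table = tab,
                                  mode = "fast", jitter_frac = 0)
  co <- pose_to_coordinates(pose)
  kp3d <- rbind(co$backbone, co$eyes)
  for (j in 1:12) {
    px <- lapply(1:3, function(k)
      ex$annotation[[k]][j, ] + as.numeric(ex$origins[[k]]))
    tr <- triangulate_point(proj, px)
    expect_lt(sqrt(sum((tr$point - kp3d[j, ])^2)), 1e-3)
  }
})

test_that("randomized generation is reproducible under a fixed seed", {
  proj <- fixture_proj()
  tab <- fixture_table()
  pose <- fixture_pose()
  run <- function() {
    set.seed(20)
    generate_training_example(pose, proj = proj, table = tab, mode = "fast")
  }
  a <- run(); b <- run()
  expect_identical(a$images, b$images)
  expect_identical(a$annotation, b$annotation)
  run_kde <- function() {
    set.seed(21)
    kde <- fit_angle_kde(pose_prior_ensemble(60), bandwidth = 0.05)
    kde_sample(kde, 10)
  }
  expect_identical(run_kde(), run_kde())
})

test_that("synthetic bouts are smooth with bounded centroid speed", {
  set.seed(22)
  kde <- fit_angle_kde(pose_prior_ensemble(100), bandwidth = 0.05)
  bout <- generate_synthetic_bout(kde, 60, smoothness = 5, fps = 500,
                                  max_speed = 150)
  expect_s3_class(bout, "swim_bout")
  pos <- t(vapply(bout$poses, function(p) c(p$x0, p$y0, p$z0), numeric(3)))
  steps <- sqrt(rowSums(diff(pos)^2))
  expect_true(all(steps <= 150 / 500 + 1e-9))
  ## infinite smoothness freezes the pose
  const <- generate_synthetic_bout(kde, 10, smoothness = Inf)
  v <- vapply(const$poses, function(p) pose_to_vector(p)[5], numeric(1))
  expect_equal(diff(range(v)), 0)
  expect_error(generate_synthetic_bout(kde, 1), "n_frames")
})

test_that("training datasets round-trip through the PNG/JSON format", {
  proj <- fixture_proj()
  tab <- fixture_table()
  set.seed(23)
  exs <- lapply(1:2, function(i)
    generate_training_example(random_pose(0.2), proj = proj, table = tab,
                              mode = "fast"))
  dir <- tempfile()
  manifest <- write_training_dataset(exs, dir)
  m <- read.csv(manifest)
  expect_equal(nrow(m), 6L)
  img <- png::readPNG(file.path(dir, m$image[1]))
  expect_equal(dim(img), c(141L, 141L))
  ## PNG stores the transposed image at 8-bit precision
  expect_equal(t(img * 255), exs[[1]]$images[[1]], tolerance = 0.51)
  ann <- jsonlite::read_json(file.path(dir, m$annotation[1]),
                             simplifyVector = TRUE)
  expect_equal(ann$pose, pose_to_vector(exs[[1]]$pose), tolerance = 1e-9)
})
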