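## Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fixture_optics <- function() memo("optics", tank_optics)

fixture_cams <- function() memo("cams", function() {
  make_tank_cameras(fixture_optics())
})

## simulated dot-grid calibration and the fitted projection functions
fixture_grid <- function() memo("grid", function() {
  simulate_dot_grid(fixture_optics(), fixture_cams())
})

fixture_proj <- function() memo("proj", function() {
  g <- fixture_grid()
  fit_refractive_projection(g$dots, g$pixels_water)
})

fixture_table <- function() memo("table", build_lookup_table_p)

## a moderately bent reference pose inside the imaging volume
fixture_pose <- function() {
  fish_pose(x0 = 1.5, y0 = -2, z0 = 0.8, theta0 = 0.8, phi0 = -0.15,
            gamma0 = 0.1, dtheta = c(0.2, 0.25, 0.3, 0.3, 0.25, 0.2,
                                     0.15, 0.1),
            dphi = rep(0.05, 8), length = 4.0)
}

random_pose <- function(bend = 0.3) {
  fish_pose(x0 = runif(1, -8, 8), y0 = runif(1, -8, 8),
            z0 = runif(1, -8, 8), theta0 = runif(1, -pi, pi),
            phi0 = runif(1, -0.4, 0.4), gamma0 = runif(1, -1.2, 1.2),
            dtheta = runif(8, -bend, bend), dphi = runif(8, -bend / 2,
                                                         bend / 2),
            length = runif(1, 3.6, 4.4))
}

backbone_error <- function(pose_a, pose_b) {
  a <- pose_to_coordinates(pose_a)$backbone
  b <- pose_to_coordinates(pose_b)$backbone
  mean(sqrt(rowSums((a - b)^2)))
}

## noise-free sensor-pixel keypoints of a pose in every view
pose_keypoints <- function(pose, proj = fixture_proj()) {
  co <- pose_to_coordinates(pose)
  kp3d <- rbind(co$backbone, co$eyes)
  lapply(1:3, function(k) project_to_view_test(proj, k, kp3d))
}

## projection helper mirroring the package-internal view projection
project_to_view_test <- function(proj, k, pts) {
  project_refractive(proj, pts, cameras = k, check_domain = FALSE)[[1]]
}
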