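---
title: "Physical-model 3-D pose estimation for larval zebrafish: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physical-model 3-D pose estimation for larval zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(larvapose)
```

`larvapose` reconstructs the three-dimensional posture of larval zebrafish
from synchronized orthogonal camera views of a water-filled glass tank. The
pipeline couples an explicit physical model of the larva's body to
refraction-corrected camera geometry: the model is used both to fit poses
directly to images (template optimization) and to render arbitrarily many
annotated synthetic images on which a keypoint-regression network is
trained. This vignette explains the underlying models, the parameters that
matter, and the choices made where the design was genuinely open. It states
no empirical result beyond what the package's own test-suite and acceptance
script compute.

## The pose model

A pose is a 22-parameter vector plus the body length `L`. Six rigid-body
parameters place the head in the lab frame: position `(x0, y0, z0)` in mm
and the yaw, inclination and roll Euler angles `(theta0, phi0, gamma0)`,
applied in Z-Y-X order. The backbone is a chain of 9 rigid segments of
length `L/9`; each of the 8 joints bends by a lateral angle `dtheta_i`
(about the moving fish dorsal axis) and a dorso-ventral angle `dphi_i`
(toward the dorsal axis), both measured in the moving fish frame. The
equivalent coordinate representation is 10 equally spaced backbone points
plus the two eye centroids; `pose_to_coordinates()` and
`coordinates_to_pose()` convert exactly in both directions for equidistant
points, with the roll recovered from the eye axis under a never-belly-up
convention (`gamma0` folded into `(-pi/2, pi/2]`). Because the two chained
maps are exact inverses, every test of the reconstruction chain can compare
recovered angles directly against generating angles.

The lab frame has its origin at the tank centre with axes along the three
camera principal axes, right-handed, in mm. Pixels are 0-based with centres
on integer coordinates, x right and y down.

## Camera geometry and refraction

Without the tank, each camera is an ideal pinhole with intrinsics
`(fx, fy, u0, v0, skew)` and extrinsics `(R, t)`; the 4 x 3 row-vector
camera matrix factorizes as extrinsic times intrinsic
(`camera_matrix()`). With the tank in place, rays refract at the flat
water-glass and glass-air interfaces, so the true projection is no longer
linear. Rather than modelling the refraction analytically in the fitting
path, the package follows the empirical route: project a dot grid (here,
simulated by `simulate_refraction()`, an exact Snell's-law ray tracer that
serves as the physical oracle), then fit, per camera and per pixel axis, a
bivariate cubic polynomial in the one transverse lab coordinate that axis
responds to and the coordinate along the camera axis. This separability is
exact for flat interfaces perpendicular to orthogonal camera axes and is
verified by a dedicated test. The full 10-monomial cubic basis is used per
axis, on centred and scaled coordinates, solved by QR.

Numerical choices: triangulation (`triangulate_point()`) is a
Levenberg-damped Gauss-Newton on the stacked 6-residual system with
analytic polynomial Jacobians, started from the tank centre; the
calibration simulator places the grid at compound tilts (about both lab
axes) because single-axis tilts leave the cubic design rank-deficient --
the fit detects and names such degenerate layouts. Ray lookup tables
(`build_ray_table()`) invert the separable fit with two 1-D root solves
per probe depth; by default the three probe points sit at fixed depths
spanning the central 90 percent of the calibrated depth range
(deterministic), with a seeded random-depth mode retained. Cross-view
matching uses the closed-form skew-line distance with a point-to-line
fallback for parallel rays, a greedy ascending-delta assignment, and a
heuristic threshold of 1 mm.

The simulator's optical constants are chosen once as physically realistic
for this kind of rig: a 70 mm inner tank, 2.5 mm glass walls,
`n_water = 1.33`, `n_glass = 1.52`, cameras 250 mm from the tank centre
with a 35 mm lens on 7.4 um pixels (648 x 488 sensor). Only
self-consistency is ever tested against these values.

## Rendering the larva

The anterior (two eyes, head, belly) is a voxel intensity field: the
pointwise maximum of four anisotropic Gaussians whose axes follow the fish
frame. Dimensions are full extents; the Gaussian sigma of each organ axis
is extent/4 so the 2-sigma ellipsoid matches the stated size. The default
body constants (eye separation 0.4 mm, organ extents of a few tenths of a
mm, brightness eye:head:belly = 255:180:200) are plausible placeholders for
a 4 mm larva, scaled linearly with `L`; they are not published values, they
are overridable, and the tests depend only on self-consistency. In
accurate mode every voxel is projected through the calibrated projection
function and pixel intensities are the sums of voxel intensities; the
default voxel pitch of 15 um resolves the eyes with several voxels per
axis, and a convergence test checks that halving the pitch halves the
image change. The tail is drawn in image space as 8 capsule segments along
the projected backbone: a transverse Gaussian profile of width
`tail_width_scale * L / 40`, a linear longitudinal intensity falling from
1.0 at the start of the tail to 0.3 at the tip, and a width taper to 0.6 of
the base width (the trapezoid-plus-end-disk silhouette). Anterior and tail
combine by pixelwise maximum and each view is rescaled so its brightest
pixel is 255.

The fast renderer replaces both parts with precomputed sprites (the sprite
lookup table, `build_lookup_table_p()`): tail-segment entries are indexed
by segment number, projected orientation in 5 degree bins, projected
length in 0.25 px bins, and the subpixel offset of the segment start in
0.2 px bins; anterior entries are orthographic projections of the voxel
cloud along the camera axis, indexed by the three head Euler angles in 5
degree bins and a 2 percent magnification grid. Entries are generated
lazily and memoised -- an optimization run touches only a narrow band of
orientations, so only that part of the table is ever built -- and sprites
are trimmed to their non-negligible support to keep pasting cheap.

## Template-based pose optimization

The cost of a candidate pose is the sum over camera views of squared pixel
differences between the preprocessed observation crop and the rendered
model projection. Optimization is derivative-free pattern search in the
Hooke-Jeeves style: coordinate-wise opportunistic polling with mesh
doubling on success and halving on failure, exploratory pattern moves
that extrapolate the net displacement of a successful sweep (so diagonal
valleys are followed at full speed), per-parameter scales of 0.5 mm
(positions) and 0.1-0.2 rad (angles), and convergence when the mesh falls
below a small tolerance. The joint fine phase additionally polls three
coupled directions -- yaw-against-lateral-bend, inclination-against-dorsal-
bend, and a slide along the heading -- because those are the sloppy modes
of a chain anchored at the head, which isolated coordinate steps cannot
descend. Any conforming derivative-free optimizer could be substituted
behind this interface. The first frame of a bout is seeded by
triangulating the view centroids and brute-forcing the straight-backbone
head orientation (yaw every 10 degrees, inclination every 10 degrees in
[-60, 60], roll every 15 degrees); later frames start from the previous
frame's fit. Coarse optimization polls all 22 parameters against the fast
sprite renderer; fine optimization then refines with the voxel-projected
anterior in three phases -- rigid-body parameters only, bending angles
only, then all 22 jointly -- and falls back (flagged) if it cannot improve
the accurate-render cost of its initialization. A closed-form translation
polish ends the fine round: per view, the difference between observed and
rendered intensity centroids constrains the two transverse lab
coordinates, and the stacked six-equation system is solved for the 3-D
shift (accepted only when it lowers the cost). This removes the one slow
failure mode of coordinate polling on a near-straight fish, a small
uniform offset along the body axis.

Two implementation details matter for correctness. First, the cost
restricts each view to a region of interest around the observed fish
(pixels above 15 percent of the image maximum, padded), which both speeds
the evaluation and keeps background noise from dominating the bounding
box. Second, the tail magnification is evaluated at the model fish's
position exactly as the renderer does, so the exported `cost_function()`
digitizes its render to 8-bit and returns exactly zero for a self-rendered
pose; the optimizers use the same surface without the final rounding to
avoid quantization plateaus.

Body length is estimated from straight-pose frames: a 4.5 mm straight
model is oriented by a small pattern search, and the segmented extent of
the largest connected component in each view, divided by the projected
foreshortening of the fitted body axis, gives a per-view length; views
with strong foreshortening are discarded and the rest averaged over frames.

## Pose ensembles and synthetic training data

Real swim recordings are heavily biased toward straight poses. The package
reproduces the two-stage ensemble machinery on top of any source ensemble
(a generative prior, `pose_prior_ensemble()`, stands in for unpublished
recorded poses): first, a 2-D Gaussian KDE over the mean absolute lateral
and dorso-ventral bending summaries assigns every pose a selection weight
inversely proportional to its density, and a subset (2500 by default) is
drawn to flatten the curvature distribution; second, an 18-dimensional
isotropic Gaussian KDE over `(dtheta_1..8, dphi_1..8, phi0, gamma0)` is
fitted to the flattened subset and sampled to any size, with positions
uniform in the central 3 x 3 x 3 cm imaging volume and yaw uniform on
(-pi, pi]. Bandwidths are selected by repeated 1:9 random-split
cross-validation over 50 candidates spanning [0.01, 0.1] rad (20 splits),
maximizing held-out log-likelihood; a single scalar bandwidth is shared
across all dimensions, matching the single-bandwidth grid search the
procedure is modelled on. Density weights are clipped from below at the
0.1 percent quantile before inversion to stop isolated tail points from
absorbing all the sampling mass.

Training examples are rendered triplets with three randomizations: the
fixed body parameters jittered uniformly by +/-5 percent, the larva
displaced by 0-20 whole pixels per axis inside the 141 x 141 crop (with
the 2-D annotation displaced identically), and background noise drawn
from the hierarchical model -- per image, a Gaussian whose mean is the
product of `X_mu ~ U(0, 1/255)` and `Y_mu ~ N(50, 10)` for bottom views
(`N(20, 10)` for side views) and whose variance is uniform on
[20, 70]/255^2 (bottom) or [10, 60]/255^2 (side), applied on the unit
scale before rescaling to unsigned 8-bit. What this generator does *not*
emulate: optical blur and depth-of-field, the brightness dependence on
body orientation of a semi-transparent animal, water-surface reflections,
and multiple larvae per crop. Tests passing on these images therefore
demonstrate the correctness of the pipeline's geometry, losses and
optimization, not performance on any particular recording rig.

`generate_synthetic_bout()` produces temporally correlated pose sequences
(spline-interpolated KDE control points, a speed-capped smooth centroid
path) purely as a fixture for tracking and kinematics tests; real bouts
are not statistically emulated.

## The keypoint network

The regressor follows a compact bottleneck-residual design: four
pre-activation bottleneck blocks of 32, 64, 128 and 256 output channels
(internal width one quarter of that), each reducing the spatial grid by
stride 2 through its 3 x 3 convolution (141 to 71, 36, 18, 9), global
average pooling, and three fully connected layers of 288, 144 and 72
units. Batch normalization precedes every convolutional and fully
connected layer and leaky rectifiers (slope 0.01) follow them; the final
72-vector passes through a sigmoid scaled to [0, 141] and reshapes to
three 2 x 12 keypoint matrices. The stated block and layer widths fix the
architecture, but a 3 x 3 stride-1 path cannot reduce a 141 x 141 image
to a 288-dimensional code, so the stride-2 downsampling path and the
pooled (rather than flattened) encoder output are this package's recorded
decisions; both are isolated behind `pose_net_spec()`.

The loss is the backbone RMSE over all 60 backbone coordinates plus
`lambda = 5` times the eye loss, which per camera takes the smaller RMSE
of the two eye labelings and sums over cameras -- the only reading under
which the loss is exactly symmetric in the eye indices, and the symmetry
is asserted as an identity in the tests. Training uses Adam (learning
rate 0.001), a 9:1 train/validation split, and seeded shuffling; the
full-scale recipe (batch 300, 120 epochs, 500k images) is supported by
configuration, while the shipped desk-scale profile uses a few thousand
examples, around ten epochs, batch around 100, and mean-pool downscaling
of the 141 px inputs (keypoints always stay on the 141 px scale). All
layers, the backward pass and the optimizer are implemented natively in
R with vectorized array arithmetic; gradients are verified against
numerical differentiation in the unit tests.

## Reconstruction and scoring

Each of the 10 predicted backbone points is triangulated independently
(tank-centre start); the eyes are triangulated under all 8 combinations of
per-view eye indices and the assignment with the least total residual is
accepted, ties breaking deterministically to the lowest lexicographic
assignment with a flag. A chord-parameterized cubic spline through the
backbone is resampled to 10 points equally spaced in arc length (dense
arc-length table of 4001 samples, endpoints preserved), and the
coordinate set converts back to the 22 parameters with the roll taken from
the eye axis. Equal-arc points on a bent spline have slightly unequal
chords (about a percent at strong bends), which is why the inverse map's
equidistance check warns only beyond 2 percent.

The prediction score renders the candidate pose into the observed crop
windows and computes, per view, Pearson's correlation over the mask of
non-zero rendered pixels (the rendered background is exactly zero); the
frame score is the minimum over views, so 1 is a perfect prediction.
Frames whose mask is empty propagate a missing score and are excluded
from bout minima with a warning. For model-vs-model comparisons, where
both images carry a mask, the union of the masks is used. Bouts are
accepted when no frame scores below 0.85.

## Kinematics and statistics

Bout summaries unwrap each angle series, measure changes relative to the
first frame, and report the signed extremum of the deviation as the
"maximum change" (a max-minus-min range convention is available by flag)
plus the final-minus-initial total change and the vertical displacement
range. Quartiles use the linear-interpolation definition (R type 7). The
difference-of-means test pools both samples, redraws two resamples of the
original sizes 10000 times, and reports the one-sided tail probability of
the observed difference (larger mean first, by convention); the same
machinery applies to quartile differences through its `statistic`
argument. Binomial asymmetry tests are exact upper tails at null
probabilities 0.5 (sign symmetry) or 0.25 (quadrant predominance).
Bending eigenshapes are the right singular vectors of the mean-centred
frames x 16 bending-angle matrix, ordered by singular value, with
variance fractions and a lateral/dorsal label from the energy split
between the two angle blocks.

## Problem sizes used by the shipped tests

The test-suite and acceptance script run everything at desk scale, chosen
as the package's own evaluation conditions: calibration uses a 15 x 15
dot grid at 5 mm pitch in three compound-tilt placements; loop closure
checks 100 KDE-sampled poses; template-fit recovery runs 50 noisy frames
with a coarse budget of 1000 evaluations and fine budgets of 200/300/700
per phase at a 60 um working pitch plus a 100-evaluation rigid polish at
the 30 um render pitch; the training smoke test renders 2000 examples
and trains 10 epochs at batch 100 on 28 px downscaled inputs; the
statistical null check simulates 1000 tests of 2000 resamples each. The template-recovery protocol renders its
observations with the background-noise model and random displacement but
with the fitter's own fixed body parameters: the +/-5 percent parameter
jitter belongs to training-set diversification, whereas recovery is
evaluated in the regime where the fixed parameters have already been
estimated, as they are before fitting real bouts.

## Known limitations

The fixed body parameters are plausible defaults, not measured values;
absolute image realism is out of scope. Pectoral fins, eye orientation,
and multi-animal composites are not modelled. The renderer's fast mode
inherits the sprite discretization (5 degrees, 0.2 px), which is why the
coarse round is always followed by a fine round before angles are
reported. Temporal smoothing across frames is deliberately absent: every
frame is estimated independently, and bout-level continuity enters only
through initialization. Training at the full published scale (500k
images, 120 epochs) is supported by configuration but takes far longer
than the desk-scale profile and is not exercised by the tests.
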