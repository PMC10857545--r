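---
title: "Measuring dairy cow conformation from 3D point clouds: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dairy cow conformation from 3D point clouds: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cowmorph)
```

# The measurement problem

Linear conformation scoring grades dairy cows on fixed anatomical traits.
`cowmorph` implements four of them from a 3D point cloud of a standing
animal:

* **stature height** — the vertical distance from the highest point of the
  back to the ground plane;
* **rump angle** — recorded here, as in conformation practice, as the
  *signed height difference in centimeters* between the hook (hip) bone and
  the pin bone, positive when the hook sits higher;
* **rump width** — the transverse distance between the inner ischium points
  `C1`, `C2` on the cross-section of the rump cut through the two hook
  bones;
* **front teat length** — the top-to-bottom distance of each front teat,
  left and right averaged.

Each measured value is mapped to an integer score 1–9 against a fixed
column of nine reference values (stature 128–152 cm in 3 cm steps,
hook-pin offset −4 to +12 cm in 2 cm steps, rump width 5–17 cm in 1.5 cm
steps, teat length 2–10 cm in 1 cm steps).

The chain assumes a single standing animal, captured between two dominant
planar structures (ground below, a fence to one side), in metric units.
All internal computation is in meters; centimeters appear only in reports.

## The scoring rule

Published materials pair values with scores (142.0 cm → 6, 6.06 cm → 6,
11.7 cm → 5, 4.16 cm → 3) without stating the interpolation rule. The
nearest-reference-row rule — with values beyond the extremes clamped to
scores 1 and 9, and exact midpoints rounded to the higher score — is the
unique simple rule consistent with all four pairs, so `score_measurement()`
implements it. The rump-angle column is encoded as signed hook-above-pin
offsets (score *s* at offset *2s − 6* cm), which makes "hips level" score 3
and reproduces the 6.06 → 6 pairing. The suite checks that every scoring
map is a non-decreasing step function with clamped tails.

# Scene preprocessing

`fit_plane_ransac()` draws 3-point plane hypotheses, counts points within
`dist_thresh` of each, and keeps the winner. Defaults: voxel edge 10 mm,
inlier threshold 15 mm, 1000 iterations, seeded RNG — sized for depth
cameras whose range error is roughly 1 cm at the 1–2 m working distances
of a livestock rig.

Two numerical choices deserve a note:

* **Trimmed refit.** The winning plane is refit to its inliers by total
  least squares, but points that merely *graze* the plane — the bottom few
  centimeters of a leg standing on the ground — sit inside any sensible
  threshold while lying off the plane, and a single refit would average
  them in. The refit therefore iterates, shrinking the selection radius to
  three times the current inlier RMS (never above `dist_thresh`). On
  noiseless data this converges to the exact plane; under Gaussian noise it
  behaves like the plain refit.
* **Plane ordering.** The ground is by convention the *larger* of the two
  extracted planes. Because RANSAC finds planes in a random order, the
  extraction stage re-counts both candidates on the full cloud and swaps
  them if needed, and both stages run at least 3000 iterations — the count
  that the coverage bound `log(0.001) / log(1 − f³)` requires at the fence's
  ~0.13 share of the remaining points.

Fence trimming removes the half-space on the far side of the fence plane,
the side not containing the centroid of the ground-cleared cloud; whether
points beyond the fence should ever be kept is not observable from a single
standing pose, so the half-space rule is a deliberate reconstruction.

Statistical outlier removal drops points whose mean distance to their `k`
nearest neighbours (default `k = 20` for stand-alone use, 12 inside the
pipeline where clouds are already trimmed) exceeds the global mean by
`std_ratio = 2` standard deviations — the standard parameter-light choice.

`normalize_coordinates()` maps the ground normal to `+z`, the ground to
`z = 0`, and the first principal component of the xy-projected body to
`+x`. The 180° heading ambiguity is resolved by point count in the outer
quarters of the body axis: the head end carries more surface, hence more
points; exact ties keep the current heading. Degenerate (isotropic) clouds
fall back to the eigenvector returned by the symmetric eigensolver, which
is deterministic.

# Registration

`evaluate_registration()` reports **fitness** (the fraction of source
points with a target neighbour within `max_corr_dist`) and **inlier RMSE**
(root-mean-square distance over those correspondences). The evaluation
default `max_corr_dist = 30` mm is the package's own choice; published
fitness values depend on an unstated threshold, so only the *direction* of
improvement from the fixed two-camera initialization is meaningful, and
that is what the tests assert. Nearest-neighbour search is exact brute
force in C++; any future accelerated index must match it. ICP alternates
nearest-neighbour assignment with the closed-form SVD (Kabsch) update and
stops when the correspondence RMSE improves by less than `tol`.

# The synthetic scene generator

`generate_scene()` builds a cow-shaped scene from analytic primitives:
ellipsoid torso, sphere head, four cylinder legs, two cylinder front teats
with end caps, a rectangle of ground samples, a vertical fence rectangle,
isotropic Gaussian sensor noise on all surface points, and uniform outliers
in the scene bounding box inflated by 20%. Surfaces are sampled
area-uniformly (rejection sampling on the ellipsoid), with minimum quotas
for the teats and landmark bosses, as a capture focused on the scored
regions would provide. The exact keypoints are appended as surface samples,
so annotations reference true cloud members.

Ground-truth keypoints are placed analytically: the highest back point is
the torso apex; the hooks, pins and ischium inner edges lie on the torso at
the heights and separation the template prescribes; teat tops are
attachment points and teat bottoms end-cap centers. Every ground-truth
measurement is therefore exactly recomputable from its keypoints, and a
noiseless, outlier-free scene measured with oracle keypoints round-trips
through the entire pipeline to within 10⁻⁴ cm — the suite asserts this.

**Landmark bosses.** On a live animal the hooks, pins and ischium edges
are palpable bony prominences. On a bare ellipsoid they would be labels on
a featureless surface: the cloud would carry *no geometric information*
about their heights, the detection task would be ill-posed, and no
detector — however trained — could beat the prior spread of those heights.
Each of those six landmarks therefore carries a small hemispherical boss
(2 cm hooks/pins, 1.5 cm ischium) centered on the landmark, which leaves
every ground-truth formula unchanged while making the landmarks
observable.

Default template values describe a Holstein-sized animal (body length
1.6 m, radius 0.35 m, stature 1.42 m, hook 6.06 cm above pin, rump width
11.7 cm, teats 4.06/4.26 cm, 5 mm noise, 2% outliers, 6000 points).
Training draws template fields independently and uniformly from ranges that
span the score tables (stature 1.28–1.52 m, rump width 5–17 cm, teat
length 2–10 cm, hook and pin heights covering offsets of roughly −3 to
+15 cm).

What the generator does **not** emulate: articulated pose variation, breed
and condition-dependent shape, non-planar fences, occlusion and
view-dependent sampling, or correlated (non-isotropic) sensor error.
Passing tests therefore demonstrate that the measurement chain is correct
and that the learning formulation recovers observable landmarks under
realistic noise — not that the shipped configuration reaches any particular
accuracy on live animals.

# Keypoint detection by distance-field regression

For a cloud `P` (n×3) and `m` ordered landmarks, the regression target is
the n×m matrix of Euclidean distances from every point to every landmark;
keypoints are recovered from a predicted field as per-column argmins, with
ties broken toward the lowest point index. `build_distance_field()` and
`extract_keypoints()` form an exact oracle pair, tested as such.

The network is a PointNet-style encoder–decoder: shared per-point dense
ReLU layers (64-64-128 by default), a global descriptor pooled from the top
encoder layer, concatenation of the descriptor back onto the per-point
local features, and a per-point decoder. Three architectural choices go
beyond the textbook layout, each with a specific numerical reason:

* **Max- and mean-pooling.** The scene's latent shape parameters are
  extents and moments; a max-pool alone encodes extents but represents
  moments poorly, so the global descriptor concatenates both pools.
* **Coordinate skip.** The decoder input includes the raw (aligned)
  coordinates. The distance to landmark *j* is `‖p − k_j‖` with `k_j` a
  function of the global descriptor only; giving the decoder `p` directly
  turns the hard part of that map into an additive interaction.
* **Norm output head.** An MSE-trained network with a plain linear head
  smooths the cone tip of the field, and the argmin wanders inside the
  blurred basin, so localization error equals the tip resolution. The
  default head instead decodes one 3-vector per landmark and predicts its
  Euclidean norm: the cone at the zero crossing is exactly sharp, while the
  training target (the true distance field) and the loss (plain MSE) are
  unchanged. The literal linear head and the sigmoid segmentation view
  remain configuration options.

Training follows the standard recipe — mean squared error, Adam, learning
rate 0.001, 100 epochs without early stopping — with a cosine anneal of the
step size as the package default, optional decoupled weight decay, and two
regularizers that matter at small scene counts: every gradient step sees a
fresh random subsample of `sample_points = 512` points per scene (annotated
members always kept, so the targets stay sharp), and
`mirror_prepared_scene()` reflects a prepared scene across the body midline
while swapping the left/right landmark labels, exactly doubling the scene
diversity of a bilaterally symmetric body plan. Distances are regressed in
meters without target normalization; clouds are centered in x/y per scene
(translation nuisance) while z stays anchored to the ground plane, where
absolute height is informative. At prediction time the global descriptor is
pooled over deterministic subsamples at the training density (averaged over
eight draws) while the decoder scores every point, so pooled statistics stay
calibrated on denser clouds and the argmin keeps full resolution.

All gradients — including both optional T-Net alignment sub-networks — are
hand-derived and verified against central finite differences in the test
suite. Gradients at exact ReLU kinks use the zero subgradient.

Problem sizes used by the suite: the held-out accuracy check trains on 50
scenes (plus mirrors) of about 4000 body points each, subsampled to 512
per step, for 150 epochs with a 256-128 decoder, and evaluates the median
localization error over 10 held-out scenes against a 2 cm bound; the
noise-sensitivity property uses 12+4 scenes at three noise levels with a
lighter configuration. These sizes were chosen as the smallest at which the
properties are stable.

# Measurement details

`measure_rump_width()` cuts the slab of points within `slab_half_width`
(default 15 mm, the package's own choice) of the vertical plane through the
hook landmarks A1 and B1. When the ischium keypoints are available they are
used directly after a slab-membership check (snapping to the nearest slab
point when outside); without them, the transverse extrema of the slab
within a height band around its lower quartile serve as a coarse fallback,
and its coarseness is the main reason the ischium landmarks are part of the
detector's label set. The auxiliary right-side landmarks B1/B2 exist to
define the cutting plane (B1) and for symmetry (B2); only A1 and A2 enter
the rump-angle formula.

`annotate_cloud()` overlays red keypoint markers and blue measurement
segments (sampled every 5 mm) on the input cloud without touching the
original points, and the report serializes to a JSON sidecar that
round-trips exactly.

# Known limitations

* The heading rule needs a visible head; a cloud cropped to the torso may
  normalize facing backwards (measurements are heading-invariant, but
  detector input frames would flip).
* The rump-width fallback overestimates on convex cross-sections; it is a
  fallback, not the method.
* The detector is trained and evaluated on the generator's shape family;
  transfer to live-animal scans would require retraining on annotated real
  clouds, which the fitting interface accepts unchanged.
* PLY support covers ASCII and binary-little-endian vertex data; meshes are
  read as their vertices, and binary files with non-leading vertex elements
  are rejected rather than guessed at.
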