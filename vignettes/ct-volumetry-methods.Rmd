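---
title: "Methods: simulated CT volumetry of sphere phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated CT volumetry of sphere phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Volumetric assessment of solid tumors by CT is limited less by segmentation
software than by the imaging physics of the voxel grid itself. A voxel that
straddles a lesion boundary reports an attenuation intermediate between
lesion and background (the partial-volume effect), so any fixed-threshold
segmentation systematically misplaces the boundary, and the bias grows as
the voxel becomes large relative to the object — most dramatically along
the slice direction, where clinical thicknesses of 2.5–5 mm are common.

`ctphantom` quantifies this bias under controlled conditions. It simulates
a gelatin phantom containing PMMA (acrylic) spheres of known diameter,
renders it onto CT voxel grids with exact partial-volume behaviour,
emulates reconstruction kernels and image noise, synthesizes thick slices
by averaging thin ones, segments the spheres with a calibrated global
threshold plus filtered 3D connected components, and reports accuracy
(percent error, origin-forced slope of measured vs true volume) and
precision (coefficient of variation, 95% confidence intervals) across the
full grid of slice thickness x field of view x kernel. Because the objects
are ideal spheres in a homogeneous background, the resulting error
estimates are an upper bound on what clinical volumetry can achieve.

## The phantom and what the generator does (and does not) emulate

The default phantom holds 55 spheres — eleven diameters with five-fold
replication — in a 15.2 x 15.2 x 40.0 cm container of gelatin. Material
attenuations default to 118.2 HU (PMMA) and 37.6 HU (gelatin). The
diameter series is the inch-fraction ladder 1/16, 1/8, 3/16, 1/4, 5/16,
3/8, 1/2, 5/8, 3/4, 7/8 and 1 in (1.5875–25.4 mm): precision acrylic
spheres are manufactured to inch fractions, and the reference true volumes
this package reproduces (16.8, 134, 8580 mm^3) are exact for 1/8, 1/4 and
1 in but not for their rounded millimetre labels.

Spheres are laid out in five horizontal layers, one sphere of every
diameter per layer, with a different random in-plane arrangement per layer
and a seeded random axial jitter of each layer. The jitter matters: it
places sphere centers at arbitrary phase relative to any slice grid, which
is a genuine source of replicate-to-replicate variability in slice-sampled
volume measurement. Placement is rejection-sampled with a pairwise
non-overlap guarantee (center distance greater than the sum of radii plus
a 2 mm margin) and fails loudly if the container cannot host the request.

What the generator does *not* emulate: manufacturing tolerance on sphere
diameters, scanner positioning error, gelatin inhomogeneity, beam
hardening, helical interpolation artifacts, or scatter. Replicate scatter
in the simulation therefore comes only from grid phase and image noise and
is narrower than what a physical experiment shows, especially for large
spheres at thin slices. Passing trend tests on synthetic data consequently
demonstrates the partial-volume and threshold logic, not the full
variance budget of a real scanner.

## Voxelization

`voxelize()` renders the analytic geometry onto a grid of square in-plane
pixels (size `FOV * 10 / matrix` mm) and a chosen slice thickness. Each
voxel's HU is the occupancy-weighted mean of sphere and background HU,
where occupancy is the fraction of the voxel inside a sphere. Voxels whose
center is farther than `r + half-diagonal` from a sphere center are exact
background; closer than `r - half-diagonal`, exact sphere; only the
boundary shell is integrated numerically, on a `supersample^3` subgrid of
the voxel (default 8 per axis, i.e. 512 samples). At native resolution
this keeps the occupancy error of the smallest analyzed sphere below one
percent, which the test suite verifies against the closed-form volume at
0.2 mm isotropic sampling. The output is noiseless, deterministic, and
bounded by the two material HUs.

Coordinates are defined once and used everywhere: voxel `(i, j, k)`
(0-based) spans a half-open box starting at `origin + (i, j, k) * size`;
sphere centers live in continuous mm. Volumes serialize to NIfTI or to raw
little-endian float32 with a JSON sidecar.

## Kernel models and noise

A reconstruction kernel is modelled by two numbers: an in-plane Gaussian
point-spread width `psf_sigma_xy` (mm) and an additive zero-mean Gaussian
noise level `noise_sigma` (HU), applied in that order by `apply_kernel()`
(blur, then noise; both seeded). Defaults:

| kernel   | psf_sigma_xy (mm) | noise_sigma (HU) |
|----------|-------------------|------------------|
| standard | 0.8               | 4                |
| lung     | 0.3               | 8                |
| bone     | 0.5               | 10               |

These are chosen to reproduce the qualitative clinical ordering — the lung
kernel sharpest and most accurate but with the noisiest error profile, the
standard kernel smoothest, bone the noisiest image — and are fully
configurable per run. The blur is implemented as a separable 1D Gaussian
convolution (banded-matrix products with replicated boundaries), truncated
at 3 sigma; the test suite checks it against the analytic Gaussian edge
response.

A known limitation of this model is that the noise is *white*: a real
reconstruction kernel correlates noise over the same scale as its PSF.
White noise interacts with the neighbor-count filter (below) to erode
segmented surfaces slightly — isolated noise-gained surface voxels are
pruned while noise-lost voxels stay lost — and because slice averaging
reduces noise by the square root of the averaging factor, the noisiest
kernel can measure marginally *better* at 1.25 mm than at 0.625 mm slices
(the effect is about 0.005 in slope for the bone defaults), where correlated
noise would not produce this inversion. The trend test suite exposes this
as a deliberate red flag rather than papering over it.

## Thick-slice synthesis

`average_slices()` converts a thin stack into thicker slices: every output
slice is the weighted mean of `slices_per_thick` consecutive thin slices,
with fractional boundary slices weighted by their fractional coverage
(linear interpolation), and output thickness equal to
`slices_per_thick x` input thickness. The main experiment uses the exact
integer factors 2, 4 and 8 over 0.625 mm native slices to produce 1.25,
2.5 and 5.0 mm images.

For validating slice averaging against an independently reconstructed
thick stack whose grid phase is unknown, `phase_shift_search()` evaluates
candidate phase skips (default 0–9 leading thin slices) and returns the
plan minimizing the mean absolute voxel difference; ties break toward the
smaller skip. Two numerical choices deserve note. First, the alignment
metric is the mean *absolute* difference — a signed mean would be near
zero for any phase and could not drive a minimization. Second, when a
phase skip is applied, the consumed leading slices are not emitted as a
partial first output slice: emitting it would make candidate stacks
non-congruent across phases and the partial slice has incomplete coverage;
only full averaging windows are returned, and the search compares the
leading slices the stacks share. On noiseless stacks the search recovers a
planted phase with a metric of exactly zero, which the tests assert for
all ten candidates, including the fractional factor 9.625.

## Segmentation

`segment_volume()` chains three steps with fixed, documented tie-breaks:

1. **Global threshold** — foreground where `HU >= threshold` (inclusive at
   the boundary; the choice is arbitrary but must be fixed for bit-exact
   tests). The shipped default is 93 HU.
2. **3D connected components** — maximal connected foreground sets under
   full 26-adjacency ("contiguous" in the everyday sense) labelled
   1..n in deterministic first-voxel (lexicographic) order. Adjacency is
   resolved by building the voxel edge list and taking graph components.
3. **Filtering** — (a) every voxel must have at least `min_neighbors = 3`
   face-adjacent foreground neighbors; removal is iterated to a fixed
   point because each removal can strand further voxels, and components
   are relabelled afterwards since pruning can split an object. (b)
   components smaller than `min_volume` (default ten percent of the true
   volume of the smallest analyzed sphere: 1.68 mm^3 for the 1/8 in
   sphere, recomputed automatically from the configured diameter list) are
   deleted and labels compacted.

The two adjacencies differ on purpose: labeling uses the permissive
26-neighborhood so an object is whatever hangs together at all, while the
per-voxel pruning rule uses the strict face neighborhood, which is what
lets it break one-voxel noise bridges between nearby objects. Both are
configurable. The filter is idempotent and never adds voxels; property
tests cover both invariants, and the labeling is checked against a
breadth-first flood-fill oracle on hundreds of random masks.

## Measurement and matching

Component volume is the voxel-counting estimate `V_CT = N_V x l x w x t` —
exact integer count times voxel volume, no surface fitting. Components are
matched to ground-truth spheres by a distance gate: a component belongs to
the nearest sphere center within that sphere's radius plus one voxel
diagonal (the gate must scale with resolution; blur displaces centroids by
far less than a voxel). Equidistant ties go to the lower sphere id; if
several components fall in one gate, the largest is kept and the others
are counted as fragments, since the volume filters are designed to yield
one object per sphere. Undetected spheres are flagged and excluded from
accuracy statistics — with their count reported — rather than imputed.

The smallest size class (1/16 in = 1.6 mm) is generated and measured but
excluded from the accuracy analysis by default; its segmentation at
clinical voxel sizes is unreliable and would mix detection failures into
accuracy statistics. That exclusion is why the default grid yields
`36 x 50 = 1800` analyzed measurement slots from 55 spheres per image set.

## Threshold calibration

The global threshold is not arbitrary: `sweep_thresholds()` segments a
calibration volume at several thresholds (default 90, 100, 110 HU),
averages percent error over replicates within each size class, and reduces
to the min / median / max across size classes. `optimal_threshold()` fits
an ordinary least-squares line to median error versus threshold and
returns its zero crossing; `global_threshold()` averages the per-case
optima across calibration cases (by design a smoothest, a noisiest and an
intermediate reconstruction) and rounds to integer HU. Degenerate sweep
points — a threshold below background that merges the phantom into one
giant component, or a threshold above the sphere HU that detects nothing —
are flagged and excluded from the fit rather than erroring. On a noiseless
synthetic case the recovered optimum falls strictly between the two
material HUs (near the 77.9 HU midpoint, since blur is symmetric), and
re-applying it yields a median error closer to zero than either sweep
endpoint; both properties are asserted in the tests.

## Statistics

All statistics operate on the tidy measurement table and are grouped by
whatever condition columns are present:

* **Percent error** `(V_CT - V_true) / V_true x 100`, detected only.
* **Precision** — sample (n-1) standard deviation everywhere (five
  replicates are a sample), COV = sd/mean x 100, and Student-t 95%
  confidence intervals (t rather than normal because n = 5).
* **Accuracy slope** — least squares forced through the origin,
  `slope = sum(xy) / sum(x^2)`, with the uncentered R^2 appropriate to a
  through-origin fit. The slope is dominated by the largest spheres and
  reads directly as the measured/true volume ratio.
* **ANOVA** — classical one-way analysis of variance on percent error,
  fitted one factor at a time (sphere size, slice thickness, FOV, kernel),
  with pairwise pooled-t comparisons Bonferroni-corrected by
  multiplication and capping at 1.
* **Minimum measurable diameter** — for each condition, the expected
  |percent error| curve (mean over replicates per diameter) is linearly
  interpolated to find the smallest diameter beyond which the error stays
  within a tolerance (10% and 20% by default). Sentinels mark conditions
  where even the largest tested diameter fails ("> max tested") or the
  smallest already passes ("< min tested"); an undetected size class
  counts as failing every tolerance, and no interpolation is attempted
  from an infinite-error point.

## Problem sizes and reproducibility

The shipped default configuration is the full reference design: 512
matrix, three FOVs (20/30/40 cm), three kernels, four thicknesses, 640
native slices. The packaged trend checks and the acceptance script run the
same 36-condition grid at a 256 matrix — halving in-plane sampling — which
completes in a few minutes on one CPU while preserving every qualitative
behaviour of interest; the vignette and README quote numbers only from
runs the test suite or acceptance script actually performs. Every source
of randomness (layout, layer jitter, per-condition noise) derives
deterministically from the single config seed, and a config hash is
recorded in each run log; re-running a config byte-reproduces its
measurement CSVs.

At the reduced matrix the in-plane pixels (0.78/1.17/1.56 mm) are twice
the reference size and twice as spread across FOVs, so per-diameter FOV
differences in mean error can exceed the (already narrow) synthetic
standard-error bands at mid-range diameters even though the one-way ANOVA
still finds FOV non-significant while kernel, thickness and size remain
highly significant. The corresponding strict band check in the acceptance
tests is allowed to fail visibly for the same reason the bone-kernel slope
inversion is: both are honest consequences of the stated noise and
resolution model, documented above, not bugs to be hidden.

## Using the package

```{r}
library(ctphantom)

# full default experiment (512 matrix; several tens of minutes)
report <- run_experiment(experiment_config(), out_dir = "runs/full")

# reduced grid as used by the packaged checks (a few minutes)
report <- run_experiment(experiment_config(matrix_size = 256, seed = 1))

glance(report)                  # one-row overall summary
tidy(report)                    # per-sphere x condition measurements
report$slopes                   # origin-forced slopes per condition
report$min_diameter             # minimum measurable diameter lookup
autoplot(report)                # error profiles by diameter and thickness
autoplot(report, "slopes")      # slope vs thickness by kernel and FOV
```

A thin command-line wrapper with `run-all`, `calibrate`, `simulate`,
`make-fixture` and `report` subcommands ships in
`inst/cli/ctphantom.R`.
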