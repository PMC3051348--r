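# ctphantom

Accuracy and precision of threshold-based CT volumetry, measured on
digital sphere phantoms.

Three-dimensional tumor volume is widely expected to replace longest-
diameter (RECIST-style) measurements for assessing therapy response, but a
volume read off a CT segmentation inherits systematic error from the voxel
grid: any voxel straddling the lesion boundary reports an intermediate
attenuation (the partial-volume effect), so fixed-threshold segmentation
misplaces the surface, and the bias grows with slice thickness and shrinks
with object size. `ctphantom` is for medical physicists and imaging
scientists who need those limits quantified under controlled conditions —
for protocol design, for sample-size planning in volumetric trials, or as
a baseline when validating cleverer segmentation.

The package simulates a gelatin phantom holding 55 PMMA spheres (eleven
inch-fraction diameters from 1.6 to 25.4 mm, five replicates each, 118.2
HU in a 37.6 HU background), voxelizes it with exact partial-volume
behaviour, emulates reconstruction kernels (Gaussian PSF + seeded noise),
synthesizes 1.25/2.5/5 mm slices by averaging 0.625 mm native slices, and
segments with a calibrated global threshold followed by filtered 3D
connected components. Per labelled object the volume estimate is

    V_CT = N_V * l * w * t

(voxel count times voxel volume), compared with the true volume
V = (4/3)*pi*r^3 as

    percent error = (V_CT - V_true) / V_true * 100%.

Accuracy per condition is summarized by the slope of the least-squares fit
of measured on true volume forced through the origin (slope 1 = perfect,
< 1 = underestimation); precision by the coefficient of variation and
Student-t 95% confidence intervals over the five replicates; significance
of each imaging factor by one-way ANOVA with Bonferroni-corrected pairwise
comparisons; and practical guidance by a lookup table of the minimum
sphere diameter measurable within a 10% or 20% error tolerance.

## Worked example

```r
library(ctphantom)

sphere_true_volume(c(3.175, 6.35, 25.4))
#> [1]   16.75829  134.06635 8580.24665
pixel_size(c(20, 30, 40))          # mm per pixel at a 512 matrix
#> [1] 0.3906250 0.5859375 0.7812500
global_threshold(c(101, 78, 101))  # averaged per-case calibration optima
#> [1] 93

# the full 36-condition grid at a reduced 256 matrix (a few minutes)
report <- run_experiment(experiment_config(matrix_size = 256, seed = 1),
                         verbose = FALSE)
report
#> <ct_report>
#>   36 conditions, 1800 measurement slots (10 analyzed sizes)
#>   detected: 1425/1800 (79.2%)
#>   accuracy slope range: 0.803 - 0.960
#>   config hash: a8b39fcb627fd898c3d4e6200c57fb04

head(report$slopes)
#> # A tibble: 6 × 6
#>     fov kernel slice_thickness slope r_squared     n
#>   <dbl> <chr>            <dbl> <dbl>     <dbl> <int>
#> 1    20 bone             0.625 0.921     1.000    50
#> 2    20 bone             1.25  0.926     1.000    47
#> 3    20 bone             2.5   0.901     0.999    39
#> 4    20 bone             5     0.823     0.997    28
#> 5    20 lung             0.625 0.960     1.000    50
#> 6    20 lung             1.25  0.952     1.000    48

head(report$min_diameter[report$min_diameter$tolerance == 20, ])
#> # A tibble: 6 × 6
#>     fov kernel slice_thickness tolerance min_diameter label
#>   <dbl> <chr>            <dbl>     <dbl>        <dbl> <chr>
#> 1    20 bone             0.625        20         9.57 9.57
#> 2    30 bone             0.625        20         8.91 8.91
#> 3    40 bone             0.625        20         9.73 9.73
#> 4    20 lung             0.625        20         5.61 5.61
#> 5    30 lung             0.625        20         7.15 7.15
#> 6    40 lung             0.625        20         9.40 9.4

report$anova$fov$p_value
#> [1] 0.6967182
```

Reading the output: every condition underestimates volume (all slopes
below 1), the underestimation deepens as slices thicken (0.921 at 0.625 mm
down to 0.823 at 5 mm for the bone kernel at 20 cm), the sharp lung kernel
is the most accurate, a ~20% error tolerance restricts thin-slice
volumetry to lesions of roughly 6–10 mm diameter and up, and field of view
has no significant effect on accuracy (p = 0.70) while kernel, thickness
and sphere size are highly significant. `tidy(report)` returns the
per-sphere measurement table, `glance(report)` a one-row summary, and
`autoplot(report)` / `autoplot(report, "slopes")` the error-profile and
slope figures. `run_experiment(..., out_dir = ...)` writes all tables as
tidy CSV plus a run log with a config hash; re-running a config
byte-reproduces its outputs.

A thin CLI over the same functions ships in `inst/cli/ctphantom.R`
(subcommands `run-all`, `calibrate`, `simulate`, `make-fixture`,
`report`).

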