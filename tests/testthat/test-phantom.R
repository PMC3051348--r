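test_that("sphere_true_volume reproduces reference volumes from inch fractions", {
  expect_equal(signif(sphere_true_volume(3.175), 3), 16.8)
  expect_equal(signif(sphere_true_volume(6.35), 3), 134)
  expect_equal(signif(sphere_true_volume(25.4), 3), 8580)
  expect_equal(sphere_true_volume(0), 0)
  expect_error(sphere_true_volume(-1), "non-negative")
})

test_that("pixel_size is FOV * 10 / matrix", {
  expect_equal(round(pixel_size(20, 512), 3), 0.391)
  expect_equal(round(pixel_size(40, 512), 3), 0.781)
  expect_equal(pixel_size(51.2, 512), 1.0)
  expect_error(pixel_size(0), "positive")
  expect_error(pixel_size(20, 0), ">= 1")
})

test_that("default diameter series is the 11 inch fractions", {
  d <- inch_fraction_diameters()
  expect_length(d, 11)
  expect_equal(min(d), 1.5875)
  expect_equal(max(d), 25.4)
  expect_true(all(diff(d) > 0))
})

test_that("build_phantom_spec lays out sizes x replicates spheres", {
  spec <- build_phantom_spec(seed = 7)
  expect_s3_class(spec, "phantom_spec")
  expect_equal(nrow(spec$spheres), 55)
  expect_equal(spec$n_sizes, 11)
  # every layer carries one sphere of every diameter
  per_layer <- table(spec$spheres$replicate)
  expect_true(all(per_layer == 11))
  # geometric invariants hold (validate errors otherwise)
  expect_silent(validate_phantom_spec(spec))
})

test_that("phantom layout is seed-deterministic and seed-sensitive", {
  a <- build_phantom_spec(seed = 3)
  b <- build_phantom_spec(seed = 3)
  c <- build_phantom_spec(seed = 4)
  expect_identical(a$spheres, b$spheres)
  expect_equal(sort(a$spheres$diameter), sort(c$spheres$diameter))
  expect_false(isTRUE(all.equal(a$spheres$x, c$spheres$x)))
  # layer layouts differ from each other within one phantom
  xy <- split(a$spheres[order(a$spheres$diameter), c("x", "y")],
              a$spheres$replicate[order(a$spheres$diameter)])
  expect_false(isTRUE(all.equal(xy[[1]], xy[[2]], check.attributes = FALSE)))
})

test_that("degenerate layout: one sphere is centered in the container", {
  spec <- build_phantom_spec(diameters = 10, n_replicates = 1,
                             container = c(40, 40, 40), seed = 1)
  expect_equal(nrow(spec$spheres), 1)
  # single layer sits mid-container (with bounded z jitter)
  expect_lt(abs(spec$spheres$z - 20), 2.5 + 1e-9)
})

test_that("placement in an impossible container errors", {
  expect_error(
    build_phantom_spec(diameters = c(20, 20), n_replicates = 1,
                       container = c(30, 30, 100), seed = 1),
    "too small"
  )
})

test_that("voxelize renders an empty phantom as uniform background", {
  spec <- build_phantom_spec(diameters = 5, n_replicates = 1,
                             container = c(20, 20, 20), seed = 1)
  spec$spheres <- spec$spheres[0, ]
  spec$n_sizes <- 0L
  vol <- voxelize(spec, pixel_size = 1, slice_thickness = 1, supersample = 2)
  expect_true(all(vol$data == 37.6))
})

test_that("voxel fully inside a sphere carries the sphere HU exactly", {
  spec <- single_sphere_spec(12.7)
  vol <- voxelize(spec, pixel_size = 0.5, slice_thickness = 0.5,
                  supersample = 4)
  expect_equal(max(vol$data), 118.2)
  # all HU within [background, sphere] before any noise
  expect_gte(min(vol$data), 37.6)
  expect_lte(max(vol$data), 118.2)
})

test_that("partial-volume occupancy conserves analytic sphere volume", {
  spec <- single_sphere_spec(9.525)
  vol <- voxelize(spec, pixel_size = 0.25, slice_thickness = 0.25,
                  supersample = 8)
  v <- occupancy_volume(vol)
  expect_lt(abs(v - sphere_true_volume(9.525)) / sphere_true_volume(9.525),
            0.01)
})

test_that("voxelization is symmetric under reflection of sphere centers", {
  spec <- build_phantom_spec(diameters = c(5, 8), n_replicates = 1,
                             container = c(40, 40, 20), seed = 5)
  vol <- voxelize(spec, pixel_size = 1, slice_thickness = 1, supersample = 4)
  refl <- spec
  refl$spheres$x <- refl$container[1] - refl$spheres$x
  refl$spheres$y <- refl$container[2] - refl$spheres$y
  refl$spheres$z <- refl$container[3] - refl$spheres$z
  vol_r <- voxelize(refl, pixel_size = 1, slice_thickness = 1,
                    supersample = 4)
  d <- dim(vol$data)
  expect_equal(vol_r$data[d[1]:1, d[2]:1, d[3]:1], vol$data,
               tolerance = 1e-12)
})

test_that("voxelize rejects a phantom that does not fit the grid", {
  spec <- single_sphere_spec(12.7, container = c(152, 152, 20))
  expect_error(voxelize(spec, pixel_size = 1, slice_thickness = 1,
                        supersample = 1, matrix_size = 16),
               "representable grid")
})

test_that("phantom manifest JSON round-trips", {
  spec <- build_phantom_spec(diameters = c(5, 8), n_replicates = 2,
                             container = c(40, 40, 60), seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back$spheres, spec$spheres)
  expect_equal(back$container, spec$container)
  expect_equal(back$background_hu, spec$background_hu)
})

test_that("ct_volume IO round-trips through NIfTI and raw + sidecar", {
  spec <- single_sphere_spec(8)
  vol <- voxelize(spec, pixel_size = 0.5, slice_thickness = 1,
                  supersample = 2)
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  write_ct_volume(vol, nii)
  back <- read_ct_volume(nii)
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(back$pixel_size, vol$pixel_size)
  expect_equal(back$slice_thickness, vol$slice_thickness)

  raw <- withr::local_tempfile(fileext = ".raw")
  write_ct_volume(vol, raw)
  back2 <- read_ct_volume(raw)
  expect_equal(back2$data, vol$data, tolerance = 1e-5)
  expect_equal(back2$origin, vol$origin)
})
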