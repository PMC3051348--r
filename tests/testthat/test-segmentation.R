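test_that("thresholding is inclusive and bounded", {
  v <- ct_volume(array(37.6, c(4, 4, 2)), 1, 1)
  expect_false(any(threshold_volume(v, 93)$mask))
  expect_true(all(threshold_volume(v, -1000)$mask))
  v$data[2, 2, 1] <- 93
  expect_true(threshold_volume(v, 93)$mask[2, 2, 1]) # boundary included
})

test_that("an isolated voxel labels as one object of size one", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  lab <- connected_components_3d(m)
  expect_equal(lab$n_objects, 1L)
  expect_equal(sum(lab$labels > 0), 1L)
})

test_that("corner-touching voxels merge under 26- but not 6-adjacency", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE
  expect_equal(connected_components_3d(m, "face-6")$n_objects, 2L)
  expect_equal(connected_components_3d(m, "full-26")$n_objects, 1L)
})

test_that("labels are deterministic and ordered by first voxel", {
  m <- array(FALSE, c(6, 6, 2))
  m[5:6, 5:6, 2] <- TRUE # later in lexicographic order
  m[1:2, 1:2, 1] <- TRUE # first voxel of the grid
  lab <- connected_components_3d(m)
  expect_equal(lab$labels[1, 1, 1], 1L)
  expect_equal(lab$labels[5, 5, 2], 2L)
})

test_that("random masks match the flood-fill oracle under both adjacencies", {
  set.seed(31)
  for (i in 1:40) {
    m <- random_mask()
    conn <- if (i %% 2 == 0) "full-26" else "face-6"
    got <- connected_components_3d(m, conn)
    want <- flood_fill_label(m, conn)
    expect_same_partition(got$labels, want)
    expect_equal(got$n_objects, max(want, 0L))
  }
})

test_that("neighbor pruning removes under-connected voxels iteratively", {
  # isolated voxel: 0 face neighbors < 3 -> removed
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  lab <- connected_components_3d(m)
  out <- filter_components(lab, seg_params(min_neighbors = 3, min_volume = 0))
  expect_equal(out$n_objects, 0L)

  # a chain hanging off a block is eaten back voxel by voxel: each removal
  # exposes the next (single pass would stop after the tip)
  m2 <- array(FALSE, c(12, 4, 4))
  m2[1:3, 1:3, 1:3] <- TRUE # 27-voxel block, interior-rich
  m2[4:9, 2, 2] <- TRUE     # 1-voxel-wide tail
  lab2 <- connected_components_3d(m2)
  out2 <- filter_components(lab2, seg_params(min_neighbors = 3,
                                             min_volume = 0))
  kept <- which(out2$labels > 0L, arr.ind = TRUE)
  expect_true(all(kept[, 1] <= 3)) # the whole tail is gone
  expect_gt(sum(out2$labels > 0L), 0)
})

test_that("minimum-volume filtering deletes small components", {
  # 10 voxels x 0.1 mm^3 each = 1.0 mm^3 < 1.68 mm^3 -> deleted
  m <- array(FALSE, c(10, 3, 3))
  m[1:10, 2, 2] <- TRUE
  lab <- connected_components_3d(m, pixel_size = sqrt(0.1 / 1),
                                 slice_thickness = 1)
  expect_equal(sum(lab$labels > 0) * voxel_volume(lab), 1.0,
               tolerance = 1e-12)
  out <- filter_components(lab, seg_params(min_neighbors = 0,
                                           min_volume = 1.68))
  expect_equal(out$n_objects, 0L)
})

test_that("the no-op filter is the identity", {
  set.seed(41)
  m <- random_mask(c(8, 8, 8), 0.3)
  lab <- connected_components_3d(m)
  out <- filter_components(lab, seg_params(min_neighbors = 0,
                                           min_volume = 0))
  expect_identical(out$labels, lab$labels)
  expect_identical(out$n_objects, lab$n_objects)
})

test_that("filtering is idempotent and never adds voxels", {
  set.seed(43)
  params <- seg_params(min_neighbors = 3, min_volume = 0.5)
  for (i in 1:10) {
    m <- random_mask(c(8, 8, 8), 0.45)
    lab <- connected_components_3d(m)
    once <- filter_components(lab, params)
    twice <- filter_components(once, params)
    expect_identical(twice$labels, once$labels)
    # subset property
    expect_true(all(lab$labels[once$labels > 0L] > 0L))
    # surviving labels are consecutive 1..n
    if (once$n_objects > 0) {
      expect_setequal(unique(once$labels[once$labels > 0]),
                      seq_len(once$n_objects))
    }
  }
})

test_that("label compaction preserves surviving voxel sets exactly", {
  m <- array(FALSE, c(12, 5, 5))
  m[1, 1, 1] <- TRUE         # 1 voxel, first in label order; dropped
  m[5:6, 3:4, 2:3] <- TRUE   # 8 voxels
  m[9:12, 1:3, 4:5] <- TRUE  # 24 voxels
  lab <- connected_components_3d(m)
  expect_equal(lab$n_objects, 3L)
  out <- filter_components(lab, seg_params(min_neighbors = 0, min_volume = 2))
  expect_equal(out$n_objects, 2L)
  # bijection between surviving old and new labels, voxel sets unchanged
  expect_identical(which(out$labels == 1L), which(lab$labels == 2L))
  expect_identical(which(out$labels == 2L), which(lab$labels == 3L))
})

test_that("segment_volume chains threshold, labeling, and filters", {
  fx <- make_fixture("tiny", seed = 3)
  lab <- segment_volume(fx$volume, seg_params(threshold = 78))
  expect_equal(lab$n_objects, 3L)
  # origin preserved so downstream centroids are in phantom coordinates
  expect_equal(lab$origin, fx$volume$origin)
})
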