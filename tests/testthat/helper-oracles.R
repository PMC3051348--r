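# Independent oracles used across tests. These deliberately use naive
# scalar loops so they share no code path with the package internals.

# Breadth-first flood fill labeling of a 3D logical mask.
flood_fill_label <- function(mask, connectivity = "full-26") {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == "face-6") {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  }
  labels <- array(0L, d)
  lab <- 0L
  for (start in which(mask)) { # ascending = lexicographic first-voxel order
    if (labels[start] > 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      vc <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        n1 <- vc[1] + offs$dx[r]; n2 <- vc[2] + offs$dy[r]
        n3 <- vc[3] + offs$dz[r]
        if (n1 >= 1 && n1 <= d[1] && n2 >= 1 && n2 <= d[2] &&
            n3 >= 1 && n3 <= d[3]) {
          ni <- n1 + (n2 - 1L) * d[1] + (n3 - 1L) * d[1] * d[2]
          if (mask[ni] && labels[ni] == 0L) {
            labels[ni] <- lab
            queue <- c(queue, ni)
          }
        }
      }
    }
  }
  labels
}

# Per-voxel accumulation of component sizes and centroids (in mm).
accumulate_components <- function(labeled) {
  d <- dim(labeled$labels)
  n <- labeled$n_objects
  count <- integer(n)
  sx <- sy <- sz <- numeric(n)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    l <- labeled$labels[i, j, k]
    if (l > 0L) {
      count[l] <- count[l] + 1L
      sx[l] <- sx[l] + labeled$origin[1] + (i - 0.5) * labeled$pixel_size
      sy[l] <- sy[l] + labeled$origin[2] + (j - 0.5) * labeled$pixel_size
      sz[l] <- sz[l] + labeled$origin[3] + (k - 0.5) * labeled$slice_thickness
    }
  }
  list(n_voxels = count,
       v_ct = count * labeled$pixel_size^2 * labeled$slice_thickness,
       x = sx / count, y = sy / count, z = sz / count)
}

# Grid-search minimizer of sum((v_ct - s * v_true)^2) over slopes.
grid_search_slope <- function(v_true, v_ct, lo = 0, hi = 3, n = 60001) {
  s <- seq(lo, hi, length.out = n)
  sse <- vapply(s, function(si) sum((v_ct - si * v_true)^2), numeric(1))
  s[which.min(sse)]
}

# A single-sphere phantom in a small container, for voxelization checks.
single_sphere_spec <- function(diameter, container = NULL,
                               background_hu = 37.6, sphere_hu = 118.2) {
  if (is.null(container)) container <- rep(diameter + 6, 3)
  build_phantom_spec(diameters = diameter, n_replicates = 1,
                     container = container, background_hu = background_hu,
                     sphere_hu = sphere_hu, seed = 1)
}

# Occupancy-sum volume recovered from a noiseless voxelized sphere volume.
occupancy_volume <- function(vol, background_hu = 37.6, sphere_hu = 118.2) {
  sum((vol$data - background_hu) / (sphere_hu - background_hu)) *
    voxel_volume(vol)
}

random_mask <- function(d = c(6, 6, 6), p = 0.35) {
  array(runif(prod(d)) < p, d)
}

# Compare two labelings as partitions (label ids may differ).
expect_same_partition <- function(a, b) {
  expect_identical(a > 0L, b > 0L)
  fa <- a[a > 0L]
  fb <- b[b > 0L]
  expect_identical(as.integer(match(fa, unique(fa))),
                   as.integer(match(fb, unique(fb))))
}
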