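#' Segmentation parameters
#'
#' Parameters of the global-threshold + filtered connected-components
#' segmentation: the HU threshold (inclusive, `HU >= threshold` is
#' foreground), the minimum surviving component volume in mm^3, the minimum
#' per-voxel neighbor count, and the adjacency used for component labeling.
#' Component labeling defaults to full 26-adjacency ("contiguous" objects);
#' the per-voxel neighbor rule counts face (6-) neighbors, a stricter
#' adjacency whose purpose is to break thin noise bridges.
#'
#' @param threshold Segmentation threshold in HU, default 93.
#' @param min_volume Minimum component volume in mm^3; default
#'   [default_min_volume()] = 1.68 (ten percent of the true volume of the
#'   smallest analyzed sphere, 1/8 in).
#' @param min_neighbors Minimum neighbors per voxel (0-26), default 3.
#' @param connectivity Adjacency for component labeling: `"full-26"`
#'   (default) or `"face-6"`.
#' @param neighbor_connectivity Adjacency for the neighbor-count rule,
#'   default `"face-6"`.
#' @return A `seg_params` list.
#' @export
seg_params <- function(threshold = 93,
                       min_volume = default_min_volume(),
                       min_neighbors = 3,
                       connectivity = c("full-26", "face-6"),
                       neighbor_connectivity = c("face-6", "full-26")) {
  connectivity <- match.arg(connectivity)
  neighbor_connectivity <- match.arg(neighbor_connectivity)
  if (min_volume < 0) stop("`min_volume` must be >= 0", call. = FALSE)
  if (min_neighbors < 0 || min_neighbors > 26) {
    stop("`min_neighbors` must be in [0, 26]", call. = FALSE)
  }
  structure(
    list(threshold = threshold, min_volume = min_volume,
         min_neighbors = as.integer(min_neighbors),
         connectivity = connectivity,
         neighbor_connectivity = neighbor_connectivity),
    class = "seg_params"
  )
}

#' Default minimum component volume
#'
#' Ten percent of the true volume of the smallest analyzed sphere in the
#' diameter series. The smallest size class is excluded from analysis (its
#' segmentation is unreliable), so the reference sphere is the second
#' smallest diameter: 1/8 in = 3.175 mm, giving 1.68 mm^3.
#'
#' @param diameters Diameter series in mm, default
#'   [inch_fraction_diameters()].
#' @param fraction Fraction of the reference true volume, default 0.1.
#' @return Minimum volume in mm^3.
#' @export
#' @examples
#' round(default_min_volume(), 2) # 1.68
default_min_volume <- function(diameters = inch_fraction_diameters(),
                               fraction = 0.1) {
  d <- sort(diameters)
  ref <- if (length(d) >= 2) d[2] else d[1]
  fraction * sphere_true_volume(ref)
}

#' Threshold a volume into a foreground mask
#'
#' Foreground where `HU >= threshold` (inclusive at the boundary).
#'
#' @param volume A `ct_volume`.
#' @param threshold Threshold in HU.
#' @return A `ct_mask`: logical 3D array plus voxel geometry.
#' @export
threshold_volume <- function(volume, threshold) {
  stopifnot(inherits(volume, "ct_volume"))
  structure(
    list(mask = volume$data >= threshold,
         pixel_size = volume$pixel_size,
         slice_thickness = volume$slice_thickness,
         origin = volume$origin),
    class = "ct_mask"
  )
}

#' @export
print.ct_mask <- function(x, ...) {
  cat(sprintf("<ct_mask> %s voxels, %d foreground\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask)))
  invisible(x)
}

neighbor_offsets <- function(connectivity, forward_only = FALSE) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == "face-6") {
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  }
  if (forward_only) {
    # one of each +/- pair (lexicographically positive direction)
    keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) |
      (g$dz == 0 & g$dy == 0 & g$dx > 0)
    g <- g[keep, ]
  }
  as.matrix(g)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "ct_mask")) mask$mask else mask
}

#' Label 3D connected components
#'
#' Maximal connected sets of foreground voxels under the chosen adjacency
#' receive distinct labels 1..n. Labels are ordered by each component's
#' first voxel in array (lexicographic) order, so labeling is deterministic.
#' Connectivity is resolved by building the voxel-adjacency edge list and
#' taking graph components (igraph).
#'
#' @param mask A `ct_mask` or a logical 3D array.
#' @param connectivity `"full-26"` (default) or `"face-6"`.
#' @param pixel_size,slice_thickness Voxel geometry in mm; taken from the
#'   `ct_mask` when available, otherwise default 1.
#' @param origin Grid origin in mm.
#' @return A `labeled_volume`: integer label array (`0` = background),
#'   `n_objects`, and voxel geometry.
#' @export
connected_components_3d <- function(mask,
                                    connectivity = c("full-26", "face-6"),
                                    pixel_size = NULL,
                                    slice_thickness = NULL,
                                    origin = NULL) {
  connectivity <- match.arg(connectivity)
  if (inherits(mask, "ct_mask")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    if (is.null(slice_thickness)) slice_thickness <- mask$slice_thickness
    if (is.null(origin)) origin <- mask$origin
    mask <- mask$mask
  }
  if (is.null(pixel_size)) pixel_size <- 1
  if (is.null(slice_thickness)) slice_thickness <- 1
  if (is.null(origin)) origin <- c(0, 0, 0)
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  idx <- which(mask) # ascending linear indices = lexicographic voxel order
  labels <- array(0L, d)
  n_obj <- 0L
  if (length(idx)) {
    offs <- neighbor_offsets(connectivity, forward_only = TRUE)
    co <- arrayInd(idx, d)
    vid <- integer(prod(d))
    vid[idx] <- seq_along(idx)
    edges <- vector("list", nrow(offs))
    for (r in seq_len(nrow(offs))) {
      dx <- offs[r, 1]; dy <- offs[r, 2]; dz <- offs[r, 3]
      ok <- co[, 1] + dx >= 1L & co[, 1] + dx <= d[1] &
        co[, 2] + dy >= 1L & co[, 2] + dy <= d[2] &
        co[, 3] + dz >= 1L & co[, 3] + dz <= d[3]
      src <- idx[ok]
      nbr <- src + dx + dy * d[1] + dz * d[1] * d[2]
      hit <- vid[nbr] > 0L
      edges[[r]] <- cbind(vid[src[hit]], vid[nbr[hit]])
    }
    E <- do.call(rbind, edges)
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (nrow(E)) g <- igraph::add_edges(g, t(E))
    mem <- igraph::components(g)$membership
    # relabel in order of first appearance along ascending voxel index
    lab <- match(mem, unique(mem))
    labels[idx] <- lab
    n_obj <- max(lab)
  }
  structure(
    list(labels = labels, n_objects = n_obj,
         pixel_size = pixel_size, slice_thickness = slice_thickness,
         origin = origin, connectivity = connectivity),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s voxels, %d object(s) (%s)\n",
              paste(dim(x$labels), collapse = " x "), x$n_objects,
              x$connectivity %||% "full-26"))
  invisible(x)
}

# Remove foreground voxels with fewer than min_neighbors foreground
# neighbors, iterating to a fixed point. Sparse: counts are evaluated only
# at foreground voxels (the grid is mostly background), so each pass costs
# O(|foreground| x |offsets|).
prune_under_connected <- function(mask, min_neighbors,
                                  connectivity = "face-6") {
  d <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  lin_off <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  idx <- which(mask)
  co <- arrayInd(idx, d)
  pruned <- FALSE
  while (length(idx)) {
    cnt <- integer(length(idx))
    for (r in seq_len(nrow(offs))) {
      ok <- co[, 1] + offs[r, 1] >= 1L & co[, 1] + offs[r, 1] <= d[1] &
        co[, 2] + offs[r, 2] >= 1L & co[, 2] + offs[r, 2] <= d[2] &
        co[, 3] + offs[r, 3] >= 1L & co[, 3] + offs[r, 3] <= d[3]
      cnt[ok] <- cnt[ok] + mask[idx[ok] + lin_off[r]]
    }
    drop <- cnt < min_neighbors
    if (!any(drop)) break
    mask[idx[drop]] <- FALSE
    idx <- idx[!drop]
    co <- co[!drop, , drop = FALSE]
    pruned <- TRUE
  }
  list(mask = mask, pruned = pruned)
}

#' Filter labeled components by connectedness and minimum volume
#'
#' Two-stage filter: (a) voxels with fewer than `min_neighbors` foreground
#' neighbors (under `neighbor_connectivity`) are removed, iterating to a
#' fixed point because each removal can strand further voxels; if any voxel
#' was pruned, components are relabeled (pruning can split an object);
#' (b) components whose volume (voxel count x l x w x t) is below
#' `min_volume` are deleted and the surviving labels are compacted to
#' 1..n in first-voxel order. The filter is idempotent and never adds
#' voxels.
#'
#' @param labeled A `labeled_volume`.
#' @param params A `seg_params`.
#' @return A filtered `labeled_volume`.
#' @export
filter_components <- function(labeled, params = seg_params()) {
  stopifnot(inherits(labeled, "labeled_volume"),
            inherits(params, "seg_params"))
  mask <- labeled$labels > 0L
  pruned <- FALSE
  if (params$min_neighbors > 0L && any(mask)) {
    res <- prune_under_connected(mask, params$min_neighbors,
                                 params$neighbor_connectivity)
    mask <- res$mask
    pruned <- res$pruned
  }
  if (pruned) {
    relabeled <- connected_components_3d(
      mask, connectivity = labeled$connectivity %||% "full-26",
      pixel_size = labeled$pixel_size,
      slice_thickness = labeled$slice_thickness,
      origin = labeled$origin
    )
    labels <- relabeled$labels
    n_obj <- relabeled$n_objects
  } else {
    labels <- labeled$labels
    n_obj <- labeled$n_objects
  }

  if (n_obj > 0L && params$min_volume > 0) {
    vox_vol <- labeled$pixel_size^2 * labeled$slice_thickness
    counts <- tabulate(labels[labels > 0L], nbins = n_obj)
    keep <- counts * vox_vol >= params$min_volume
    if (!all(keep)) {
      remap <- integer(n_obj)
      remap[keep] <- seq_len(sum(keep)) # order preserved => first-voxel order
      old <- labels[labels > 0L]
      labels[labels > 0L] <- remap[old]
      n_obj <- sum(keep)
    }
  }
  structure(
    list(labels = labels, n_objects = as.integer(n_obj),
         pixel_size = labeled$pixel_size,
         slice_thickness = labeled$slice_thickness,
         origin = labeled$origin,
         connectivity = labeled$connectivity %||% "full-26"),
    class = "labeled_volume"
  )
}

#' Segment a CT volume end to end
#'
#' Threshold, label 3D connected components, and filter, in one call. For
#' large grids the foreground bounding box (plus a one-voxel margin) is
#' cropped before labeling and the result re-embedded; the returned origin
#' is unchanged.
#'
#' @param volume A `ct_volume`.
#' @param params A `seg_params`.
#' @return A `labeled_volume` on the full input grid.
#' @export
segment_volume <- function(volume, params = seg_params()) {
  stopifnot(inherits(volume, "ct_volume"))
  mask <- volume$data >= params$threshold
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) {
    return(structure(
      list(labels = array(0L, d), n_objects = 0L,
           pixel_size = volume$pixel_size,
           slice_thickness = volume$slice_thickness,
           origin = volume$origin, connectivity = params$connectivity),
      class = "labeled_volume"
    ))
  }
  co <- arrayInd(idx, d)
  lo <- pmax(apply(co, 2, min) - 1L, 1L)
  hi <- pmin(apply(co, 2, max) + 1L, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  lab_sub <- connected_components_3d(
    sub, connectivity = params$connectivity,
    pixel_size = volume$pixel_size,
    slice_thickness = volume$slice_thickness
  )
  lab_sub <- filter_components(lab_sub, params)
  labels <- array(0L, d)
  labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- lab_sub$labels
  structure(
    list(labels = labels, n_objects = lab_sub$n_objects,
         pixel_size = volume$pixel_size,
         slice_thickness = volume$slice_thickness,
         origin = volume$origin, connectivity = params$connectivity),
    class = "labeled_volume"
  )
}
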