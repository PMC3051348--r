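#' Measure labeled components
#'
#' One row per label: voxel count `n_voxels`, volume
#' `V_CT = N_V * l * w * t` (exact integer count times voxel volume), and
#' the centroid (mean of voxel centers) in mm, in the same frame as the
#' phantom coordinates.
#'
#' @param labeled A `labeled_volume`.
#' @return A tibble with columns `label`, `n_voxels`, `v_ct`, `x`, `y`, `z`;
#'   voxel geometry is carried in attributes `pixel_size` and
#'   `slice_thickness`. Empty labeling gives a zero-row tibble.
#' @export
measure_components <- function(labeled) {
  stopifnot(inherits(labeled, "labeled_volume"))
  vox_vol <- labeled$pixel_size^2 * labeled$slice_thickness
  if (labeled$n_objects == 0L) {
    out <- tibble::tibble(label = integer(), n_voxels = integer(),
                          v_ct = numeric(), x = numeric(), y = numeric(),
                          z = numeric())
  } else {
    idx <- which(labeled$labels > 0L)
    lab <- labeled$labels[idx]
    co <- arrayInd(idx, dim(labeled$labels))
    # voxel centers in mm
    cx <- labeled$origin[1] + (co[, 1] - 0.5) * labeled$pixel_size
    cy <- labeled$origin[2] + (co[, 2] - 0.5) * labeled$pixel_size
    cz <- labeled$origin[3] + (co[, 3] - 0.5) * labeled$slice_thickness
    n <- tabulate(lab, nbins = labeled$n_objects)
    sums <- rowsum(cbind(cx, cy, cz), lab)
    out <- tibble::tibble(
      label = sort(unique(lab)),
      n_voxels = n[n > 0L],
      v_ct = n[n > 0L] * vox_vol,
      x = as.numeric(sums[, 1]) / n[n > 0L],
      y = as.numeric(sums[, 2]) / n[n > 0L],
      z = as.numeric(sums[, 3]) / n[n > 0L]
    )
  }
  attr(out, "pixel_size") <- labeled$pixel_size
  attr(out, "slice_thickness") <- labeled$slice_thickness
  out
}

#' Percent error of a measured volume
#'
#' `(V_CT - V_true) / V_true * 100`.
#'
#' @param v_ct Measured volume(s), mm^3.
#' @param v_true True volume(s), mm^3 (> 0).
#' @return Percent error (negative = underestimate).
#' @export
#' @examples
#' percent_error(8.4, 16.8) # -50
percent_error <- function(v_ct, v_true) {
  if (any(v_true <= 0)) stop("`v_true` must be > 0", call. = FALSE)
  (v_ct - v_true) / v_true * 100
}

#' Match measured components to ground-truth spheres
#'
#' Each component is assigned to the nearest sphere center lying within
#' that sphere's radius plus one voxel diagonal (the gate scales with
#' resolution; blur shifts centroids by far less than a voxel). A component
#' equidistant to two gates goes to the nearer center, exact ties to the
#' lower sphere id. When several components match one sphere, the largest
#' is kept and the rest are counted as fragments. Spheres with no matching
#' component are marked `detected = FALSE` with `v_ct` and `percent_error`
#' absent (`NA`).
#'
#' @param components Tibble from [measure_components()] (its
#'   `pixel_size` / `slice_thickness` attributes supply the gate size).
#' @param spec The `phantom_spec` the volume was generated from.
#' @param voxel_diag Optional override of the gate margin in mm.
#' @return A tibble with one row per sphere: `id`, `replicate`, `diameter`,
#'   `v_true`, `detected`, `n_voxels`, `v_ct`, `percent_error`,
#'   `n_fragments`.
#' @export
match_to_spheres <- function(components, spec, voxel_diag = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(voxel_diag)) {
    p <- attr(components, "pixel_size")
    t <- attr(components, "slice_thickness")
    if (is.null(p) || is.null(t)) {
      stop("`components` lacks voxel geometry; supply `voxel_diag`",
           call. = FALSE)
    }
    voxel_diag <- sqrt(2 * p^2 + t^2)
  }
  sph <- spec$spheres
  out <- tibble::tibble(
    id = sph$id, replicate = sph$replicate, diameter = sph$diameter,
    v_true = sphere_true_volume(sph$diameter),
    detected = FALSE, n_voxels = NA_integer_, v_ct = NA_real_,
    percent_error = NA_real_, n_fragments = 0L
  )
  if (nrow(components) == 0) return(out)

  # assignment of each component to a sphere gate (NA if outside all gates)
  assign_id <- integer(nrow(components))
  for (i in seq_len(nrow(components))) {
    dist <- sqrt((sph$x - components$x[i])^2 +
                   (sph$y - components$y[i])^2 +
                   (sph$z - components$z[i])^2)
    gate <- dist <= sph$diameter / 2 + voxel_diag
    if (!any(gate)) {
      assign_id[i] <- NA_integer_
    } else {
      cand <- which(gate)
      # nearest center; exact tie -> lower sphere id (cand is id-ordered)
      assign_id[i] <- cand[which.min(dist[cand])]
    }
  }
  for (s in unique(assign_id[!is.na(assign_id)])) {
    hits <- which(assign_id == s)
    main <- hits[which.max(components$v_ct[hits])] # tie -> lower label
    out$detected[s] <- TRUE
    out$n_voxels[s] <- components$n_voxels[main]
    out$v_ct[s] <- components$v_ct[main]
    out$percent_error[s] <- percent_error(components$v_ct[main],
                                          out$v_true[s])
    out$n_fragments[s] <- length(hits) - 1L
  }
  out
}

#' Detection rate for one sphere diameter
#'
#' Fraction of measurements at the given diameter with `detected = TRUE`.
#'
#' @param measurements Tibble with `diameter` and `detected` columns.
#' @param diameter Diameter in mm (matched within a small tolerance).
#' @return Detected fraction in `[0, 1]`.
#' @export
detection_rate <- function(measurements, diameter) {
  rows <- measurements[abs(measurements$diameter - diameter) < 1e-6, ]
  if (nrow(rows) == 0) {
    stop("no measurements at that diameter", call. = FALSE)
  }
  mean(rows$detected)
}
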