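#' Default sphere diameter series (inch fractions)
#'
#' Eleven diameters from 1/16 in to 1 in (1.5875 mm to 25.4 mm), matching the
#' commercially available acrylic (PMMA) precision sphere sizes used in CT
#' volumetry phantoms. True volumes back-calculated from these exact inch
#' fractions reproduce the reference values 16.8, 134, and 8580 mm^3 (for
#' 1/8, 1/4, and 1 in), where the rounded millimetre labels (3.2, 6.4,
#' 25.4 mm) would not for the smaller sizes.
#'
#' @return Numeric vector of 11 diameters in mm, ascending.
#' @export
#' @examples
#' inch_fraction_diameters()
inch_fraction_diameters <- function() {
  25.4 * c(1 / 16, 1 / 8, 3 / 16, 1 / 4, 5 / 16, 3 / 8, 1 / 2, 5 / 8,
           3 / 4, 7 / 8, 1)
}

#' True volume of a sphere from its diameter
#'
#' `(4/3) * pi * r^3` with `r = diameter / 2`.
#'
#' @param diameter Sphere diameter in mm (vectorized, must be >= 0).
#' @return Volume in mm^3.
#' @export
#' @examples
#' sphere_true_volume(25.4) # 8580 mm^3 to 3 s.f.
sphere_true_volume <- function(diameter) {
  if (!is.numeric(diameter) || any(diameter < 0)) {
    stop("`diameter` must be non-negative", call. = FALSE)
  }
  (4 / 3) * pi * (diameter / 2)^3
}

#' Reconstruction pixel size from field of view and matrix
#'
#' Square pixel edge length in mm: `FOV (cm) * 10 / matrix`.
#'
#' @param fov Reconstruction field of view in cm.
#' @param matrix Reconstruction matrix size (pixels per side), default 512.
#' @return Pixel size in mm.
#' @export
#' @examples
#' pixel_size(20) # 0.391 mm
#' pixel_size(40) # 0.781 mm
pixel_size <- function(fov, matrix = 512) {
  if (!is.numeric(fov) || any(fov <= 0)) {
    stop("`fov` must be positive", call. = FALSE)
  }
  if (!is.numeric(matrix) || any(matrix < 1)) {
    stop("`matrix` must be >= 1", call. = FALSE)
  }
  fov * 10 / matrix
}

#' Build a ground-truth phantom specification
#'
#' Lays out `length(diameters) * n_replicates` spheres in `n_replicates`
#' horizontal layers inside a rectangular gelatin container, one sphere of
#' every diameter per layer. In-plane placement is randomized per layer (no
#' two layers share a layout) with a pairwise non-overlap guarantee; the
#' axial (z) position of every layer is jittered so that sphere centers fall
#' at arbitrary phase relative to any slice grid, which is a real source of
#' replicate-to-replicate variability in slice-sampled volumetry.
#'
#' @param diameters Sphere diameters in mm, default [inch_fraction_diameters()].
#' @param n_replicates Number of layers (replicates per diameter), default 5.
#' @param container Container dimensions `c(x, y, z)` in mm, default
#'   `c(152, 152, 400)` (a 15.2 x 15.2 x 40.0 cm box).
#' @param background_hu Gelatin background attenuation, default 37.6 HU.
#' @param sphere_hu Sphere (PMMA) attenuation, default 118.2 HU.
#' @param seed Layout seed; placement is deterministic given the seed.
#' @param margin Minimum clearance between spheres and to container walls, mm.
#' @param max_tries Rejection-sampling attempts per sphere before a layer is
#'   restarted; after 25 failed layer restarts an error reports the container
#'   as too small.
#'
#' @return A `phantom_spec`: list with a `spheres` tibble (`id`, `replicate`,
#'   `diameter`, `x`, `y`, `z`, `hu`), `background_hu`, `container`,
#'   `n_sizes`, `n_replicates`, `seed`.
#' @export
#' @examples
#' spec <- build_phantom_spec(seed = 1)
#' nrow(spec$spheres) # 55
build_phantom_spec <- function(diameters = inch_fraction_diameters(),
                               n_replicates = 5,
                               container = c(152, 152, 400),
                               background_hu = 37.6,
                               sphere_hu = 118.2,
                               seed = 1,
                               margin = 2,
                               max_tries = 400) {
  if (length(diameters) == 0 || any(diameters <= 0)) {
    stop("`diameters` must be non-empty and positive", call. = FALSE)
  }
  stopifnot(n_replicates >= 1, length(container) == 3L, all(container > 0))
  if (background_hu == sphere_hu) {
    stop("background and sphere HU must differ", call. = FALSE)
  }
  radii <- diameters / 2
  if (any(2 * radii + 2 * margin > container[1]) ||
      any(2 * radii + 2 * margin > container[2])) {
    stop("container too small for the largest sphere", call. = FALSE)
  }

  layer_pitch <- container[3] / n_replicates
  max_r <- max(radii)
  if (layer_pitch < 2 * max_r + margin) {
    stop("container too small: layers would overlap axially", call. = FALSE)
  }

  place_layer <- function(rep_i) {
    z_mid <- (rep_i - 0.5) * layer_pitch
    # jitter the layer relative to any slice grid; keep spheres inside both
    # the layer band and the container
    jit_max <- min(2.5, (layer_pitch - 2 * max_r - margin) / 2,
                   z_mid - max_r - margin,
                   container[3] - z_mid - max_r - margin)
    jit_max <- max(jit_max, 0)
    z_l <- z_mid + stats::runif(1, -jit_max, jit_max)
    ord <- order(radii, decreasing = TRUE) # place big spheres first
    for (restart in seq_len(25)) {
      xs <- ys <- numeric(length(radii))
      ok_all <- TRUE
      for (i in ord) {
        r <- radii[i]
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          x <- stats::runif(1, r + margin, container[1] - r - margin)
          y <- stats::runif(1, r + margin, container[2] - r - margin)
          prev <- ord[seq_len(which(ord == i) - 1)]
          if (length(prev) == 0 ||
              all(sqrt((xs[prev] - x)^2 + (ys[prev] - y)^2) >
                  radii[prev] + r + margin)) {
            xs[i] <- x; ys[i] <- y
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok_all <- FALSE; break }
      }
      if (ok_all) {
        return(tibble::tibble(
          replicate = rep_i,
          diameter = diameters,
          x = xs, y = ys, z = z_l,
          hu = sphere_hu
        ))
      }
    }
    stop("sphere placement failed: container too small for this layout",
         call. = FALSE)
  }

  spheres <- withr::with_seed(
    seed,
    purrr::map(seq_len(n_replicates), place_layer)
  )
  spheres <- dplyr::bind_rows(spheres)
  spheres <- dplyr::mutate(spheres, id = dplyr::row_number(),
                           .before = "replicate")

  spec <- structure(
    list(
      spheres = spheres,
      background_hu = background_hu,
      container = as.numeric(container),
      n_sizes = length(diameters),
      n_replicates = as.integer(n_replicates),
      seed = seed
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks the geometric invariants: sphere count equals sizes x replicates,
#' every sphere (plus its radius) lies inside the container, and no two
#' spheres overlap (pairwise center distance exceeds the sum of radii).
#'
#' @param spec A `phantom_spec`.
#' @return `spec`, invisibly; errors if an invariant is violated.
#' @export
validate_phantom_spec <- function(spec) {
  s <- spec$spheres
  if (nrow(s) != spec$n_sizes * spec$n_replicates) {
    stop("sphere count != n_sizes * n_replicates", call. = FALSE)
  }
  r <- s$diameter / 2
  inside <- s$x - r >= 0 & s$x + r <= spec$container[1] &
    s$y - r >= 0 & s$y + r <= spec$container[2] &
    s$z - r >= 0 & s$z + r <= spec$container[3]
  if (!all(inside)) stop("sphere outside container", call. = FALSE)
  if (nrow(s) > 1) {
    d2 <- as.matrix(stats::dist(cbind(s$x, s$y, s$z)))
    lim <- outer(r, r, "+")
    diag(d2) <- Inf
    if (any(d2 <= lim)) stop("overlapping spheres in phantom", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d spheres (%d sizes x %d replicates), %.3g-%.3g mm\n",
    nrow(x$spheres), x$n_sizes, x$n_replicates,
    min(x$spheres$diameter), max(x$spheres$diameter)
  ))
  cat(sprintf("  container %.1f x %.1f x %.1f mm; background %.1f HU; seed %s\n",
              x$container[1], x$container[2], x$container[3],
              x$background_hu, format(x$seed)))
  invisible(x)
}

#' Serialize a phantom specification as a JSON manifest
#'
#' @param spec A `phantom_spec`.
#' @param path Output `.json` path.
#' @return `path` invisibly; `read_phantom_spec()` returns the `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(
    list(
      spheres = spec$spheres,
      background_hu = spec$background_hu,
      container = spec$container,
      n_sizes = spec$n_sizes,
      n_replicates = spec$n_replicates,
      seed = spec$seed
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      spheres = tibble::as_tibble(m$spheres),
      background_hu = m$background_hu,
      container = m$container,
      n_sizes = m$n_sizes,
      n_replicates = m$n_replicates,
      seed = m$seed
    ),
    class = "phantom_spec"
  )
}

#' Voxelize a phantom into a noiseless native CT volume
#'
#' Renders the analytic sphere geometry onto a voxel grid with correct
#' partial-volume behaviour: each voxel's HU is the occupancy-weighted mean
#' of sphere and background HU, where occupancy is the fraction of a
#' `supersample^3` subgrid of the voxel falling inside a sphere. Voxels whose
#' full extent is provably inside (or outside) a sphere are classified
#' analytically; only boundary-crossing voxels are supersampled. The output
#' is noiseless and deterministic.
#'
#' The grid is `matrix_size^2` pixels in-plane if `matrix_size` is given
#' (the container centered in the field of view), otherwise just large
#' enough to hold the container; axially it spans the container height.
#'
#' @param spec A `phantom_spec`.
#' @param pixel_size In-plane pixel size in mm.
#' @param slice_thickness Native slice thickness in mm, default 0.625.
#' @param supersample Subsamples per axis per voxel (default 8; 1 gives
#'   binary center-in-sphere occupancy).
#' @param matrix_size Optional in-plane matrix (e.g. 512); the in-plane
#'   field of view is then `matrix_size * pixel_size`.
#' @return A `ct_volume` at native resolution.
#' @export
voxelize <- function(spec, pixel_size, slice_thickness = 0.625,
                     supersample = 8, matrix_size = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (pixel_size <= 0 || slice_thickness <= 0) {
    stop("voxel dimensions must be positive", call. = FALSE)
  }
  if (supersample < 1) stop("`supersample` must be >= 1", call. = FALSE)
  supersample <- as.integer(supersample)

  if (is.null(matrix_size)) {
    nx <- ny <- as.integer(ceiling(spec$container[1] / pixel_size))
  } else {
    nx <- ny <- as.integer(matrix_size)
  }
  nz <- as.integer(ceiling(spec$container[3] / slice_thickness))
  if (as.double(nx) * ny * nz > 2^31 - 1) {
    stop("phantom larger than representable grid", call. = FALSE)
  }
  # container centered in-plane, aligned axially
  origin <- c((spec$container[1] - nx * pixel_size) / 2,
              (spec$container[2] - ny * pixel_size) / 2,
              0)
  if (nx * pixel_size < spec$container[1] - 1e-9 && nrow(spec$spheres)) {
    ok <- spec$spheres$x - spec$spheres$diameter / 2 >= origin[1] &
      spec$spheres$x + spec$spheres$diameter / 2 <= origin[1] + nx * pixel_size
    if (!all(ok)) stop("phantom larger than representable grid", call. = FALSE)
  }

  occ_hu <- array(0, c(nx, ny, nz)) # accumulated occupancy * (hu - bg)
  half_diag <- sqrt(2 * pixel_size^2 + slice_thickness^2) / 2
  sub <- (seq_len(supersample) - 0.5) / supersample
  sub_off <- expand.grid(ox = sub * pixel_size, oy = sub * pixel_size,
                         oz = sub * slice_thickness)

  for (i in seq_len(nrow(spec$spheres))) {
    s <- spec$spheres[i, ]
    r <- s$diameter / 2
    c_grid <- c(s$x, s$y, s$z) - origin
    ix <- max(1L, floor((c_grid[1] - r) / pixel_size)):min(nx, ceiling((c_grid[1] + r) / pixel_size) + 1L)
    iy <- max(1L, floor((c_grid[2] - r) / pixel_size)):min(ny, ceiling((c_grid[2] + r) / pixel_size) + 1L)
    iz <- max(1L, floor((c_grid[3] - r) / slice_thickness)):min(nz, ceiling((c_grid[3] + r) / slice_thickness) + 1L)
    dx2 <- ((ix - 0.5) * pixel_size - c_grid[1])^2
    dy2 <- ((iy - 0.5) * pixel_size - c_grid[2])^2
    dz2 <- ((iz - 0.5) * slice_thickness - c_grid[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    dist <- sqrt(d2)
    frac <- array(0, dim(d2))
    frac[dist <= r - half_diag] <- 1
    bnd <- which(abs(dist - r) < half_diag)
    if (length(bnd)) {
      bi <- arrayInd(bnd, dim(d2))
      # lower corners of boundary voxels, in grid mm
      x0 <- (ix[bi[, 1]] - 1) * pixel_size
      y0 <- (iy[bi[, 2]] - 1) * pixel_size
      z0 <- (iz[bi[, 3]] - 1) * slice_thickness
      r2 <- r^2
      chunk <- max(1L, as.integer(2e6 / nrow(sub_off)))
      fr <- numeric(length(bnd))
      for (start in seq(1L, length(bnd), by = chunk)) {
        sel <- start:min(start + chunk - 1L, length(bnd))
        dd <- outer(x0[sel], sub_off$ox, "+")
        dd <- (dd - c_grid[1])^2
        t2 <- outer(y0[sel], sub_off$oy, "+")
        dd <- dd + (t2 - c_grid[2])^2
        t2 <- outer(z0[sel], sub_off$oz, "+")
        dd <- dd + (t2 - c_grid[3])^2
        fr[seq_along(sel) + start - 1L] <- rowMeans(dd <= r2)
      }
      frac[bnd] <- fr
    }
    occ_hu[ix, iy, iz] <- occ_hu[ix, iy, iz] +
      frac * (s$hu - spec$background_hu)
  }

  ct_volume(
    occ_hu + spec$background_hu,
    pixel_size = pixel_size,
    slice_thickness = slice_thickness,
    origin = origin,
    provenance = sprintf(
      "voxelized: %d spheres, pixel %.4g mm, slice %.4g mm, supersample %d, seed %s",
      nrow(spec$spheres), pixel_size, slice_thickness, supersample,
      format(spec$seed)
    )
  )
}
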