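#' CT volume container
#'
#' A `ct_volume` holds a 3D grid of Hounsfield units (HU) together with its
#' voxel geometry: the in-plane pixel size (square pixels, so length `l` and
#' width `w` are one number), the slice thickness `t`, and the position in mm
#' of the lower corner of voxel `(0, 0, 0)`. Voxels span half-open boxes:
#' voxel `(i, j, k)` (0-based) covers
#' `[origin + c(i, j, k) * size, origin + c(i + 1, j + 1, k + 1) * size)`.
#'
#' @param data 3D numeric array of HU values.
#' @param pixel_size In-plane voxel edge length in mm (`l == w`).
#' @param slice_thickness Axial voxel extent in mm (`t`).
#' @param origin Length-3 numeric, mm position of the grid's lower corner.
#' @param provenance Character vector of free-text processing history.
#'
#' @return An object of class `ct_volume`.
#' @export
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 2)), pixel_size = 1, slice_thickness = 2)
#' voxel_volume(v)
ct_volume <- function(data, pixel_size, slice_thickness, origin = c(0, 0, 0),
                      provenance = character()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("grid dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (square pixels)",
         call. = FALSE)
  }
  if (!is.numeric(slice_thickness) || length(slice_thickness) != 1L ||
      slice_thickness <= 0) {
    stop("`slice_thickness` must be a single positive number", call. = FALSE)
  }
  stopifnot(length(origin) == 3L, is.numeric(origin))
  structure(
    list(
      data = data,
      pixel_size = as.numeric(pixel_size),
      slice_thickness = as.numeric(slice_thickness),
      origin = as.numeric(origin),
      provenance = as.character(provenance)
    ),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
    d[1], d[2], d[3], x$pixel_size, x$pixel_size, x$slice_thickness
  ))
  cat(sprintf("  HU range: [%.1f, %.1f]\n", min(x$data), max(x$data)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  }
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Voxel volume of a CT grid
#'
#' `l * w * t` in mm^3, the per-voxel factor in the voxel-counting volume
#' estimate `V_CT = N_V * l * w * t`.
#'
#' @param x A `ct_volume` or `labeled_volume`.
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(x) {
  x$pixel_size^2 * x$slice_thickness
}

with_provenance <- function(vol, note) {
  vol$provenance <- c(vol$provenance, note)
  vol
}

#' Read and write CT volumes
#'
#' Volumes are stored either as NIfTI (`.nii` / `.nii.gz`, via the RNifti
#' package, voxel sizes in the header) or as raw little-endian float32 with a
#' JSON sidecar carrying dimensions, voxel sizes, origin and provenance
#' (`.raw` plus `.json`).
#'
#' @param vol A `ct_volume`.
#' @param path Output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   anything else is written as raw + sidecar).
#' @return `write_ct_volume()` returns `path` invisibly; `read_ct_volume()`
#'   returns a `ct_volume`.
#' @export
write_ct_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- c(vol$pixel_size, vol$pixel_size,
                             vol$slice_thickness)
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
    sidecar <- sub("\\.[^.]+$", ".json", path)
    if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
    jsonlite::write_json(
      list(
        dim = dim(vol$data),
        pixel_size = vol$pixel_size,
        slice_thickness = vol$slice_thickness,
        origin = vol$origin,
        dtype = "float32le",
        provenance = vol$provenance
      ),
      sidecar, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_ct_volume
#' @export
read_ct_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    arr <- array(as.numeric(img), dim = dim(img))
    if (abs(pd[1] - pd[2]) > 1e-6) {
      stop("non-square pixels in NIfTI header", call. = FALSE)
    }
    ct_volume(arr, pixel_size = pd[1], slice_thickness = pd[3],
              provenance = sprintf("read from %s", basename(path)))
  } else {
    sidecar <- sub("\\.[^.]+$", ".json", path)
    if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    n <- prod(meta$dim)
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
    ct_volume(array(vals, dim = meta$dim),
              pixel_size = meta$pixel_size,
              slice_thickness = meta$slice_thickness,
              origin = meta$origin,
              provenance = meta$provenance)
  }
}
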