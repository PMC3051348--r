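#' Reconstruction kernel models
#'
#' A kernel model is a two-parameter stand-in for a CT reconstruction
#' filter: an in-plane Gaussian point-spread function width (`psf_sigma_xy`,
#' mm) and an additive noise level (`noise_sigma`, HU). The shipped defaults
#' reproduce the qualitative ordering of clinical kernels: the lung kernel
#' is the sharpest but noisiest of the sharp kernels' error profiles, the
#' standard kernel the smoothest and least noisy, bone in between on
#' sharpness but the noisiest overall.
#'
#' @param name One of `"standard"`, `"lung"`, `"bone"`.
#' @param psf_sigma_xy Optional override of the PSF width in mm (>= 0).
#' @param noise_sigma Optional override of the noise standard deviation in
#'   HU (>= 0).
#' @return A `ct_kernel` list with fields `name`, `psf_sigma_xy`,
#'   `noise_sigma`.
#' @export
#' @examples
#' ct_kernel("lung")
#' ct_kernel("standard", noise_sigma = 0) # noiseless smoothing only
ct_kernel <- function(name = c("standard", "lung", "bone"),
                      psf_sigma_xy = NULL, noise_sigma = NULL) {
  name <- match.arg(name)
  defaults <- kernel_defaults()
  row <- defaults[defaults$name == name, ]
  psf <- if (is.null(psf_sigma_xy)) row$psf_sigma_xy else psf_sigma_xy
  ns <- if (is.null(noise_sigma)) row$noise_sigma else noise_sigma
  if (psf < 0 || ns < 0) stop("kernel parameters must be >= 0", call. = FALSE)
  structure(list(name = name, psf_sigma_xy = psf, noise_sigma = ns),
            class = "ct_kernel")
}

#' @rdname ct_kernel
#' @export
kernel_defaults <- function() {
  tibble::tibble(
    name = c("standard", "lung", "bone"),
    psf_sigma_xy = c(0.8, 0.3, 0.5),
    noise_sigma = c(4, 8, 10)
  )
}

#' @export
print.ct_kernel <- function(x, ...) {
  cat(sprintf("<ct_kernel> %s: psf sigma %.2f mm, noise sigma %.1f HU\n",
              x$name, x$psf_sigma_xy, x$noise_sigma))
  invisible(x)
}

# 1D Gaussian convolution matrix with replicated (clamped) boundaries.
gauss_band_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  w <- w / sum(w)
  W <- matrix(0, n, n)
  for (k in seq_along(w)) {
    idx <- pmin(pmax(seq_len(n) + (k - r - 1L), 1L), n)
    W[cbind(seq_len(n), idx)] <- W[cbind(seq_len(n), idx)] + w[k]
  }
  W
}

# Separable in-plane Gaussian blur of a 3D array, sigma in voxels.
blur_xy <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  d <- dim(x)
  Wx <- gauss_band_matrix(d[1], sigma_vox)
  dim(x) <- c(d[1], d[2] * d[3])
  x <- Wx %*% x
  dim(x) <- d
  x <- aperm(x, c(2, 1, 3))
  Wy <- gauss_band_matrix(d[2], sigma_vox)
  dim(x) <- c(d[2], d[1] * d[3])
  x <- Wy %*% x
  dim(x) <- c(d[2], d[1], d[3])
  x <- aperm(x, c(2, 1, 3))
  array(x, d)
}

#' Apply a reconstruction kernel model to a native volume
#'
#' In-plane Gaussian blur of width `psf_sigma_xy` followed by additive
#' zero-mean Gaussian noise of standard deviation `noise_sigma`, seeded for
#' reproducibility. Blur acts within slices only; the axial response is
#' modelled separately by slice averaging.
#'
#' @param volume A `ct_volume` at native resolution.
#' @param kernel A `ct_kernel`.
#' @param seed Noise seed; if `NULL` the current RNG stream is used.
#' @return A blurred, noisy `ct_volume` with updated provenance.
#' @export
apply_kernel <- function(volume, kernel, seed = NULL) {
  stopifnot(inherits(volume, "ct_volume"), inherits(kernel, "ct_kernel"))
  sigma_vox <- kernel$psf_sigma_xy / volume$pixel_size
  out <- volume
  out$data <- blur_xy(volume$data, sigma_vox)
  if (kernel$noise_sigma > 0) {
    add_noise <- function() {
      out$data + array(stats::rnorm(length(out$data), 0, kernel$noise_sigma),
                       dim(out$data))
    }
    out$data <- if (is.null(seed)) add_noise() else {
      withr::with_seed(seed, add_noise())
    }
  }
  with_provenance(out, sprintf(
    "kernel %s: psf %.3g mm, noise %.3g HU, seed %s",
    kernel$name, kernel$psf_sigma_xy, kernel$noise_sigma,
    if (is.null(seed)) "NA" else format(seed)
  ))
}

#' Synthesize thicker slices by averaging thin slices
#'
#' Each output slice is the weighted mean of `slices_per_thick` consecutive
#' thin slices; when `slices_per_thick` is fractional, the boundary slices
#' are weighted by their fractional coverage of the output window (linear
#' interpolation of partial slices). The first `phase_skip` thin slices are
#' consumed before the first full window, shifting the phase of the output
#' grid relative to the input; only full windows are emitted. Output slice
#' thickness is `slices_per_thick` times the input thickness.
#'
#' @param volume A `ct_volume`.
#' @param slices_per_thick Number of thin slices per output slice (>= 1,
#'   may be fractional, e.g. 9.625).
#' @param phase_skip Number of leading thin slices to consume first (>= 0,
#'   may be fractional).
#' @return A `ct_volume` with fewer, thicker slices.
#' @export
#' @examples
#' v <- ct_volume(array(rep(0:7, each = 1), c(1, 1, 8)), 1, 1)
#' as.numeric(average_slices(v, 4)$data) # 1.5, 5.5
average_slices <- function(volume, slices_per_thick, phase_skip = 0) {
  stopifnot(inherits(volume, "ct_volume"))
  if (slices_per_thick < 1) {
    stop("`slices_per_thick` must be >= 1", call. = FALSE)
  }
  if (phase_skip < 0) stop("`phase_skip` must be >= 0", call. = FALSE)
  d <- dim(volume$data)
  nz <- d[3]
  n_out <- floor((nz - phase_skip) / slices_per_thick + 1e-9)
  if (n_out < 1) {
    stop("not enough thin slices for one thick slice", call. = FALSE)
  }

  int_factor <- abs(slices_per_thick - round(slices_per_thick)) < 1e-9 &&
    abs(phase_skip - round(phase_skip)) < 1e-9
  if (int_factor) {
    spt <- as.integer(round(slices_per_thick))
    skip <- as.integer(round(phase_skip))
    acc <- array(0, c(d[1], d[2], n_out))
    for (k in seq_len(spt)) {
      acc <- acc + volume$data[, , skip + seq(k, n_out * spt, by = spt),
                               drop = FALSE]
    }
    out_data <- acc / spt
  } else {
    # weight of thin slice i in output j = overlap of [i-1, i) with the
    # window [phase_skip + (j-1)*spt, phase_skip + j*spt), normalized
    W <- matrix(0, nz, n_out)
    for (j in seq_len(n_out)) {
      lo <- phase_skip + (j - 1) * slices_per_thick
      hi <- phase_skip + j * slices_per_thick
      i <- seq_len(nz)
      ov <- pmax(0, pmin(i, hi) - pmax(i - 1, lo))
      W[, j] <- ov / slices_per_thick
    }
    flat <- volume$data
    dim(flat) <- c(d[1] * d[2], nz)
    out_data <- array(flat %*% W, c(d[1], d[2], n_out))
  }

  new_t <- slices_per_thick * volume$slice_thickness
  out <- ct_volume(
    out_data,
    pixel_size = volume$pixel_size,
    slice_thickness = new_t,
    origin = volume$origin + c(0, 0, phase_skip * volume$slice_thickness),
    provenance = volume$provenance
  )
  with_provenance(out, sprintf(
    "averaged %.4g slices/thick (phase skip %.4g) -> t = %.4g mm",
    slices_per_thick, phase_skip, new_t
  ))
}

#' Mean absolute difference between two congruent volumes
#'
#' The alignment metric for the slice-averaging phase search: the mean over
#' all voxels of |a - b| in HU. (A signed mean would be near zero even for
#' misaligned stacks, so the magnitude is what is minimized.)
#'
#' @param a,b `ct_volume`s on congruent grids.
#' @return Mean absolute difference in HU.
#' @export
subtraction_metric <- function(a, b) {
  stopifnot(inherits(a, "ct_volume"), inherits(b, "ct_volume"))
  if (!identical(dim(a$data), dim(b$data))) {
    stop("volumes are not congruent", call. = FALSE)
  }
  mean(abs(a$data - b$data))
}

#' Search the slice-averaging phase that best reproduces a thick stack
#'
#' Averages the thin stack into virtual thick slices for every candidate
#' phase skip, compares each candidate to the true thick stack with
#' [subtraction_metric()] (over the leading slices both stacks share), and
#' returns the plan with the smallest metric. Ties break toward the smaller
#' phase skip.
#'
#' @param thin Thin-slice `ct_volume`.
#' @param true_thick Reference thick-slice `ct_volume` (same in-plane grid).
#' @param slices_per_thick Thin slices per thick slice (may be fractional).
#' @param candidates Candidate phase skips, default `0:9`.
#' @return A `slice_plan`: list with `slices_per_thick`, `phase_skip`,
#'   `metric`, and a `search` tibble of all candidates.
#' @export
phase_shift_search <- function(thin, true_thick, slices_per_thick,
                               candidates = 0:9) {
  stopifnot(inherits(thin, "ct_volume"), inherits(true_thick, "ct_volume"))
  if (length(candidates) == 0) {
    stop("empty candidate set", call. = FALSE)
  }
  if (!identical(dim(thin$data)[1:2], dim(true_thick$data)[1:2])) {
    stop("in-plane grids differ", call. = FALSE)
  }
  candidates <- sort(candidates)
  metrics <- purrr::map_dbl(candidates, function(s) {
    avg <- average_slices(thin, slices_per_thick, phase_skip = s)
    k <- min(dim(avg$data)[3], dim(true_thick$data)[3])
    mean(abs(avg$data[, , seq_len(k), drop = FALSE] -
               true_thick$data[, , seq_len(k), drop = FALSE]))
  })
  best <- which.min(metrics) # first minimum = smallest candidate on ties
  structure(
    list(
      slices_per_thick = slices_per_thick,
      phase_skip = candidates[best],
      metric = metrics[best],
      search = tibble::tibble(phase_skip = candidates, metric = metrics)
    ),
    class = "slice_plan"
  )
}

#' @export
print.slice_plan <- function(x, ...) {
  cat(sprintf(
    "<slice_plan> %.4g slices/thick, phase skip %.4g (metric %.4g HU)\n",
    x$slices_per_thick, x$phase_skip, x$metric
  ))
  invisible(x)
}
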