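#' Experiment configuration
#'
#' Bundles every setting of the full phantom experiment: phantom geometry,
#' the reconstruction grid (fields of view, kernels, slice thicknesses,
#' matrix size), segmentation parameters, optional threshold calibration,
#' and the master seed. The shipped defaults encode the reference study
#' design: 55 spheres (11 inch-fraction diameters x 5 replicates) in a
#' 15.2 x 15.2 x 40.0 cm gelatin container, 0.625 mm native slices, a
#' 512 matrix at 20/30/40 cm FOV, standard/lung/bone kernels, thicknesses
#' 0.625/1.25/2.5/5 mm, a 93 HU global threshold and a 1.68 mm^3 minimum
#' component volume.
#'
#' @param diameters Sphere diameters, mm.
#' @param n_replicates Replicates per diameter.
#' @param container Container dims `c(x, y, z)`, mm.
#' @param background_hu,sphere_hu Material attenuations, HU.
#' @param fov_cm Fields of view, cm.
#' @param kernels Kernel names.
#' @param thicknesses Reconstructed slice thicknesses, mm (multiples of
#'   `native_thickness`).
#' @param native_thickness Native slice thickness, mm.
#' @param matrix_size Reconstruction matrix.
#' @param supersample Voxelization supersampling per axis.
#' @param threshold Segmentation threshold, HU.
#' @param min_volume Minimum component volume, mm^3 (`NULL` = derive from
#'   the diameter series via [default_min_volume()]).
#' @param min_neighbors Minimum per-voxel neighbor count.
#' @param connectivity Component adjacency.
#' @param calibrate If `TRUE`, derive the threshold by running
#'   [calibrate_threshold()] on `calibration_cases` before the main grid.
#' @param calibration_thresholds Sweep grid for calibration, HU.
#' @param calibration_cases Data frame of calibration conditions (`fov`,
#'   `kernel`, `slice_thickness`); default the smoothest, noisiest, and an
#'   intermediate reconstruction.
#' @param kernel_models Data frame overriding [kernel_defaults()].
#' @param seed Master seed (layout and noise seeds derive from it).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(diameters = inch_fraction_diameters(),
                              n_replicates = 5,
                              container = c(152, 152, 400),
                              background_hu = 37.6,
                              sphere_hu = 118.2,
                              fov_cm = c(20, 30, 40),
                              kernels = c("standard", "lung", "bone"),
                              thicknesses = c(0.625, 1.25, 2.5, 5),
                              native_thickness = 0.625,
                              matrix_size = 512,
                              supersample = 8,
                              threshold = 93,
                              min_volume = NULL,
                              min_neighbors = 3,
                              connectivity = "full-26",
                              calibrate = FALSE,
                              calibration_thresholds = c(90, 100, 110),
                              calibration_cases = NULL,
                              kernel_models = kernel_defaults(),
                              seed = 2010L) {
  if (!length(fov_cm) || !length(kernels) || !length(thicknesses) ||
      !length(diameters)) {
    stop("config lists must be non-empty", call. = FALSE)
  }
  if (is.null(min_volume)) min_volume <- default_min_volume(diameters)
  if (is.null(calibration_cases)) {
    # smoothest, noisiest, and an intermediate reconstruction
    calibration_cases <- tibble::tibble(
      fov = c(min(fov_cm), max(fov_cm),
              fov_cm[ceiling(length(fov_cm) / 2)]),
      kernel = c("standard", "bone", "lung"),
      slice_thickness = c(min(thicknesses), max(thicknesses),
                          thicknesses[ceiling(length(thicknesses) / 2)])
    )
    calibration_cases <- dplyr::distinct(calibration_cases[
      calibration_cases$kernel %in% kernels, , drop = FALSE])
  }
  cfg <- structure(
    list(
      diameters = diameters, n_replicates = n_replicates,
      container = container, background_hu = background_hu,
      sphere_hu = sphere_hu, fov_cm = fov_cm, kernels = kernels,
      thicknesses = thicknesses, native_thickness = native_thickness,
      matrix_size = matrix_size, supersample = supersample,
      threshold = threshold, min_volume = min_volume,
      min_neighbors = min_neighbors, connectivity = connectivity,
      calibrate = calibrate,
      calibration_thresholds = calibration_thresholds,
      calibration_cases = calibration_cases,
      kernel_models = tibble::as_tibble(kernel_models),
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
  validate_experiment_config(cfg)
  cfg
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @export
validate_experiment_config <- function(config) {
  with(config, {
    if (!length(fov_cm) || !length(kernels) || !length(thicknesses) ||
        !length(diameters)) {
      stop("config lists must be non-empty", call. = FALSE)
    }
    ratio <- thicknesses / native_thickness
    if (any(abs(ratio - round(ratio)) > 1e-9) || any(ratio < 1 - 1e-9)) {
      stop("thicknesses must be integer multiples of the native thickness",
           call. = FALSE)
    }
    if (!all(kernels %in% kernel_models$name)) {
      stop("unknown kernel name in config", call. = FALSE)
    }
    if (matrix_size < 8) stop("matrix_size too small", call. = FALSE)
  })
  invisible(config)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %d FOV x %d kernel x %d thickness = %d conditions\n",
    length(x$fov_cm), length(x$kernels), length(x$thicknesses),
    length(x$fov_cm) * length(x$kernels) * length(x$thicknesses)
  ))
  cat(sprintf("  %d spheres, matrix %d, threshold %.4g HU, seed %d\n",
              length(x$diameters) * x$n_replicates, x$matrix_size,
              x$threshold, x$seed))
  invisible(x)
}

#' Read or write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_experiment_config()` returns an `experiment_config`;
#'   `write_experiment_config()` returns `path` invisibly.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$kernel_models)) {
    args$kernel_models <- dplyr::bind_rows(y$kernel_models)
  }
  if (!is.null(y$calibration_cases)) {
    args$calibration_cases <- dplyr::bind_rows(y$calibration_cases)
  }
  do.call(experiment_config, args)
}

#' @rdname read_experiment_config
#' @param config An `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  y <- unclass(config)
  y$kernel_models <- purrr::transpose(as.list(config$kernel_models))
  y$calibration_cases <- purrr::transpose(as.list(config$calibration_cases))
  yaml::write_yaml(y, path)
  invisible(path)
}

# deterministic per-condition noise seed below 2^31
condition_seed <- function(seed, i_fov, i_kernel) {
  (seed + 7919L * i_fov + 104729L * i_kernel) %% 2147483647L
}

#' Run the full phantom experiment
#'
#' Simulates the phantom once, then for every field of view voxelizes a
#' native-resolution volume, applies each kernel model (seeded noise),
#' synthesizes each slice thickness by averaging, segments with the global
#' threshold, measures all components, matches them to the ground-truth
#' spheres, and assembles accuracy and precision statistics. The smallest
#' size class is excluded from the analysis tables (its segmentation is
#' unreliable); it remains in the raw measurement table.
#'
#' Deterministic given `config$seed`. With `out_dir` set, writes tidy CSVs
#' (measurements, error summary, slopes, COV table, minimum-diameter
#' table), the phantom manifest, the resolved config, and a run log with a
#' config hash.
#'
#' @param config An `experiment_config`.
#' @param out_dir Optional output directory.
#' @param verbose Log per-condition progress and timing.
#' @return A `ct_report`: list with `config`, `config_hash`, `phantom`,
#'   `measurements` (all spheres), `analysis` (analyzed sizes only),
#'   `error_summary`, `slopes`, `cov_table`, `min_diameter`, `anova`,
#'   `calibration` (if enabled), and `conditions`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           verbose = TRUE) {
  validate_experiment_config(config)
  cfg_hash <- rlang::hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()

  spec <- build_phantom_spec(
    diameters = config$diameters, n_replicates = config$n_replicates,
    container = config$container, background_hu = config$background_hu,
    sphere_hu = config$sphere_hu, seed = config$seed
  )
  params <- seg_params(
    threshold = config$threshold, min_volume = config$min_volume,
    min_neighbors = config$min_neighbors, connectivity = config$connectivity
  )
  km <- config$kernel_models
  get_kernel <- function(name) {
    row <- km[km$name == name, ]
    ct_kernel(name, psf_sigma_xy = row$psf_sigma_xy,
              noise_sigma = row$noise_sigma)
  }

  natives <- list() # per-FOV noiseless native volumes, built lazily
  native_for <- function(fov) {
    key <- as.character(fov)
    if (is.null(natives[[key]])) {
      px <- pixel_size(fov, config$matrix_size)
      say("voxelizing native volume: FOV %g cm (pixel %.3f mm)", fov, px)
      natives[[key]] <<- voxelize(
        spec, pixel_size = px,
        slice_thickness = config$native_thickness,
        supersample = config$supersample,
        matrix_size = config$matrix_size
      )
    }
    natives[[key]]
  }

  calibration <- NULL
  if (isTRUE(config$calibrate)) {
    say("calibrating threshold on %d case(s)", nrow(config$calibration_cases))
    vols <- purrr::pmap(config$calibration_cases, function(fov, kernel,
                                                           slice_thickness) {
      i_f <- match(fov, config$fov_cm)
      i_k <- match(kernel, config$kernels)
      v <- apply_kernel(native_for(fov), get_kernel(kernel),
                        seed = condition_seed(config$seed, i_f, i_k))
      average_slices(v, slice_thickness / config$native_thickness)
    })
    names(vols) <- sprintf("%gcm_%s_%gmm", config$calibration_cases$fov,
                           config$calibration_cases$kernel,
                           config$calibration_cases$slice_thickness)
    calibration <- calibrate_threshold(
      vols, spec, thresholds = config$calibration_thresholds, params = params
    )
    params$threshold <- calibration$global_threshold
    say("calibrated global threshold: %g HU", params$threshold)
  }

  measurements <- list()
  conditions <- list()
  for (i_f in seq_along(config$fov_cm)) {
    fov <- config$fov_cm[i_f]
    native <- native_for(fov)
    for (i_k in seq_along(config$kernels)) {
      kname <- config$kernels[i_k]
      t_k <- Sys.time()
      vol_k <- apply_kernel(native, get_kernel(kname),
                            seed = condition_seed(config$seed, i_f, i_k))
      for (thick in config$thicknesses) {
        t_c <- Sys.time()
        vol_t <- average_slices(vol_k, thick / config$native_thickness)
        labeled <- segment_volume(vol_t, params)
        comps <- measure_components(labeled)
        meas <- match_to_spheres(comps, spec)
        meas <- dplyr::mutate(meas, fov = fov, kernel = kname,
                              slice_thickness = thick, .before = 1)
        key <- sprintf("%g_%s_%g", fov, kname, thick)
        measurements[[key]] <- meas
        conditions[[key]] <- tibble::tibble(
          fov = fov, kernel = kname, slice_thickness = thick,
          n_components = labeled$n_objects,
          n_detected = sum(meas$detected),
          seconds = as.numeric(difftime(Sys.time(), t_c, units = "secs"))
        )
        say("condition FOV %g cm / %s / %.3g mm: %d objects, %d/%d detected (%.1fs)",
            fov, kname, thick, labeled$n_objects, sum(meas$detected),
            nrow(meas), conditions[[key]]$seconds)
      }
      rm(vol_k)
    }
    natives[[as.character(fov)]] <- NULL # free before the next FOV
    gc(verbose = FALSE)
  }

  measurements <- dplyr::bind_rows(measurements)
  analysis <- measurements[
    measurements$diameter > min(config$diameters) + 1e-9 |
      length(config$diameters) == 1, ]

  det <- analysis[analysis$detected, ]
  maybe_anova <- function(group) {
    tryCatch(anova_oneway_bonferroni(det, "percent_error", group),
             error = function(e) NULL) # skipped for single-level factors
  }
  anova <- list(
    sphere_size = maybe_anova("diameter"),
    slice_thickness = maybe_anova("slice_thickness"),
    fov = maybe_anova("fov"),
    kernel = maybe_anova("kernel")
  )

  report <- structure(
    list(
      config = config, config_hash = cfg_hash, phantom = spec,
      measurements = measurements, analysis = analysis,
      error_summary = error_summary(analysis),
      slopes = accuracy_slopes(analysis),
      cov_table = cov_table(analysis),
      min_diameter = min_diameter_table(analysis),
      anova = anova,
      calibration = calibration,
      conditions = dplyr::bind_rows(conditions),
      elapsed = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
    ),
    class = "ct_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(report$measurements, "measurements.csv")
  wr(report$error_summary, "error_summary.csv")
  wr(report$slopes, "slopes.csv")
  wr(report$cov_table, "cov_table.csv")
  wr(report$min_diameter, "min_diameter_table.csv")
  write_phantom_spec(report$phantom, file.path(out_dir, "phantom.json"))
  write_experiment_config(report$config, file.path(out_dir, "config.yaml"))
  if (!is.null(report$calibration)) {
    wr(report$calibration$points, "calibration_points.csv")
    jsonlite::write_json(
      list(cases = report$calibration$cases,
           global_threshold = report$calibration$global_threshold),
      file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA
    )
  }
  writeLines(
    c(sprintf("config_hash: %s", report$config_hash),
      sprintf("conditions: %d", nrow(report$conditions)),
      sprintf("elapsed_seconds: %.1f", report$elapsed)),
    file.path(out_dir, "run_log.txt")
  )
  invisible(out_dir)
}

#' Build a small test fixture
#'
#' `"tiny"` is a 3-sphere phantom on a coarse isotropic grid (built in
#' well under a second); `"small"` is the full 55-sphere phantom at a
#' reduced matrix. Both return the phantom spec and a noiseless native
#' volume; with `dir` set, the manifest (JSON) and volume (NIfTI) are also
#' written to disk.
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed Layout seed.
#' @param dir Optional output directory.
#' @return List with `spec` and `volume`.
#' @export
make_fixture <- function(size = c("tiny", "small"), seed = 1, dir = NULL) {
  size <- match.arg(size)
  if (size == "tiny") {
    spec <- build_phantom_spec(
      diameters = c(6.35, 9.525, 12.7), n_replicates = 1,
      container = c(64, 64, 40), seed = seed
    )
    volume <- voxelize(spec, pixel_size = 1, slice_thickness = 1,
                       supersample = 4)
  } else {
    spec <- build_phantom_spec(seed = seed)
    volume <- voxelize(spec, pixel_size = pixel_size(20, 128),
                       slice_thickness = 2.5, supersample = 4,
                       matrix_size = 128)
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_phantom_spec(spec, file.path(dir, sprintf("%s_phantom.json", size)))
    write_ct_volume(volume, file.path(dir, sprintf("%s_volume.nii.gz", size)))
  }
  list(spec = spec, volume = volume)
}
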