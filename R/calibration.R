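#' Sweep segmentation thresholds and summarize percent error
#'
#' For each candidate threshold: segment, measure, match to ground truth,
#' average percent error over replicates within each size class (detected
#' only), and reduce to the minimum / median / maximum across size classes.
#' A threshold detecting no spheres yields a point flagged `"empty"`; a
#' threshold that merges the phantom into one giant component (e.g. below
#' the background HU) is flagged `"degenerate"`. Flagged points carry `NA`
#' summaries and are excluded from the line fit in [optimal_threshold()].
#'
#' @param volume A `ct_volume`.
#' @param spec The `phantom_spec` it was generated from.
#' @param thresholds Candidate thresholds in HU, default `c(90, 100, 110)`.
#' @param params Base `seg_params` (its `threshold` is replaced per sweep
#'   point).
#' @param exclude_smallest Drop the smallest size class before summarizing,
#'   default `TRUE` (mirrors its exclusion from the main analysis).
#' @return A tibble with `threshold`, `min_error`, `median_error`,
#'   `max_error`, `n_sizes_detected`, `status`.
#' @export
sweep_thresholds <- function(volume, spec, thresholds = c(90, 100, 110),
                             params = seg_params(),
                             exclude_smallest = TRUE) {
  if (length(thresholds) == 0) stop("`thresholds` is empty", call. = FALSE)
  v_max <- max(sphere_true_volume(spec$spheres$diameter))
  purrr::map_dfr(sort(thresholds), function(thr) {
    p <- params
    p$threshold <- thr
    labeled <- segment_volume(volume, p)
    comps <- measure_components(labeled)
    meas <- match_to_spheres(comps, spec)
    if (exclude_smallest && length(unique(meas$diameter)) > 1) {
      meas <- meas[meas$diameter > min(meas$diameter) + 1e-9, ]
    }
    degenerate <- nrow(comps) > 0 && max(comps$v_ct) > 2 * v_max
    by_size <- dplyr::summarise(
      dplyr::group_by(meas[meas$detected, ], .data$diameter),
      err = mean(.data$percent_error),
      .groups = "drop"
    )
    if (degenerate) {
      tibble::tibble(threshold = thr, min_error = NA_real_,
                     median_error = NA_real_, max_error = NA_real_,
                     n_sizes_detected = nrow(by_size), status = "degenerate")
    } else if (nrow(by_size) == 0) {
      tibble::tibble(threshold = thr, min_error = NA_real_,
                     median_error = NA_real_, max_error = NA_real_,
                     n_sizes_detected = 0L, status = "empty")
    } else {
      tibble::tibble(
        threshold = thr,
        min_error = min(by_size$err),
        median_error = stats::median(by_size$err),
        max_error = max(by_size$err),
        n_sizes_detected = nrow(by_size),
        status = "ok"
      )
    }
  })
}

#' Optimal threshold from a median-error sweep
#'
#' Ordinary least-squares line of median percent error against threshold;
#' the threshold at which the fitted line crosses zero error
#' (`-intercept / slope`) is the optimal threshold. Invariant to the order
#' of the points.
#'
#' @param points Tibble from [sweep_thresholds()] (flagged points are
#'   dropped).
#' @return Optimal threshold in HU.
#' @export
#' @examples
#' pts <- tibble::tibble(threshold = c(90, 110), median_error = c(2, -2))
#' optimal_threshold(pts) # 100
optimal_threshold <- function(points) {
  if ("status" %in% names(points)) points <- points[points$status == "ok", ]
  points <- points[!is.na(points$median_error), ]
  if (nrow(points) < 2 || length(unique(points$threshold)) < 2) {
    stop("need >= 2 non-degenerate sweep points with distinct thresholds",
         call. = FALSE)
  }
  fit <- stats::lm(median_error ~ threshold, data = points)
  slope <- stats::coef(fit)[["threshold"]]
  if (abs(slope) < 1e-12) {
    stop("median error does not vary with threshold: no zero crossing",
         call. = FALSE)
  }
  -stats::coef(fit)[["(Intercept)"]] / slope
}

#' Global threshold from per-case optima
#'
#' Arithmetic mean of the per-case optimal thresholds, rounded to the
#' nearest integer HU.
#'
#' @param case_optima Numeric vector of per-case optimal thresholds, HU.
#' @return Global threshold, integer-valued HU.
#' @export
#' @examples
#' global_threshold(c(101, 78, 101)) # 93
global_threshold <- function(case_optima) {
  if (length(case_optima) == 0) stop("empty optima list", call. = FALSE)
  round(mean(case_optima))
}

#' Calibrate the global segmentation threshold on a set of cases
#'
#' Runs [sweep_thresholds()] and [optimal_threshold()] on each calibration
#' volume (typically a smoothest, a noisiest and an intermediate
#' reconstruction) and averages the per-case optima into a global
#' threshold.
#'
#' @param volumes Named list of `ct_volume`s.
#' @param spec The shared `phantom_spec`.
#' @param thresholds Sweep grid in HU.
#' @param params Base `seg_params`.
#' @param exclude_smallest Passed to [sweep_thresholds()].
#' @return A `threshold_calibration`: list with `points` (all sweep points,
#'   with a `case` column), `cases` (per-case optima), and
#'   `global_threshold`.
#' @export
calibrate_threshold <- function(volumes, spec, thresholds = c(90, 100, 110),
                                params = seg_params(),
                                exclude_smallest = TRUE) {
  stopifnot(length(volumes) >= 1)
  if (is.null(names(volumes))) {
    names(volumes) <- paste0("case", seq_along(volumes))
  }
  points <- purrr::imap_dfr(volumes, function(v, nm) {
    dplyr::mutate(
      sweep_thresholds(v, spec, thresholds, params, exclude_smallest),
      case = nm, .before = 1
    )
  })
  cases <- purrr::imap_dfr(split(points, points$case)[unique(points$case)],
                           function(pts, nm) {
    tibble::tibble(case = nm, optimal_threshold = optimal_threshold(pts))
  })
  structure(
    list(points = points, cases = cases,
         global_threshold = global_threshold(cases$optimal_threshold)),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat("<threshold_calibration>\n")
  for (i in seq_len(nrow(x$cases))) {
    cat(sprintf("  %s: optimal %.1f HU\n", x$cases$case[i],
                x$cases$optimal_threshold[i]))
  }
  cat(sprintf("  global threshold: %d HU\n", x$global_threshold))
  invisible(x)
}
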