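#' @export
print.ct_report <- function(x, ...) {
  cat("<ct_report>\n")
  cat(sprintf("  %d conditions, %d measurement slots (%d analyzed sizes)\n",
              nrow(x$conditions), nrow(x$analysis),
              length(unique(x$analysis$diameter))))
  cat(sprintf("  detected: %d/%d (%.1f%%)\n", sum(x$analysis$detected),
              nrow(x$analysis), 100 * mean(x$analysis$detected)))
  cat(sprintf("  accuracy slope range: %.3f - %.3f\n",
              min(x$slopes$slope), max(x$slopes$slope)))
  cat(sprintf("  config hash: %s\n", x$config_hash))
  invisible(x)
}

#' Tidy a phantom experiment report
#'
#' `tidy()` returns the per-sphere measurement table of the analyzed size
#' classes (one row per sphere x condition); `glance()` returns a one-row
#' overall summary.
#'
#' @param x A `ct_report` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ct_report <- function(x, ...) {
  tibble::as_tibble(x$analysis)
}

#' @rdname tidy.ct_report
#' @export
glance.ct_report <- function(x, ...) {
  det <- x$analysis[x$analysis$detected, ]
  tibble::tibble(
    n_conditions = nrow(x$conditions),
    n_spheres = nrow(x$phantom$spheres),
    n_measurement_slots = nrow(x$analysis),
    detection_rate = mean(x$analysis$detected),
    slope_min = min(x$slopes$slope),
    slope_max = max(x$slopes$slope),
    mean_error = mean(det$percent_error),
    mean_abs_error = mean(abs(det$percent_error))
  )
}

#' Plot a phantom experiment report
#'
#' `type = "error_profile"` plots mean percent error against sphere
#' diameter (one curve per slice thickness, faceted by FOV x kernel, error
#' bars = +/- 1 standard error over replicates). `type = "slopes"` plots
#' the origin-forced accuracy slope against slice thickness, colored by
#' kernel, one line per FOV, with the unity line as reference.
#'
#' @param object A `ct_report`.
#' @param type `"error_profile"` or `"slopes"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ct_report <- function(object, type = c("error_profile", "slopes"),
                               ...) {
  type <- match.arg(type)
  if (type == "error_profile") {
    es <- object$error_summary
    es <- es[!is.na(es$mean_error), ]
    ggplot2::ggplot(es, ggplot2::aes(
      x = .data$diameter, y = .data$mean_error,
      colour = factor(.data$slice_thickness),
      group = factor(.data$slice_thickness)
    )) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean_error - .data$se_error,
        ymax = .data$mean_error + .data$se_error
      ), width = 0.3, na.rm = TRUE) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::facet_grid(
        rows = ggplot2::vars(.data$fov),
        cols = ggplot2::vars(.data$kernel),
        labeller = ggplot2::label_both
      ) +
      ggplot2::labs(x = "sphere diameter (mm)",
                    y = "mean percent error in volume (%)",
                    colour = "slice thickness (mm)") +
      ggplot2::theme_bw()
  } else {
    sl <- object$slopes
    ggplot2::ggplot(sl, ggplot2::aes(
      x = .data$slice_thickness, y = .data$slope,
      colour = .data$kernel,
      group = interaction(.data$kernel, .data$fov)
    )) +
      ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
      ggplot2::geom_line(alpha = 0.7) +
      ggplot2::geom_point(ggplot2::aes(shape = factor(.data$fov))) +
      ggplot2::labs(x = "slice thickness (mm)",
                    y = "measured / true volume slope",
                    colour = "kernel", shape = "FOV (cm)") +
      ggplot2::theme_bw()
  }
}

#' @export
autoplot.threshold_calibration <- function(object, ...) {
  pts <- object$points[object$points$status == "ok", ]
  long <- tidyr::pivot_longer(
    pts, c("min_error", "median_error", "max_error"),
    names_to = "stat", values_to = "error"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$error,
                                     colour = .data$stat)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_smooth(
      data = long[long$stat == "median_error", ],
      method = "lm", formula = y ~ x, se = FALSE,
      colour = "grey30", linewidth = 0.4
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$case)) +
    ggplot2::geom_vline(xintercept = object$cases$optimal_threshold,
                        linetype = 3) +
    ggplot2::labs(x = "threshold (HU)", y = "percent error across sizes",
                  colour = NULL) +
    ggplot2::theme_bw()
}
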