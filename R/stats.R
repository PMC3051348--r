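#' Coefficient of variation, percent
#'
#' Sample (n - 1) standard deviation divided by the mean, times 100.
#'
#' @param values Numeric vector (>= 2 values, nonzero mean).
#' @return COV in percent.
#' @export
#' @examples
#' cov_pct(c(1, 2, 3)) # 50
cov_pct <- function(values) {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("zero mean: COV undefined", call. = FALSE)
  stats::sd(values) / m * 100
}

#' 95% confidence interval for a mean
#'
#' Student-t interval: `mean +/- t(0.975, n - 1) * sd / sqrt(n)`; the t
#' rather than normal quantile because replicate counts are small (n = 5
#' in the default design).
#'
#' @param values Numeric vector (>= 2 values).
#' @return Named numeric `c(lower, upper)`.
#' @export
ci95 <- function(values) {
  n <- length(values)
  if (n < 2) stop("need >= 2 values", call. = FALSE)
  m <- mean(values)
  half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  c(lower = m - half, upper = m + half)
}

#' Origin-forced accuracy slope
#'
#' Least-squares slope of measured volume against true volume with the fit
#' forced through the origin: `slope = sum(x * y) / sum(x^2)`, with the
#' uncentered `r^2 = 1 - SS_res / sum(y^2)` appropriate to a through-origin
#' fit. A slope of 1 is perfect agreement; slopes below 1 indicate
#' systematic volume underestimation.
#'
#' @param v_true True volumes, mm^3 (not all zero).
#' @param v_ct Measured volumes, mm^3.
#' @return A one-row tibble: `slope`, `r_squared`, `n`.
#' @export
#' @examples
#' origin_slope(c(10, 20), c(9, 18)) # slope 0.9
origin_slope <- function(v_true, v_ct) {
  stopifnot(length(v_true) == length(v_ct), length(v_true) >= 1)
  if (all(v_true == 0)) stop("all true volumes are zero", call. = FALSE)
  s <- sum(v_true * v_ct) / sum(v_true^2)
  ss_res <- sum((v_ct - s * v_true)^2)
  ss_tot <- sum(v_ct^2)
  tibble::tibble(slope = s,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n = length(v_true))
}

condition_cols <- function(data) {
  intersect(c("fov", "kernel", "slice_thickness"), names(data))
}

#' Per-condition accuracy slopes
#'
#' Groups a measurement table by whichever condition columns it carries
#' (`fov`, `kernel`, `slice_thickness`), drops non-detections, and fits the
#' origin-forced slope of `v_ct` on `v_true` within each group.
#'
#' @param measurements Measurement tibble (e.g. from [run_experiment()]'s
#'   report) with `v_true`, `v_ct`, `detected`.
#' @return Tibble of condition columns plus `slope`, `r_squared`, `n`.
#' @export
accuracy_slopes <- function(measurements) {
  det <- measurements[measurements$detected, ]
  cols <- condition_cols(det)
  dplyr::reframe(
    dplyr::group_by(det, dplyr::across(dplyr::all_of(cols))),
    origin_slope(.data$v_true, .data$v_ct)
  )
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Classical one-way analysis of variance (fit with [stats::aov()]) plus
#' pairwise pooled-variance t-tests whose p values are multiplied by the
#' number of comparisons and capped at 1.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor.
#' @param n_comparisons Multiplier for the Bonferroni correction; default
#'   the number of pairwise comparisons actually made.
#' @return List with `f_statistic`, `p_value`, `df`, `n_comparisons`, and a
#'   `pairwise` tibble (`group1`, `group2`, `p_raw`, `p_adjusted`).
#' @export
anova_oneway_bonferroni <- function(data, value, group,
                                    n_comparisons = NULL) {
  g <- factor(data[[group]])
  y <- data[[value]]
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("each group needs >= 2 values", call. = FALSE)
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(y, g, p.adjust.method = "none",
                               pool.sd = TRUE)$p.value
  pairs <- which(!is.na(pw), arr.ind = TRUE)
  m <- if (is.null(n_comparisons)) nrow(pairs) else n_comparisons
  pairwise <- tibble::tibble(
    group1 = rownames(pw)[pairs[, 1]],
    group2 = colnames(pw)[pairs[, 2]],
    p_raw = pw[pairs],
    p_adjusted = pmin(pw[pairs] * m, 1)
  )
  list(
    f_statistic = tab[["F value"]][1],
    p_value = tab[["Pr(>F)"]][1],
    df = c(tab[["Df"]][1], tab[["Df"]][2]),
    n_comparisons = m,
    pairwise = pairwise
  )
}

#' Percent-error summaries by condition and sphere size
#'
#' Grouped summaries of percent error (detected measurements only): mean,
#' median, min, max, standard deviation and standard error, with the
#' detected and total counts per cell. Grouping uses whichever condition
#' columns are present plus `diameter`.
#'
#' @param measurements Measurement tibble with `diameter`, `detected`,
#'   `percent_error`.
#' @return A tibble, one row per condition x diameter cell.
#' @export
error_summary <- function(measurements) {
  cols <- c(condition_cols(measurements), "diameter")
  dplyr::summarise(
    dplyr::group_by(measurements, dplyr::across(dplyr::all_of(cols))),
    n_total = dplyr::n(),
    n_detected = sum(.data$detected),
    mean_error = mean(.data$percent_error[.data$detected]),
    median_error = stats::median(.data$percent_error[.data$detected]),
    min_error = suppressWarnings(min(.data$percent_error[.data$detected])),
    max_error = suppressWarnings(max(.data$percent_error[.data$detected])),
    sd_error = stats::sd(.data$percent_error[.data$detected]),
    se_error = .data$sd_error / sqrt(.data$n_detected),
    mean_abs_error = mean(abs(.data$percent_error[.data$detected])),
    .groups = "drop"
  )
}

#' Precision (COV and confidence interval) table
#'
#' Per condition x diameter: replicate count detected, mean measured
#' volume, sample standard deviation, COV (%), and the 95% t confidence
#' interval of the mean measured volume. Cells with fewer than two detected
#' replicates carry `NA` (reported in the study design as not assessable).
#'
#' @param measurements Measurement tibble.
#' @return A tibble, one row per condition x diameter cell.
#' @export
cov_table <- function(measurements) {
  cols <- c(condition_cols(measurements), "diameter")
  dplyr::summarise(
    dplyr::group_by(measurements, dplyr::across(dplyr::all_of(cols))),
    n_detected = sum(.data$detected),
    mean_v_ct = mean(.data$v_ct[.data$detected]),
    sd_v_ct = stats::sd(.data$v_ct[.data$detected]),
    cov = ifelse(.data$n_detected >= 2 & .data$mean_v_ct != 0,
                 .data$sd_v_ct / .data$mean_v_ct * 100, NA_real_),
    ci_lower = ifelse(.data$n_detected >= 2,
                      .data$mean_v_ct - stats::qt(0.975, .data$n_detected - 1) *
                        .data$sd_v_ct / sqrt(.data$n_detected), NA_real_),
    ci_upper = ifelse(.data$n_detected >= 2,
                      .data$mean_v_ct + stats::qt(0.975, .data$n_detected - 1) *
                        .data$sd_v_ct / sqrt(.data$n_detected), NA_real_),
    .groups = "drop"
  )
}

#' Minimum measurable diameter for an error tolerance
#'
#' Given a per-diameter expected absolute error curve (sorted by
#' diameter), returns the smallest diameter `d` such that the linearly
#' interpolated |error| stays at or below `tolerance` for every tested
#' diameter `>= d`. If even the largest diameter fails, the sentinel is
#' `"> max tested"`; if the smallest diameter already passes, it is
#' `"< min tested"`.
#'
#' @param curve Data frame with columns `diameter` (strictly increasing)
#'   and `abs_error` (expected |percent error|).
#' @param tolerance Error tolerance in percent.
#' @return A one-row tibble: `tolerance`, `min_diameter` (mm, `NA` for
#'   `"> max tested"`), `label` (printable value or sentinel, e.g.
#'   `">25.4"`).
#' @export
#' @examples
#' curve <- tibble::tibble(diameter = c(5, 10), abs_error = c(15, 5))
#' lookup_min_diameter(curve, 10) # 7.5 mm
lookup_min_diameter <- function(curve, tolerance) {
  d <- curve$diameter
  e <- curve$abs_error
  if (length(d) < 2) stop("need >= 2 curve points", call. = FALSE)
  if (any(diff(d) <= 0)) {
    stop("`curve` must be sorted by strictly increasing diameter",
         call. = FALSE)
  }
  keep <- !is.na(e)
  d <- d[keep]; e <- e[keep]
  if (length(d) < 2) stop("need >= 2 non-missing curve points", call. = FALSE)
  fails <- e > tolerance
  if (fails[length(d)]) {
    return(tibble::tibble(tolerance = tolerance, min_diameter = NA_real_,
                          label = sprintf(">%.3g", max(d))))
  }
  if (!any(fails)) {
    return(tibble::tibble(tolerance = tolerance, min_diameter = min(d),
                          label = sprintf("<%.3g", min(d))))
  }
  j <- max(which(fails)) # last failing diameter; all larger ones pass
  # linear interpolation of the crossing in (d[j], d[j + 1]]; an undetected
  # class (infinite error) admits no interpolation, so the first passing
  # tested diameter is returned
  dd <- if (is.finite(e[j])) {
    d[j] + (e[j] - tolerance) / (e[j] - e[j + 1]) * (d[j + 1] - d[j])
  } else {
    d[j + 1]
  }
  tibble::tibble(tolerance = tolerance, min_diameter = dd,
                 label = sprintf("%.3g", dd))
}

#' Minimum-diameter lookup table over conditions
#'
#' Builds, for every condition, the expected |percent error| curve (mean
#' over replicates of |percent error| per diameter, detected only; a
#' diameter with no detections counts as failing every tolerance) and
#' looks up the minimum measurable diameter for each tolerance.
#'
#' @param measurements Measurement tibble.
#' @param tolerances Percent tolerances, default `c(10, 20)`.
#' @return Tibble of condition columns plus `tolerance`, `min_diameter`,
#'   `label`.
#' @export
min_diameter_table <- function(measurements, tolerances = c(10, 20)) {
  cols <- condition_cols(measurements)
  grp <- dplyr::group_by(measurements,
                         dplyr::across(dplyr::all_of(c(cols, "diameter"))))
  curves <- dplyr::summarise(
    grp,
    abs_error = if (any(.data$detected)) {
      mean(abs(.data$percent_error[.data$detected]))
    } else Inf, # undetected size class fails every tolerance
    .groups = "drop"
  )
  split_cols <- if (length(cols)) curves[cols] else
    list(rep(1, nrow(curves)))
  parts <- split(curves, split_cols, drop = TRUE)
  purrr::map_dfr(parts, function(part) {
    part <- part[order(part$diameter), ]
    purrr::map_dfr(tolerances, function(tol) {
      dplyr::bind_cols(
        part[1, cols, drop = FALSE],
        lookup_min_diameter(
          tibble::tibble(diameter = part$diameter,
                         abs_error = part$abs_error),
          tol
        )
      )
    })
  })
}
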