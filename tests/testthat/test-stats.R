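test_that("COV is sample sd over mean, percent, and scale invariant", {
  expect_equal(cov_pct(rep(5, 5)), 0)
  expect_equal(cov_pct(c(1, 2, 3)), 50)
  set.seed(3)
  x <- rlnorm(10)
  expect_equal(cov_pct(3.7 * x), cov_pct(x))
  expect_error(cov_pct(7), ">= 2")
  expect_error(cov_pct(c(-1, 1)), "zero mean")
})

test_that("ci95 is the Student-t interval", {
  expect_equal(unname(ci95(rep(4, 3))), c(4, 4))
  got <- ci95(1:5)
  half <- 2.776445 * sqrt(2.5) / sqrt(5) # t(0.975, 4) x sd/sqrt(n)
  expect_equal(unname(got), c(3 - half, 3 + half), tolerance = 1e-6)
  set.seed(4)
  x <- rnorm(8)
  ci <- ci95(x)
  expect_true(ci[["lower"]] <= mean(x) && mean(x) <= ci[["upper"]])
  expect_error(ci95(1), ">= 2")
})

test_that("origin-forced slope matches exact proportionality and the oracle", {
  eq <- origin_slope(c(1, 5, 20), c(1, 5, 20))
  expect_equal(eq$slope, 1)
  expect_equal(eq$r_squared, 1)
  prop <- origin_slope(c(10, 100, 1000), 0.9 * c(10, 100, 1000))
  expect_equal(prop$slope, 0.9)
  set.seed(9)
  v_true <- runif(20, 10, 5000)
  v_ct <- 0.85 * v_true + rnorm(20, 0, 50)
  got <- origin_slope(v_true, v_ct)$slope
  expect_equal(got, grid_search_slope(v_true, v_ct), tolerance = 1e-3)
  expect_error(origin_slope(c(0, 0), c(1, 2)), "zero")
})

test_that("accuracy_slopes groups by the condition columns present", {
  meas <- tidyr::expand_grid(
    slice_thickness = c(1, 2), kernel = "standard",
    v_true = c(100, 1000)
  )
  meas$v_ct <- ifelse(meas$slice_thickness == 1, 0.95, 0.8) * meas$v_true
  meas$detected <- TRUE
  sl <- accuracy_slopes(meas)
  expect_equal(nrow(sl), 2)
  expect_equal(sl$slope[sl$slice_thickness == 1], 0.95)
  expect_equal(sl$slope[sl$slice_thickness == 2], 0.8)
})

test_that("two-group one-way ANOVA reduces to the squared t statistic", {
  set.seed(13)
  df <- data.frame(y = c(rnorm(8, 0), rnorm(8, 1)),
                   g = rep(c("a", "b"), each = 8))
  res <- anova_oneway_bonferroni(df, "y", "g")
  tt <- t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("identical groups give F = 0 and Bonferroni multiplies raw p", {
  df <- data.frame(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  res <- anova_oneway_bonferroni(df, "y", "g")
  expect_equal(res$f_statistic, 0)
  expect_equal(res$n_comparisons, 3)
  expect_equal(res$pairwise$p_adjusted,
               pmin(res$pairwise$p_raw * 3, 1))
  # the multiplication rule itself: raw 0.04 with 3 comparisons -> 0.12
  df2 <- data.frame(y = c(0.9, 1.1, 1.0, 1.4, 1.6, 1.5),
                    g = rep(c("a", "b"), each = 3))
  r2 <- anova_oneway_bonferroni(df2, "y", "g", n_comparisons = 3)
  expect_equal(r2$pairwise$p_adjusted, pmin(r2$pairwise$p_raw * 3, 1))
  expect_error(anova_oneway_bonferroni(
    data.frame(y = 1:3, g = c("a", "a", "b")), "y", "g"), ">= 2")
})

test_that("error_summary matches a flat recomputation and excludes nondetections", {
  set.seed(15)
  meas <- tidyr::expand_grid(kernel = c("standard", "lung"),
                             diameter = c(5, 10), replicate = 1:5)
  meas$detected <- TRUE
  meas$percent_error <- rnorm(nrow(meas), -20, 5)
  es <- error_summary(meas)
  expect_equal(nrow(es), 4)
  cell <- es[es$kernel == "lung" & es$diameter == 5, ]
  flat <- meas$percent_error[meas$kernel == "lung" & meas$diameter == 5]
  expect_equal(cell$mean_error, mean(flat))
  expect_equal(cell$median_error, median(flat))
  expect_equal(cell$sd_error, sd(flat))
  # dropping one observation to nondetected changes n but not the mean of
  # the remaining detected values
  meas2 <- meas
  drop_i <- which(meas2$kernel == "lung" & meas2$diameter == 5)[1]
  meas2$detected[drop_i] <- FALSE
  es2 <- error_summary(meas2)
  cell2 <- es2[es2$kernel == "lung" & es2$diameter == 5, ]
  expect_equal(cell2$n_detected, 4)
  expect_equal(cell2$n_total, 5)
  expect_equal(cell2$mean_error, mean(flat[-1]))
  # single-observation cell: mean == median == the value
  single <- error_summary(tibble::tibble(diameter = 7, detected = TRUE,
                                         percent_error = -12.5))
  expect_equal(single$mean_error, -12.5)
  expect_equal(single$median_error, -12.5)
})

test_that("cov_table reports COV and t-based CI per cell", {
  meas <- tibble::tibble(diameter = 5, detected = TRUE,
                         v_ct = c(10, 12, 14), percent_error = 0)
  ct <- cov_table(meas)
  expect_equal(ct$cov, cov_pct(c(10, 12, 14)))
  expect_equal(c(ct$ci_lower, ct$ci_upper), unname(ci95(c(10, 12, 14))))
})

test_that("lookup_min_diameter interpolates, hits boundaries, and uses sentinels", {
  expect_equal(
    lookup_min_diameter(tibble::tibble(diameter = c(5, 10),
                                       abs_error = c(30, 10)), 10)$min_diameter,
    10
  )
  expect_equal(
    lookup_min_diameter(tibble::tibble(diameter = c(5, 10),
                                       abs_error = c(15, 5)), 10)$min_diameter,
    7.5
  )
  high <- lookup_min_diameter(tibble::tibble(diameter = c(5, 10, 25.4),
                                             abs_error = c(50, 40, 30)), 10)
  expect_true(is.na(high$min_diameter))
  expect_equal(high$label, ">25.4")
  low <- lookup_min_diameter(tibble::tibble(diameter = c(3.2, 10),
                                            abs_error = c(8, 2)), 10)
  expect_equal(low$label, "<3.2")
  expect_error(
    lookup_min_diameter(tibble::tibble(diameter = c(10, 5),
                                       abs_error = c(1, 2)), 10),
    "increasing"
  )
})

test_that("minimum diameter is monotone in tolerance", {
  set.seed(25)
  for (i in 1:20) {
    # random decreasing-ish error curve
    e <- sort(runif(6, 0, 60), decreasing = TRUE) + rnorm(6, 0, 2)
    curve <- tibble::tibble(diameter = c(3.2, 4.8, 6.4, 9.5, 19.1, 25.4),
                            abs_error = pmax(e, 0))
    as_num <- function(x) {
      if (!is.na(x$min_diameter)) x$min_diameter
      else if (startsWith(x$label, ">")) Inf else -Inf
    }
    d10 <- as_num(lookup_min_diameter(curve, 10))
    d20 <- as_num(lookup_min_diameter(curve, 20))
    expect_gte(d10, d20)
  }
})
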