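test_that("percentile summaries follow the documented quantile convention", {
  s <- percentile_summary(1:100)
  expect_equal(s$p95, 95.05)
  expect_equal(s$median, 50.5)
  expect_equal(s$p5, 5.95)
  const <- percentile_summary(rep(3.2, 50))
  expect_equal(const$p5, 3.2)
  expect_equal(const$median, 3.2)
  expect_equal(const$p95, 3.2)
  set.seed(2)
  x <- rlnorm(200)
  expect_equal(percentile_summary(sample(x)), percentile_summary(x))
  expect_error(percentile_summary(1), "two")
})

test_that("bootstrap p95 interval is seeded, degenerate-safe and shrinks with n", {
  x <- rlnorm(500, 0, 0.5)
  ci1 <- bootstrap_p95_ci(x, seed = 42)
  ci2 <- bootstrap_p95_ci(x, seed = 42)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["lo"]], stats::quantile(x, 0.95, names = FALSE))
  expect_gte(ci1[["hi"]], ci1[["lo"]])
  const <- bootstrap_p95_ci(rep(7, 30), seed = 1)
  expect_equal(const[["lo"]], 7)
  expect_equal(const[["hi"]], 7)
  expect_error(bootstrap_p95_ci(rlnorm(10)), "at least 20")
  # width ~ 1/sqrt(n)
  set.seed(8)
  width <- vapply(c(125, 500, 2000), function(n) {
    w <- replicate(10, {
      ci <- bootstrap_p95_ci(rlnorm(n, 0, 0.5), B = 400, seed = 3)
      ci[["hi"]] - ci[["lo"]]
    })
    mean(w)
  }, numeric(1))
  expect_true(all(diff(width) < 0))
  expect_equal(width[1] / width[3], 4, tolerance = 0.5)
})

test_that("bootstrap interval usually covers the point p95", {
  set.seed(14)
  hits <- replicate(60, {
    x <- rlnorm(500, 0, 0.5)
    ci <- bootstrap_p95_ci(x, B = 300, seed = 7)
    p <- stats::quantile(x, 0.95, names = FALSE)
    ci[["lo"]] <= p && p <= ci[["hi"]]
  })
  expect_gte(mean(hits), 0.95)
})

fake_run <- function(values_by_age, seed = 1) {
  n <- length(values_by_age[[1]])
  df <- do.call(rbind, lapply(names(values_by_age), function(a) {
    data.frame(id = seq_len(n), age_y = as.numeric(a), compartment = "bone",
               amount_ug = NA_real_, conc = values_by_age[[a]],
               conc_units = "ug/g ww")
  }))
  structure(df, seed = seed, n = n, n_failed = 0L,
            class = c("al_population_run", "data.frame"))
}

test_that("p95 ratios implement the three treated-versus-baseline contrasts", {
  set.seed(6)
  v10 <- rlnorm(100); v50 <- rlnorm(100)
  base <- fake_run(list(`10` = v10, `50` = v50))
  same <- fake_run(list(`10` = v10, `50` = v50))
  r <- p95_ratios(same, base, 5, "bone")
  expect_equal(r$ratio_5_5, 1)
  expect_equal(r$ratio_50_50, 1)
  doubled <- fake_run(list(`10` = 2 * v10, `50` = v50))
  r2 <- p95_ratios(doubled, base, 5, "bone")
  expect_equal(r2$ratio_5_5, 2)
  expect_equal(r2$ratio_50_50, 1)
  expect_equal(r2$ratio_5_50,
               2 * stats::quantile(v10, .95, names = FALSE) /
                 stats::quantile(v50, .95, names = FALSE))
  # rounding at report precision: 5.5/5.2 -> 1.06 -> 1.1
  expect_equal(round(5.5 / 5.2, 1), 1.1)
  other <- fake_run(list(`10` = v10, `50` = v50), seed = 2)
  expect_error(p95_ratios(other, base, 5, "bone"), "identical population")
  expect_error(p95_ratios(same, base, 40, "bone"), "out_ages")
})

test_that("dry-to-wet conversion uses the registered tissue factors", {
  expect_equal(convert_dw_ww(10, "bone"), 4.97)
  expect_equal(convert_dw_ww(14, "bone"), 6.958)
  expect_equal(convert_dw_ww(4.5, "brain"), 1.035)
  expect_equal(convert_dw_ww(32, "liver"), 8)
  expect_error(convert_dw_ww(1, "kidney"), "no dry-to-wet")
  th <- threshold_table()
  expect_lt(th$uln_ww[["bone"]], th$bone_critical)
  expect_lt(th$bone_critical, th$bone_disease)
})

test_that("exceedance and safety margins follow their definitions", {
  x <- rlnorm(1000, 0, 0.4)
  expect_equal(exceedance_fraction(x, max(x) + 1), 0)
  expect_equal(exceedance_fraction(x, stats::quantile(x, .95, names = FALSE)),
               0.05, tolerance = 0.001)
  shifted <- x * 1.5
  expect_gt(exceedance_fraction(shifted,
                                stats::quantile(x, .95, names = FALSE)), 0.05)
  expect_equal(margin_of_safety(30, 7), 4.285714, tolerance = 1e-6)
  expect_equal(margin_of_safety(30, 5), 6)
  expect_equal(margin_of_safety(7, 7), 1)
})

test_that("the comparison table pairs scenarios and flags mismatched seeds", {
  set.seed(99)
  v10 <- rlnorm(60); v50 <- rlnorm(60)
  base <- fake_run(list(`10` = v10, `50` = v50))
  trt <- fake_run(list(`10` = v10 * 1.6, `50` = v50 * 1.02))
  tab <- build_table1(list(food_only = base, scit = trt),
                      start_ages = c(scit = 5))
  expect_true(all(is.na(tab$ratio_5_5[tab$scenario == "food_only"])))
  srow <- tab[tab$scenario == "scit" & tab$tissue == "bone" &
                tab$timepoint == "5y after SCIT start", ]
  expect_equal(srow$ratio_5_5, 1.6, tolerance = 1e-9)
  tab2 <- build_table1(list(food_only = base, scit = trt),
                       start_ages = c(scit = 5))
  expect_identical(tab, tab2)
  bad <- fake_run(list(`10` = v10, `50` = v50), seed = 2)
  expect_error(build_table1(list(food_only = base, scit = bad),
                            start_ages = c(scit = 5)), "identical population")
  # identical inputs give unit ratios everywhere
  tab3 <- build_table1(list(food_only = base, same = base),
                       start_ages = c(same = 5))
  expect_true(all(abs(stats::na.omit(tab3$ratio_50_50) - 1) < 1e-12))
})
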