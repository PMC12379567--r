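test_that("dietary tiers follow the age schedule and the intake arithmetic", {
  scheme <- dietary_scheme()
  expect_equal(dietary_intake_tier(scheme, 2 / 12), 0.1)
  expect_equal(dietary_intake_tier(scheme, 5 / 12), 0.2)
  expect_equal(dietary_intake_tier(scheme, 8 / 12), 0.4)
  expect_equal(dietary_intake_tier(scheme, 11 / 12), 0.8)
  expect_equal(dietary_intake_tier(scheme, 35), 0.8)
  # children/adults: 80% of the tolerable weekly intake of 1 mg/kg/week
  expect_equal(dietary_intake_tier(scheme, 10) / 1.0, 0.8)

  # 2-month-old at 5 kg ingests 0.1 * 5 * 1000 / 7 ~ 71.4 ug/day
  infant <- physiology_profile("female", growth = as_growth_table(
    data.frame(age_y = c(0, 50), bw_kg = 5, bone_g = 300, brain_g = 400,
               liver_g = 130, kidney_g = 25, rest_g = 2000, plasma_L = 0.13)))
  expect_equal(dietary_ingestion_rate(scheme, infant, 2 / 12), 71.42857,
               tolerance = 1e-6)
  # 60 kg adult: 6857 ug/day ingested, x 0.17% = 11.66 ug/day systemic
  adult <- flat_profile(bw = 60)
  ing <- dietary_ingestion_rate(scheme, adult, 35)
  expect_equal(ing, 0.8 * 60 * 1000 / 7, tolerance = 1e-9)
  expect_equal(ing * scheme$oral_bioavailability, 11.65714,
               tolerance = 1e-5)
})

test_that("maintenance schedules give the published dose counts and totals", {
  cases <- list(
    list(sched = list(scit_schedule(5, 5)), n = 65, total = 81.25),
    list(sched = list(scit_schedule(5, 5), scit_schedule(5 + 5 * 364 / 365.25, 5)),
         n = 130, total = 162.5),
    list(sched = list(scit_schedule(10, 40)), n = 520, total = 650),
    list(sched = list(scit_schedule(5, 5, n_parallel = 2)), n = 130,
         total = 162.5)
  )
  for (cs in cases) {
    ev <- do.call(combine_dose_events, lapply(cs$sched, build_scit_schedule))
    expect_equal(nrow(ev), cs$n)
    expect_equal(cumulative_dose(ev), cs$total)
  }
  ev <- build_scit_schedule(scit_schedule(5, 5))
  expect_equal(unique(diff(ev$time_days)), 28)
  expect_equal(ev$time_days[1], 5 * 365.25)
  expect_equal(cumulative_dose(empty_dose_events()), 0)
  expect_error(scit_schedule(5, 5, interval = 0), "positive")
  expect_error(scit_schedule(5, 5, dose = -1), "positive")
})

test_that("zero-order depots release at the published rates until exhaustion", {
  kin <- adjuvant_kinetics()
  expect_equal(1 / kin$k_release[["Ains"]], 121.37, tolerance = 1e-4)
  expect_equal(1 / kin$k_release[["Ahy"]], 402.19, tolerance = 1e-4)
  ev <- data.frame(time_days = 100, amount_mg = 1.25, adjuvant = "Ahy")
  k <- kin$k_release[["Ahy"]]
  expect_equal(depot_release(ev, k, 150), 1.25 * k * 1000)  # ~3.108 ug/day
  expect_equal(depot_release(ev, k, 150), 3.108, tolerance = 1e-4)
  expect_equal(depot_release(ev, k, 99), 0)      # before the dose
  expect_equal(depot_release(ev, k, 100 + 1 / k + 0.01), 0)  # exhausted
})

test_that("each depot releases exactly the administered amount", {
  set.seed(3)
  for (i in 1:5) {
    k <- runif(1, 5e-4, 2e-2)
    ev <- data.frame(time_days = sort(runif(4, 0, 300)),
                     amount_mg = runif(4, 0.2, 2), adjuvant = "Ahy")
    t_end <- max(ev$time_days) + 1 / k + 1
    # quadrature of the piecewise-constant release profile
    brk <- sort(unique(c(0, ev$time_days, ev$time_days + 1 / k, t_end)))
    total <- sum(vapply(seq_len(length(brk) - 1), function(j) {
      stats::integrate(function(t) depot_release(ev, k, t),
                       brk[j], brk[j + 1], rel.tol = 1e-10)$value
    }, numeric(1)))
    expect_equal(total, 1000 * sum(ev$amount_mg), tolerance = 1e-8)
    expect_equal(depot_released_cumulative(ev, k, t_end),
                 1000 * sum(ev$amount_mg), tolerance = 1e-12)
  }
})

test_that("steady four-weekly dosing approaches dose/interval mean release", {
  k <- adjuvant_kinetics()$k_release[["Ahy"]]
  ev <- build_scit_schedule(scit_schedule(0, 5))  # 65 doses from birth
  # in the overlap steady state (after ~1/k days) the mean release over one
  # interval is dose/28 = 44.64 ug/day
  t0 <- 3 * 365; stopifnot(t0 > 1 / k)
  mean_rate <- (depot_released_cumulative(ev, k, t0 + 28) -
                  depot_released_cumulative(ev, k, t0)) / 28
  expect_equal(mean_rate, 1250 / 28, tolerance = 1e-10)
  # number of simultaneously active depots
  n_active <- vapply(seq(t0, t0 + 28, by = 1), function(t) {
    sum(ev$time_days <= t & t < ev$time_days + 1 / k)
  }, numeric(1))
  expect_true(all(n_active %in% c(ceiling(1 / (28 * k)) - 1,
                                  ceiling(1 / (28 * k)))))
})
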