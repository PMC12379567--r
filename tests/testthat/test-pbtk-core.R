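test_that("right-hand side conserves mass and brain has no efflux", {
  sc <- food_short_scenario(horizon = 12)
  ctx <- build_model_context(sc, default_parameters(), typical_individual(),
                             physiology_profile("female"), ca_kinetics())
  expect_equal(ctx$rhs_core(100, rep(0, 7), 0, 0), rep(0, 7))
  set.seed(5)
  for (i in 1:10) {
    y <- runif(7, 0, 500)
    t <- runif(1, 1, 4000)
    # with no external input the total (including urine) is conserved
    expect_equal(sum(ctx$rhs_core(t, y, 0, 0)), 0, tolerance = 1e-10)
    # with input, d(total)/dt equals the input rate
    depot <- runif(1, 0, 50)
    d <- ctx$rhs_core(t, y, 0, depot)
    expect_equal(sum(d), depot, tolerance = 1e-10)
    # brain derivative is uptake only: independent of the brain amount
    y2 <- y; y2[3] <- y[3] * 10 + 100
    expect_equal(ctx$rhs_core(t, y2, 0, depot)[3], d[3], tolerance = 1e-12)
    expect_gte(d[3], 0)
  }
})

test_that("zero input with zero birth levels stays identically zero", {
  p <- model_parameters(renal_extraction = 0.057, k_brain_in = 0.0132,
                        kappa_bone = 0.0038,
                        birth_amounts = c(plasma = 0, bone = 0, brain = 0,
                                          liver = 0, kidney = 0, rest = 0))
  sc <- scenario("nothing", zero_diet(), list(), horizon = 10)
  sim <- simulate_individual(sc, p, out_ages = c(0, 1, 5, 10))
  expect_true(all(sim$amounts == 0))
})

test_that("mass balance closes to 1e-6 and degrades without event bracketing", {
  sim <- simulate_individual(get_scenario("food_only"), out_ages = c(50))
  expect_lt(mass_balance(sim), 1e-6)
  sc <- child_short_scenario()
  sim_on <- simulate_individual(sc, out_ages = c(12))
  expect_lt(mass_balance(sim_on), 1e-6)
  sim_off <- simulate_individual(sc, out_ages = c(12),
                                 bracket_events = FALSE)
  expect_gt(mass_balance(sim_off), mass_balance(sim_on))
})

test_that("adaptive solver agrees with the fixed-step oracle", {
  sc <- get_scenario("food_only")
  ada <- simulate_individual(sc, out_ages = seq(5, 50, by = 5))
  fx <- fixed_step_oracle(sc, dt = 0.25, out_ages = seq(5, 50, by = 5))
  expect_lt(max(rel_dev(fx$amounts, ada$amounts)), 1e-3)
})

test_that("trajectories superpose and scale linearly in the injected dose", {
  food <- simulate_individual(food_short_scenario(), out_ages = c(6, 8, 10, 12))
  treated <- simulate_individual(child_short_scenario(),
                                 out_ages = c(6, 8, 10, 12))
  # injection-only: zero diet and zero birth levels
  p0 <- default_parameters()
  p0$birth_amounts[] <- 0
  scit_only <- simulate_individual(child_short_scenario(dietary = zero_diet()),
                                   p0, out_ages = c(6, 8, 10, 12))
  expect_lt(max(rel_dev(food$amounts + scit_only$amounts, treated$amounts)),
            1e-5)
  # tripling every dose triples the treatment-attributable excess
  treated3 <- simulate_individual(child_short_scenario(dose = 3.75),
                                  out_ages = c(6, 8, 10, 12))
  excess1 <- treated$amounts - food$amounts
  excess3 <- treated3$amounts - food$amounts
  expect_lt(max(rel_dev(excess3, 3 * excess1)), 1e-5)
})

test_that("bone excess is transient while brain excess persists", {
  ages <- c(10, 15, 20, 30, 40, 50)
  food <- simulate_individual(get_scenario("food_only"), out_ages = ages)
  trt <- simulate_individual(get_scenario("child_high_ahy_5"),
                             out_ages = ages)
  bone_excess <- trt$amounts[, "bone"] - food$amounts[, "bone"]
  brain_excess <- trt$amounts[, "brain"] - food$amounts[, "brain"]
  # treatment (age 5-10) loads bone; the excess then decays towards zero
  expect_gt(bone_excess[1], 0)
  expect_true(all(diff(bone_excess) < 0))
  expect_lt(bone_excess[length(ages)], 0.05 * bone_excess[1])
  # the brain is a sink: its excess never decreases
  expect_true(all(diff(brain_excess) >= -1e-9))
  # all states non-negative in both runs
  expect_true(all(food$amounts >= 0))
  expect_true(all(trt$amounts >= 0))
})

test_that("simulation results expose tidy concentrations", {
  sim <- simulate_individual(food_short_scenario(horizon = 5),
                             out_ages = c(1, 5))
  df <- as.data.frame(sim)
  expect_setequal(unique(df$compartment),
                  c("plasma", "bone", "brain", "liver", "kidney", "rest"))
  expect_equal(unname(df$conc[df$compartment == "plasma" & df$age_y == 5]),
               unname(sim$amounts[2, "plasma"] /
                        plasma_volume(sim$physiology, 5)))
  expect_equal(unname(df$conc[df$compartment == "bone" & df$age_y == 1]),
               unname(sim$amounts[1, "bone"] /
                        organ_mass(sim$physiology, "bone", 1)))
  expect_error(simulate_individual(food_short_scenario(horizon = 5),
                                   out_ages = c(1, 60)))
})
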