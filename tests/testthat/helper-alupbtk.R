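# Shared fixtures, built in code.

# Degenerate physiology with constant masses/volumes and instantaneous
# renal maturation; collapses all age dependence so closed-form solutions
# apply.
flat_profile <- function(bw = 60, plasma_L = 2.4) {
  tab <- data.frame(
    age_y = c(0, 50), bw_kg = bw,
    bone_g = 6000, brain_g = 1300, liver_g = 1400, kidney_g = 275,
    rest_g = 40000, plasma_L = plasma_L
  )
  physiology_profile("female", growth = as_growth_table(tab),
                     gfr = gfr_model(maturation_halftime = 1e-9,
                                     birth_offset = 0.77))
}

# Dietary scheme with zero intake (injection-only runs).
zero_diet <- function() {
  dietary_scheme(tiers = data.frame(age_lo_mo = 0, age_hi_mo = Inf,
                                    intake_mg_kg_wk = 0))
}

# Parameters whose tissue/bone/brain exchange is negligible, so the model
# collapses to one plasma compartment with renal elimination.
one_compartment_params <- function(birth_plasma = 100) {
  model_parameters(
    renal_extraction = 0.058, k_brain_in = 1e-12, kappa_bone = 1e-12,
    k_in = c(liver = 0, kidney = 0, rest = 0),
    k_out = c(liver = 0, kidney = 0, rest = 0),
    birth_amounts = c(plasma = birth_plasma, bone = 0, brain = 0,
                      liver = 0, kidney = 0, rest = 0),
    scale_uptake_with_mass = FALSE
  )
}

# Child five-year treatment on a short horizon: cheap ODE runs for
# structural tests (treatment ends just before age 10).
child_short_scenario <- function(dietary = dietary_scheme(), horizon = 12,
                                 dose = 1.25, n_parallel = 1) {
  scenario("child_short", dietary,
           list(scit_schedule(5, 5, dose = dose, n_parallel = n_parallel)),
           horizon = horizon)
}

food_short_scenario <- function(horizon = 12) {
  scenario("food_short", dietary_scheme(), list(), horizon = horizon)
}

rel_dev <- function(a, b) abs(a - b) / pmax(abs(b), 1e-300)
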