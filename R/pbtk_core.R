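# The Al PBTK ODE system: amounts (ug) in plasma, bone, brain, liver,
# kidney and rest-of-body, with renal elimination via GFR, bone kinetics
# coupled to Ca turnover, a brain sink, continuous dietary input and
# zero-order subcutaneous depot input. Amount-based equations make growth
# dilution implicit: concentrations are amounts divided by growing organ
# masses / plasma volume.

AL_COMPARTMENTS <- c("plasma", "bone", "brain", "liver", "kidney", "rest",
                     "urine")

#' Model rate parameters
#'
#' Rate constants of the Al PBTK model. Plasma exchanges with liver, kidney
#' and rest-of-body by first-order uptake clearances (L/day, referring to
#' the adult organ; scaled in proportion to organ mass during growth) and
#' fractional return rates (1/day). Brain uptake is a clearance with no
#' return flux (sink). Bone uptake is proportional to the Ca accretion flux
#' via `kappa_bone` and release follows the fractional Ca release rate.
#' Renal elimination is `renal_extraction * GFR * C_plasma`, the filterable
#' plasma fraction cleared by glomerular filtration.
#'
#' @param renal_extraction fraction of GFR cleared, in (0, 1].
#' @param k_brain_in brain uptake clearance, L/day (adult brain).
#' @param kappa_bone bone coupling constant, (ug Al/day) per (mg Ca/day)
#'   per (ug Al/L).
#' @param k_in named uptake clearances (L/day) for `liver`, `kidney`,
#'   `rest` (adult organs).
#' @param k_out named fractional return rates (1/day) for the same organs.
#' @param birth_amounts named Al amounts (ug) at birth for `plasma`,
#'   `bone`, `brain`, `liver`, `kidney`, `rest` (built up in utero).
#' @param scale_uptake_with_mass logical; scale tissue and brain uptake
#'   clearances by current/adult organ mass (default `TRUE`).
#' @return an object of class `al_parameters`.
#' @export
model_parameters <- function(renal_extraction,
                             k_brain_in,
                             kappa_bone,
                             k_in = c(liver = 3, kidney = 0.5, rest = 4),
                             k_out = c(liver = 3e-3, kidney = 5.09e-3,
                                       rest = 1.33e-3),
                             birth_amounts = c(plasma = 0.65, bone = 90,
                                               brain = 72, liver = 39,
                                               kidney = 5, rest = 100),
                             scale_uptake_with_mass = TRUE) {
  stopifnot(renal_extraction > 0, renal_extraction <= 1,
            k_brain_in > 0, kappa_bone > 0,
            all(k_in >= 0), all(k_out >= 0), all(birth_amounts >= 0))
  k_in <- k_in[c("liver", "kidney", "rest")]
  k_out <- k_out[c("liver", "kidney", "rest")]
  birth_amounts <- birth_amounts[c("plasma", "bone", "brain", "liver",
                                   "kidney", "rest")]
  if (any(is.na(k_in)) || any(is.na(k_out)) || any(is.na(birth_amounts))) {
    stop("k_in, k_out and birth_amounts must name liver/kidney/rest ",
         "(and all non-urine compartments for birth_amounts)")
  }
  structure(list(renal_extraction = renal_extraction,
                 k_brain_in = k_brain_in, kappa_bone = kappa_bone,
                 k_in = k_in, k_out = k_out, birth_amounts = birth_amounts,
                 scale_uptake_with_mass = scale_uptake_with_mass),
            class = "al_parameters")
}

#' Default (calibrated) model parameters
#'
#' Reads the versioned default parameter fixture shipped with the package.
#' Dietary tiers, oral bioavailability, depot release rates, conversion
#' factors and thresholds are literature-anchored constants; the rate
#' constants in this fixture were calibrated against adult background
#' (dietary-exposure) tissue levels, see the calibration vignette section
#' and [calibrate()].
#'
#' @return an `al_parameters`.
#' @export
default_parameters <- function() {
  path <- system.file("extdata", "params_default.json",
                      package = "alupbtk", mustWork = TRUE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_parameters(renal_extraction = p$renal_extraction,
                   k_brain_in = p$k_brain_in,
                   kappa_bone = p$kappa_bone,
                   k_in = unlist(p$k_in), k_out = unlist(p$k_out),
                   birth_amounts = unlist(p$birth_amounts),
                   scale_uptake_with_mass = p$scale_uptake_with_mass)
}

# Internal: interpolation grid (days) spanning [0, horizon]; dense where
# physiology changes fast.
al_age_grid <- function(horizon_y) {
  ages <- c(seq(0, 2, by = 0.02), seq(2.05, 20, by = 0.05),
            seq(20.1, max(20.2, horizon_y), by = 0.1))
  ages <- ages[ages <= horizon_y]
  if (ages[length(ages)] < horizon_y) ages <- c(ages, horizon_y)
  ages * DAYS_PER_YEAR
}

#' Build the model context (right-hand side) for one individual
#'
#' Precomputes all age-dependent coefficient curves on a fine grid and
#' returns the ODE right-hand side plus helpers. Mainly used internally by
#' [simulate_individual()] and by the fixed-step verification oracle.
#'
#' @param scenario an `al_scenario` (see [scenario()]).
#' @param params an `al_parameters`.
#' @param individual an individual parameter row (see
#'   [typical_individual()]).
#' @param physiology an `al_physiology`.
#' @param ca an `al_ca_kinetics`.
#' @return a list with elements `rhs_core(t, y, diet_coef, depot_rate)`,
#'   `rhs_full(t, y)` (forcing evaluated from `t`), `events`, `k_sc`,
#'   `breaks` (days of dose, exhaustion and dietary-tier discontinuities),
#'   `diet_coef_at(t)`, `depot_rate_at(t)`, `y0` and `horizon_days`.
#' @export
build_model_context <- function(scenario, params, individual, physiology, ca) {
  stopifnot(inherits(scenario, "al_scenario"),
            inherits(params, "al_parameters"),
            inherits(physiology, "al_physiology"),
            inherits(ca, "al_ca_kinetics"))
  horizon_days <- scenario$horizon * DAYS_PER_YEAR
  scheme <- scenario$dietary
  events <- scenario_dose_events(scenario)
  k_sc <- individual$k_sc
  dist <- individual$dist_mult

  tg <- al_age_grid(scenario$horizon)
  ages <- tg / DAYS_PER_YEAR
  adult_mass <- vapply(c("liver", "kidney", "rest", "brain"),
                       function(o) organ_mass(physiology, o, 20), numeric(1))
  mass_scale <- function(organ) {
    if (!params$scale_uptake_with_mass) return(rep(1, length(ages)))
    organ_mass(physiology, organ, ages) / adult_mass[[organ]]
  }
  M <- cbind(
    vpl    = plasma_volume(physiology, ages),
    clren  = params$renal_extraction * 1.44 *
               gfr(physiology, ages, individual$gfr_mult),
    clbone = params$kappa_bone * dist * ca_accretion(ca, ages),
    krel   = bone_release_rate(ca, ages),
    clliv  = params$k_in[["liver"]] * dist * mass_scale("liver"),
    clkid  = params$k_in[["kidney"]] * dist * mass_scale("kidney"),
    clrest = params$k_in[["rest"]] * dist * mass_scale("rest"),
    clbrain = params$k_brain_in * dist * mass_scale("brain"),
    bw     = body_weight(physiology, ages)
  )
  dimnames(M) <- NULL  # positional access in the rhs
  ko_l <- params$k_out[["liver"]]
  ko_k <- params$k_out[["kidney"]]
  ko_r <- params$k_out[["rest"]]

  # diet systemic rate = diet_coef(t) * BW(t); coef in ug/day/kg
  tier_coef <- function(t) {
    dietary_intake_tier(scheme, t / DAYS_PER_YEAR) * 1000 / 7 *
      scheme$oral_bioavailability * individual$oral_F_mult
  }

  rhs_core <- function(t, y, diet_coef, depot_rate) {
    i <- findInterval(t, tg, all.inside = TRUE)
    w <- (t - tg[i]) / (tg[i + 1] - tg[i])
    v <- M[i, ] + w * (M[i + 1, ] - M[i, ])
    cpl <- y[1] / v[1]
    upt <- (v[3] + v[5] + v[6] + v[7] + v[8] + v[2]) * cpl
    ret <- v[4] * y[2] + ko_l * y[4] + ko_k * y[5] + ko_r * y[6]
    c(diet_coef * v[9] + depot_rate + ret - upt,   # plasma
      v[3] * cpl - v[4] * y[2],                    # bone
      v[8] * cpl,                                  # brain (sink)
      v[5] * cpl - ko_l * y[4],                    # liver
      v[6] * cpl - ko_k * y[5],                    # kidney
      v[7] * cpl - ko_r * y[6],                    # rest
      v[2] * cpl)                                  # cumulative urine
  }

  depot_rate_at <- function(t) {
    if (nrow(events) == 0) return(if (length(t) == 1) 0 else numeric(length(t)))
    out <- numeric(length(t))
    for (adj in unique(events$adjuvant)) {
      sel <- events$adjuvant == adj
      out <- out + depot_release(events[sel, , drop = FALSE],
                                 k_sc[[adj]], t)
    }
    out
  }
  rhs_full <- function(t, y) rhs_core(t, y, tier_coef(t), depot_rate_at(t))

  # analytic Jacobian (the system is linear in the amounts)
  jac <- function(t, y, parms) {
    i <- findInterval(t, tg, all.inside = TRUE)
    w <- (t - tg[i]) / (tg[i + 1] - tg[i])
    v <- M[i, ] + w * (M[i + 1, ] - M[i, ])
    J <- matrix(0, 7, 7)
    J[1, 1] <- -(v[3] + v[5] + v[6] + v[7] + v[8] + v[2]) / v[1]
    J[1, 2] <- v[4]; J[1, 4] <- ko_l; J[1, 5] <- ko_k; J[1, 6] <- ko_r
    J[2, 1] <- v[3] / v[1]; J[2, 2] <- -v[4]
    J[3, 1] <- v[8] / v[1]
    J[4, 1] <- v[5] / v[1]; J[4, 4] <- -ko_l
    J[5, 1] <- v[6] / v[1]; J[5, 5] <- -ko_k
    J[6, 1] <- v[7] / v[1]; J[6, 6] <- -ko_r
    J[7, 1] <- v[2] / v[1]
    J
  }

  breaks <- dietary_tier_breaks(scheme)
  if (nrow(events) > 0) {
    for (adj in unique(events$adjuvant)) {
      tt <- events$time_days[events$adjuvant == adj]
      breaks <- c(breaks, tt, tt + 1 / k_sc[[adj]])
    }
  }
  breaks <- sort(unique(breaks[breaks > 0 & breaks < horizon_days]))

  y0 <- c(unname(params$birth_amounts[c("plasma", "bone", "brain", "liver",
                                        "kidney", "rest")]), 0)
  names(y0) <- AL_COMPARTMENTS

  list(rhs_core = rhs_core, rhs_full = rhs_full, jac = jac, events = events,
       k_sc = k_sc, breaks = breaks, diet_coef_at = tier_coef,
       depot_rate_at = depot_rate_at, y0 = y0, horizon_days = horizon_days,
       physiology = physiology, scheme = scheme, individual = individual)
}

#' Simulate one individual
#'
#' Integrates the PBTK system from birth with a stiff-capable adaptive
#' solver (`deSolve::lsoda`). Every dose time, depot exhaustion time and
#' dietary-tier change is an exact integration restart, so the
#' piecewise-constant forcing is resolved without solver smearing
#' (`bracket_events = FALSE` disables this; only useful to demonstrate the
#' resulting loss of mass-balance accuracy).
#'
#' @param scenario an `al_scenario`.
#' @param params an `al_parameters` (default: calibrated fixture).
#' @param individual an individual parameter row ([typical_individual()]
#'   gives the population-typical individual, all multipliers 1).
#' @param physiology an `al_physiology` (default: scenario sex).
#' @param ca an `al_ca_kinetics`.
#' @param out_ages output ages in years (default: monthly grid over the
#'   scenario horizon).
#' @param rtol,atol solver tolerances (ug scale).
#' @param bracket_events logical, see above.
#' @return an object of class `al_sim` with elements `age_y`, `time_days`,
#'   `amounts` (times x compartments, ug), `conc` (times x tissues; plasma
#'   in ug/L, tissues in ug/g wet weight), and the inputs needed to audit
#'   mass balance.
#' @export
simulate_individual <- function(scenario, params = default_parameters(),
                                individual = typical_individual(),
                                physiology = physiology_profile(scenario$sex),
                                ca = ca_kinetics(),
                                out_ages = NULL,
                                rtol = 1e-8, atol = 1e-10,
                                bracket_events = TRUE) {
  ctx <- build_model_context(scenario, params, individual, physiology, ca)
  horizon <- ctx$horizon_days
  if (is.null(out_ages)) {
    out_ages <- seq(0, scenario$horizon, by = 1 / 12)
  }
  check_age(out_ages, "out_ages")
  out_t <- sort(unique(out_ages)) * DAYS_PER_YEAR
  out_t <- out_t[out_t <= horizon + 1e-9]

  seg_bounds <- if (bracket_events) {
    sort(unique(c(0, ctx$breaks, horizon)))
  } else {
    c(0, horizon)
  }

  y <- ctx$y0
  rows <- matrix(NA_real_, nrow = length(out_t),
                 ncol = length(AL_COMPARTMENTS))
  if (length(out_t) > 0 && out_t[1] <= 0) rows[1, ] <- y
  filled <- as.integer(length(out_t) > 0 && out_t[1] <= 0)

  for (s in seq_len(length(seg_bounds) - 1)) {
    t0 <- seg_bounds[s]; t1 <- seg_bounds[s + 1]
    mid <- (t0 + t1) / 2
    if (bracket_events) {
      diet_coef <- ctx$diet_coef_at(mid)
      depot <- ctx$depot_rate_at(mid)
      f <- function(t, y, parms) list(ctx$rhs_core(t, y, diet_coef, depot))
    } else {
      f <- function(t, y, parms) list(ctx$rhs_full(t, y))
    }
    inside <- out_t[out_t > t0 + 1e-9 & out_t < t1 - 1e-9]
    times <- sort(unique(c(t0, inside, t1)))
    sol <- deSolve::lsoda(y, times, f, parms = NULL,
                          jacfunc = ctx$jac, jactype = "fullusr",
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[nrow(sol), -1]))) {
      stop(sprintf(
        "solver failure in segment [%.2f, %.2f] d (age %.3f y); state: %s",
        t0, t1, t0 / DAYS_PER_YEAR,
        paste(signif(y, 4), collapse = ", ")))
    }
    y <- sol[nrow(sol), -1]
    take <- which(out_t > t0 + 1e-9 & out_t <= t1 + 1e-9)
    if (length(take) > 0) {
      m <- sol[match(out_t[take], sol[, 1]), -1, drop = FALSE]
      rows[take, ] <- m
      filled <- filled + length(take)
    }
  }
  stopifnot(filled == length(out_t))
  colnames(rows) <- AL_COMPARTMENTS
  # clamp solver-noise negatives (within absolute tolerance) to zero
  rows[rows < 0 & rows > -1e6 * atol] <- 0

  ages <- out_t / DAYS_PER_YEAR
  conc <- cbind(
    plasma = rows[, "plasma"] / plasma_volume(physiology, ages),
    bone   = rows[, "bone"]   / organ_mass(physiology, "bone", ages),
    brain  = rows[, "brain"]  / organ_mass(physiology, "brain", ages),
    liver  = rows[, "liver"]  / organ_mass(physiology, "liver", ages),
    kidney = rows[, "kidney"] / organ_mass(physiology, "kidney", ages),
    rest   = rows[, "rest"]   / organ_mass(physiology, "rest", ages)
  )
  structure(list(age_y = ages, time_days = out_t, amounts = rows,
                 conc = conc, final_state = y,
                 scenario = scenario, params = params,
                 individual = ctx$individual, events = ctx$events,
                 k_sc = ctx$k_sc, physiology = physiology,
                 scheme = ctx$scheme, horizon_days = horizon),
            class = "al_sim")
}

#' Mass-balance audit of a completed simulation
#'
#' Compares the total Al accounted for at the end of the simulation (sum of
#' compartment amounts plus cumulative urine) against the total input
#' computed independently of the solver: birth amounts, the absorbed
#' dietary input integrated by adaptive quadrature over the same intake and
#' body-weight curves, and the closed-form cumulative depot release.
#'
#' @param result an `al_sim`.
#' @return relative mass-balance error (dimensionless).
#' @export
mass_balance <- function(result) {
  stopifnot(inherits(result, "al_sim"))
  horizon <- result$horizon_days
  scheme <- result$scheme
  prof <- result$physiology
  mult <- result$individual$oral_F_mult
  rate <- function(t) {
    dietary_ingestion_rate(scheme, prof, t / DAYS_PER_YEAR) *
      scheme$oral_bioavailability * mult
  }
  bounds <- sort(unique(c(0, dietary_tier_breaks(scheme), horizon)))
  bounds <- bounds[bounds <= horizon]
  diet_int <- 0
  for (i in seq_len(length(bounds) - 1)) {
    diet_int <- diet_int + stats::integrate(
      rate, bounds[i], bounds[i + 1],
      rel.tol = 1e-12, abs.tol = 1e-10, subdivisions = 500L)$value
  }
  released <- 0
  if (nrow(result$events) > 0) {
    for (adj in unique(result$events$adjuvant)) {
      sel <- result$events$adjuvant == adj
      released <- released +
        depot_released_cumulative(result$events[sel, , drop = FALSE],
                                  result$k_sc[[adj]], horizon)
    }
  }
  total_in <- sum(result$params$birth_amounts) + diet_int + released
  accounted <- sum(result$final_state)
  abs(accounted - total_in) / total_in
}

#' @export
print.al_sim <- function(x, ...) {
  cat("<al_sim>", x$scenario$name, "-", length(x$age_y), "output ages,",
      "horizon", max(x$age_y), "y\n")
  invisible(x)
}

#' Tidy data frame of a simulation
#'
#' @param x an `al_sim`.
#' @param ... unused.
#' @return long data.frame: `age_y`, `compartment`, `amount_ug`, `conc`,
#'   `conc_units`.
#' @export
as.data.frame.al_sim <- function(x, ...) {
  tissues <- colnames(x$conc)
  do.call(rbind, lapply(tissues, function(cp) {
    data.frame(age_y = x$age_y, compartment = cp,
               amount_ug = x$amounts[, cp],
               conc = x$conc[, cp],
               conc_units = if (cp == "plasma") "ug/L" else "ug/g ww",
               stringsAsFactors = FALSE)
  }))
}
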