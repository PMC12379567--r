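# Dietary input functions, SCIT dose-event schedules and subcutaneous
# depot release by superposition of zero-order depots.

DAYS_PER_YEAR <- 365.25
TREATMENT_YEAR_DAYS <- 364  # 13 four-weekly doses
AL_ADJUVANTS <- c(Ahy = 0.0024864, Ains = 0.0082392)  # 1/day, zero-order

#' Adjuvant depot release kinetics
#'
#' Zero-order subcutaneous release rates per adjuvant type, interpreted as
#' the fraction of the administered dose released per day: a depot releases
#' `dose * k` per day until exhaustion at `1/k` days (about 402 days for
#' commercial aluminium hydroxide, Ahy, and about 121 days, ca. 4 months,
#' for in-situ precipitated hydroxide, Ains). The rate varies lognormally
#' between individuals with a 50% coefficient of variation.
#'
#' @return list with `k_release` (named vector, 1/day) and `iiv_cv`.
#' @export
adjuvant_kinetics <- function() {
  list(k_release = AL_ADJUVANTS, iiv_cv = 0.50)
}

#' Dietary aluminium intake scheme
#'
#' Age-tiered weekly intake (mg Al per kg body weight per week) with an
#' oral bioavailability fraction. The default follows European dietary
#' surveys: 0.1, 0.2, 0.4 and 0.8 mg/kg/week for infants aged 0-3, 4-6,
#' 7-9 and 10-12 months and 0.8 mg/kg/week beyond 12 months (80% of the
#' tolerable weekly intake of 1 mg/kg/week), with an average oral
#' bioavailability of 0.17\%.
#'
#' @param tiers data.frame with columns `age_lo_mo`, `age_hi_mo` (months,
#'   right-open intervals, the last may be `Inf`) and `intake_mg_kg_wk`.
#' @param oral_bioavailability fraction absorbed from the gut.
#' @return an object of class `al_dietary_scheme`.
#' @export
dietary_scheme <- function(tiers = NULL, oral_bioavailability = 0.0017) {
  if (is.null(tiers)) {
    tiers <- data.frame(
      age_lo_mo = c(0, 3, 6, 9, 12),
      age_hi_mo = c(3, 6, 9, 12, Inf),
      intake_mg_kg_wk = c(0.1, 0.2, 0.4, 0.8, 0.8)
    )
  }
  stopifnot(oral_bioavailability > 0, oral_bioavailability < 1)
  if (tiers$age_lo_mo[1] != 0 ||
      any(tiers$age_lo_mo[-1] != tiers$age_hi_mo[-nrow(tiers)]) ||
      !is.infinite(tiers$age_hi_mo[nrow(tiers)])) {
    stop("tiers must partition [0, Inf) in months")
  }
  # zero intake is allowed so that injection-only runs can be expressed
  # (superposition diagnostics); negative intake is not
  if (any(tiers$intake_mg_kg_wk < 0)) stop("intakes must be non-negative")
  structure(list(tiers = tiers, oral_bioavailability = oral_bioavailability),
            class = "al_dietary_scheme")
}

#' Weekly dietary intake tier at a given age
#'
#' @param scheme an `al_dietary_scheme`.
#' @param age age in years (vectorised).
#' @return intake in mg Al/kg/week.
#' @export
dietary_intake_tier <- function(scheme, age) {
  age_mo <- age * 12
  idx <- findInterval(age_mo, scheme$tiers$age_lo_mo)
  scheme$tiers$intake_mg_kg_wk[idx]
}

#' Ingested dietary aluminium rate
#'
#' Continuous (zero-order) ingestion: `tier(age) [mg/kg/wk] * BW(age) [kg]
#' * 1000 / 7` in ug Al/day. The systemic input to plasma is this rate
#' times the oral bioavailability and the individual bioavailability
#' multiplier.
#'
#' @param scheme an `al_dietary_scheme`.
#' @param profile an `al_physiology`.
#' @param age age in years (vectorised).
#' @return ingested rate, ug Al/day.
#' @export
dietary_ingestion_rate <- function(scheme, profile, age) {
  dietary_intake_tier(scheme, age) * body_weight(profile, age) * 1000 / 7
}

#' Tier boundaries of a dietary scheme in days
#' @param scheme an `al_dietary_scheme`.
#' @return vector of ages (days) at which the intake tier changes.
#' @export
dietary_tier_breaks <- function(scheme) {
  b <- scheme$tiers$age_lo_mo[-1]
  b[is.finite(b)] / 12 * DAYS_PER_YEAR
}

#' Define a SCIT maintenance schedule
#'
#' A perennial full-dose maintenance treatment: doses every `interval` days
#' (default 28, the shortest recommended interval), 13 doses per 364-day
#' treatment-year, so that 5, 10 and 40 treatment-years give exactly 65,
#' 130 and 520 doses. Updosing phases carry negligible Al and are omitted.
#'
#' @param start_age age at the first dose, years.
#' @param treatment_years integer number of treatment-years.
#' @param interval days between doses (default 28).
#' @param dose mg Al per dose (default 1.25, the pharmacopoeial maximum).
#' @param adjuvant `"Ahy"` or `"Ains"`.
#' @param n_parallel number of products given in parallel (same days).
#' @return an object of class `al_scit_schedule`.
#' @export
scit_schedule <- function(start_age, treatment_years, interval = 28,
                          dose = 1.25, adjuvant = c("Ahy", "Ains"),
                          n_parallel = 1) {
  adjuvant <- match.arg(adjuvant)
  if (interval <= 0 || dose <= 0) stop("interval and dose must be positive")
  stopifnot(start_age >= 0, treatment_years >= 1, n_parallel >= 1)
  structure(list(start_age = start_age,
                 treatment_years = as.integer(treatment_years),
                 interval = interval, dose = dose, adjuvant = adjuvant,
                 n_parallel = as.integer(n_parallel)),
            class = "al_scit_schedule")
}

#' Expand a SCIT schedule into dose events
#'
#' @param spec an `al_scit_schedule`.
#' @return data.frame of class `al_dose_events` with columns `time_days`,
#'   `amount_mg`, `adjuvant` (one row per administered dose; parallel
#'   products appear as separate rows at the same time).
#' @export
build_scit_schedule <- function(spec) {
  stopifnot(inherits(spec, "al_scit_schedule"))
  n_doses <- 13 * spec$treatment_years
  t0 <- spec$start_age * DAYS_PER_YEAR
  times <- t0 + (seq_len(n_doses) - 1) * spec$interval
  ev <- data.frame(
    time_days = rep(times, each = spec$n_parallel),
    amount_mg = spec$dose,
    adjuvant = spec$adjuvant,
    stringsAsFactors = FALSE
  )
  class(ev) <- c("al_dose_events", "data.frame")
  ev
}

#' Combine dose-event tables
#' @param ... `al_dose_events` data.frames.
#' @return a single `al_dose_events` sorted by time.
#' @export
combine_dose_events <- function(...) {
  evs <- list(...)
  evs <- evs[vapply(evs, function(e) !is.null(e) && nrow(e) > 0, logical(1))]
  if (length(evs) == 0) return(empty_dose_events())
  ev <- do.call(rbind, lapply(evs, as.data.frame))
  ev <- ev[order(ev$time_days), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("al_dose_events", "data.frame")
  ev
}

#' @rdname combine_dose_events
#' @export
empty_dose_events <- function() {
  ev <- data.frame(time_days = numeric(0), amount_mg = numeric(0),
                   adjuvant = character(0), stringsAsFactors = FALSE)
  class(ev) <- c("al_dose_events", "data.frame")
  ev
}

#' Cumulative administered dose
#'
#' @param events an `al_dose_events` data.frame.
#' @return total administered Al, mg.
#' @export
cumulative_dose <- function(events) {
  if (nrow(events) == 0) return(0)
  sum(events$amount_mg)
}

#' Instantaneous depot release rate
#'
#' Superposition of zero-order depots: each dose `j` releases
#' `k_ind * amount_j * 1000` ug/day on `[t_j, t_j + 1/k_ind)` and nothing
#' thereafter; the cumulative release per depot equals the administered
#' amount exactly (100% injection-site bioavailability).
#'
#' @param events an `al_dose_events` data.frame.
#' @param k_ind individual release rate, 1/day (> 0); one shared rate for
#'   all depots of the individual.
#' @param t time since birth, days (vectorised).
#' @return total release rate, ug/day.
#' @export
depot_release <- function(events, k_ind, t) {
  stopifnot(k_ind > 0)
  if (nrow(events) == 0) return(numeric(length(t)))
  dur <- 1 / k_ind
  vapply(t, function(ti) {
    active <- events$time_days <= ti & ti < events$time_days + dur
    k_ind * sum(events$amount_mg[active]) * 1000
  }, numeric(1))
}

#' Cumulative depot release (closed form)
#'
#' @param events an `al_dose_events` data.frame.
#' @param k_ind individual release rate, 1/day.
#' @param t time since birth, days (vectorised).
#' @return cumulative released Al, ug.
#' @export
depot_released_cumulative <- function(events, k_ind, t) {
  stopifnot(k_ind > 0)
  if (nrow(events) == 0) return(numeric(length(t)))
  dur <- 1 / k_ind
  vapply(t, function(ti) {
    el <- pmin(pmax(ti - events$time_days, 0), dur)
    sum(k_ind * events$amount_mg * 1000 * el)
  }, numeric(1))
}
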