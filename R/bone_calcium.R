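# Age-dependent calcium turnover driving the aluminium bone submodel:
# Al uptake into bone is proportional to the Ca accretion flux, and Al
# release from bone follows the fractional Ca release rate.

#' Calcium turnover kinetics
#'
#' Holds the two age-dependent curves of the bone submodel: the Ca
#' accretion (bone formation) flux in mg Ca/day, with its pubertal peak,
#' and the fractional Ca release (remodelling) rate in 1/day, high in
#' infancy and declining to an adult plateau. Defaults are parametric
#' curves for a female reference individual:
#' \deqn{F_{acc}(a) = base + infant \cdot e^{-a/\tau_i} +
#'   peak \cdot e^{-(a - a_p)^2 / 2 s^2}}
#' \deqn{k_{rel}(a) = k_{adult} + (k_{infant} - k_{adult}) e^{-a/\tau_r}}
#'
#' @param accretion_base adult baseline accretion flux, mg Ca/day.
#' @param accretion_infant extra infant accretion at birth, mg Ca/day.
#' @param infant_tau decay scale of the infant component, years.
#' @param peak_amplitude pubertal peak amplitude, mg Ca/day.
#' @param pubertal_peak_age centre of the pubertal peak, years.
#' @param peak_sd width (sd) of the pubertal peak, years.
#' @param release_adult adult fractional release rate, 1/day.
#' @param release_infant fractional release rate at birth, 1/day.
#' @param release_tau decay scale of the release rate decline, years.
#' @return an object of class `al_ca_kinetics` with functions
#'   `accretion(age)` and `release(age)`.
#' @export
ca_kinetics <- function(accretion_base = 250, accretion_infant = 100,
                        infant_tau = 1, peak_amplitude = 300,
                        pubertal_peak_age = 12.5, peak_sd = 1.5,
                        release_adult = 3.5e-4, release_infant = 3e-3,
                        release_tau = 6) {
  stopifnot(accretion_base > 0, accretion_infant >= 0, peak_amplitude >= 0,
            pubertal_peak_age >= 10, pubertal_peak_age <= 15,
            release_adult > 0, release_infant >= release_adult)
  accretion <- function(age) {
    accretion_base + accretion_infant * exp(-age / infant_tau) +
      peak_amplitude * exp(-(age - pubertal_peak_age)^2 / (2 * peak_sd^2))
  }
  release <- function(age) {
    release_adult + (release_infant - release_adult) * exp(-age / release_tau)
  }
  structure(list(accretion = accretion, release = release,
                 pubertal_peak_age = pubertal_peak_age,
                 baseline_adult_accretion = accretion_base),
            class = "al_ca_kinetics")
}

#' Read calcium turnover curves from CSV
#'
#' Columns: `age_y`, `ca_accretion_mg_d`, `ca_release_frac_d`. Curves are
#' linearly interpolated between the tabulated ages and held constant
#' beyond the last age.
#'
#' @param path path to the CSV file.
#' @param pubertal_peak_age documented peak age of the tabulated accretion
#'   curve (default: argmax of the table).
#' @return an `al_ca_kinetics`.
#' @export
read_ca_table <- function(path, pubertal_peak_age = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("age_y", "ca_accretion_mg_d", "ca_release_frac_d")
  if (!all(needed %in% names(tab))) {
    stop("Ca table needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(tab$ca_accretion_mg_d <= 0) || any(tab$ca_release_frac_d <= 0)) {
    stop("Ca fluxes and release rates must be positive")
  }
  acc <- stats::approxfun(tab$age_y, tab$ca_accretion_mg_d, rule = 2)
  rel <- stats::approxfun(tab$age_y, tab$ca_release_frac_d, rule = 2)
  if (is.null(pubertal_peak_age)) {
    pubertal_peak_age <- tab$age_y[which.max(tab$ca_accretion_mg_d)]
  }
  structure(list(accretion = acc, release = rel,
                 pubertal_peak_age = pubertal_peak_age,
                 baseline_adult_accretion = acc(35)),
            class = "al_ca_kinetics")
}

#' Calcium accretion flux at a given age
#'
#' @param kin an `al_ca_kinetics`.
#' @param age age in years (vectorised), in \[0, 50\].
#' @return accretion flux, mg Ca/day.
#' @export
ca_accretion <- function(kin, age) {
  check_age(age)
  kin$accretion(age)
}

#' Fractional bone release rate at a given age
#'
#' Applied as a first-order loss on the bone Al amount, identical to the
#' fractional Ca release of bone remodelling.
#'
#' @param kin an `al_ca_kinetics`.
#' @param age age in years (vectorised), in \[0, 50\].
#' @return release rate, 1/day.
#' @export
bone_release_rate <- function(kin, age) {
  check_age(age)
  kin$release(age)
}

#' Bone coupling constant
#'
#' Proportionality constant linking the Al uptake flux into bone to the Ca
#' accretion flux and the plasma Al concentration.
#'
#' @param kappa_bone (ug Al/day) per (mg Ca/day) per (ug Al/L plasma).
#' @return an object of class `al_bone_coupling`.
#' @export
bone_coupling <- function(kappa_bone) {
  stopifnot(is.finite(kappa_bone), kappa_bone > 0)
  structure(list(kappa_bone = kappa_bone), class = "al_bone_coupling")
}

#' Aluminium uptake flux into bone
#'
#' `flux = kappa_bone * F_acc(age) * c_plasma`; linear in the plasma
#' concentration and proportional to the Ca accretion flux.
#'
#' @param coupling an `al_bone_coupling`.
#' @param kin an `al_ca_kinetics`.
#' @param age age in years.
#' @param c_plasma plasma Al concentration, ug/L (non-negative).
#' @return uptake flux, ug Al/day.
#' @export
bone_uptake_flux <- function(coupling, kin, age, c_plasma) {
  if (any(c_plasma < 0)) stop("c_plasma must be non-negative")
  coupling$kappa_bone * ca_accretion(kin, age) * c_plasma
}
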