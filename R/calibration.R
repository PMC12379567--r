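# Verification oracles (closed-form one-compartment solution, fixed-step
# integrator) and the calibration routine that pins the free rate
# constants to adult background-exposure tissue levels.

#' Closed-form one-compartment trajectory
#'
#' Exact solution of `dA/dt = R(t) - k_el * A` for piecewise-constant
#' input: per segment `A(t) = A0 e^{-k t} + (R/k)(1 - e^{-k t})`.
#'
#' @param k_el elimination rate, 1/day (> 0).
#' @param segments data.frame with columns `t0`, `t1`, `rate` covering the
#'   requested times (contiguous, ascending).
#' @param A0 initial amount at the start of the first segment.
#' @param times output times (days), within the segment span.
#' @return numeric vector of amounts at `times`.
#' @export
analytic_one_compartment <- function(k_el, segments, A0, times) {
  if (k_el <= 0) stop("k_el must be positive")
  stopifnot(all(segments$t1 > segments$t0))
  out <- numeric(length(times))
  A <- A0
  for (s in seq_len(nrow(segments))) {
    t0 <- segments$t0[s]; t1 <- segments$t1[s]; R <- segments$rate[s]
    sel <- times >= t0 & times <= t1
    if (any(sel)) {
      dt <- times[sel] - t0
      out[sel] <- A * exp(-k_el * dt) + (R / k_el) * (1 - exp(-k_el * dt))
    }
    A <- A * exp(-k_el * (t1 - t0)) + (R / k_el) * (1 - exp(-k_el * (t1 - t0)))
  }
  out
}

#' Fixed-step verification integrator
#'
#' Classical fourth-order Runge-Kutta with a fixed step over the same
#' right-hand side and the same event bracketing as the adaptive solver
#' (steps never straddle a dose, exhaustion or dietary-tier time). If
#' instability is detected (non-finite states) the step is halved and the
#' integration restarted, up to `max_halvings` times. Used only for
#' verification, never for production runs.
#'
#' @param scenario an `al_scenario`.
#' @param params an `al_parameters`.
#' @param individual individual parameters.
#' @param physiology an `al_physiology`.
#' @param ca an `al_ca_kinetics`.
#' @param dt target step size in days (<= 0.5).
#' @param out_ages output ages in years.
#' @param max_halvings maximum number of automatic step halvings.
#' @return list `age_y`, `amounts` (times x compartments), `dt_used`.
#' @export
fixed_step_oracle <- function(scenario, params = default_parameters(),
                              individual = typical_individual(),
                              physiology = physiology_profile(scenario$sex),
                              ca = ca_kinetics(), dt = 0.25,
                              out_ages = NULL, max_halvings = 6L) {
  stopifnot(dt > 0, dt <= 0.5)
  ctx <- build_model_context(scenario, params, individual, physiology, ca)
  horizon <- ctx$horizon_days
  if (is.null(out_ages)) out_ages <- seq(0, scenario$horizon, by = 1)
  out_t <- sort(unique(out_ages)) * DAYS_PER_YEAR
  out_t <- out_t[out_t <= horizon + 1e-9]
  seg_bounds <- sort(unique(c(0, ctx$breaks, out_t, horizon)))

  attempt <- function(h_target) {
    y <- ctx$y0
    res <- matrix(NA_real_, length(out_t), length(y))
    if (out_t[1] <= 0) res[1, ] <- y
    for (s in seq_len(length(seg_bounds) - 1)) {
      t0 <- seg_bounds[s]; t1 <- seg_bounds[s + 1]
      diet_coef <- ctx$diet_coef_at((t0 + t1) / 2)
      depot <- ctx$depot_rate_at((t0 + t1) / 2)
      nst <- max(1L, ceiling((t1 - t0) / h_target))
      h <- (t1 - t0) / nst
      t <- t0
      for (j in seq_len(nst)) {
        k1 <- ctx$rhs_core(t, y, diet_coef, depot)
        k2 <- ctx$rhs_core(t + h / 2, y + h / 2 * k1, diet_coef, depot)
        k3 <- ctx$rhs_core(t + h / 2, y + h / 2 * k2, diet_coef, depot)
        k4 <- ctx$rhs_core(t + h, y + h * k3, diet_coef, depot)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        t <- t + h
        # instability: non-finite or unphysically large amounts (> 1 kg Al)
        if (any(!is.finite(y)) || any(abs(y) > 1e9)) return(NULL)
      }
      hit <- which(abs(out_t - t1) < 1e-9)
      if (length(hit) > 0) res[hit, ] <- y
    }
    res
  }

  h <- dt
  for (k in 0:max_halvings) {
    res <- attempt(h)
    if (!is.null(res)) {
      colnames(res) <- AL_COMPARTMENTS
      return(list(age_y = out_t / DAYS_PER_YEAR, amounts = res, dt_used = h))
    }
    h <- h / 2
  }
  stop("fixed-step integrator unstable even at dt = ", h)
}

#' Default calibration targets
#'
#' Adult background-exposure (dietary intake only) levels for the typical
#' individual: plasma 1.4 ug/L at age 40; bone 0.6 ug/g ww at ages 40 and
#' 50; brain 0.23 ug/g ww at age 40 and 0.28 at age 50; liver 1 and
#' kidney 0.5 ug/g ww near steady state (age 40).
#'
#' @return data.frame: `tissue`, `age`, `value`, `weight`.
#' @export
calibration_targets <- function() {
  data.frame(
    tissue = c("plasma", "bone", "bone", "brain", "brain", "liver",
               "kidney"),
    age = c(40, 40, 50, 40, 50, 40, 40),
    value = c(1.4, 0.6, 0.6, 0.23, 0.28, 1, 0.5),
    weight = 1,
    stringsAsFactors = FALSE
  )
}

cal_param_get <- function(params, name) {
  switch(name,
         renal_extraction = params$renal_extraction,
         k_brain_in = params$k_brain_in,
         kappa_bone = params$kappa_bone,
         k_in_liver = params$k_in[["liver"]],
         k_in_kidney = params$k_in[["kidney"]],
         k_in_rest = params$k_in[["rest"]],
         stop("unknown calibration parameter: ", name))
}

cal_param_set <- function(params, name, value) {
  switch(name,
         renal_extraction = {params$renal_extraction <- min(value, 1)},
         k_brain_in = {params$k_brain_in <- value},
         kappa_bone = {params$kappa_bone <- value},
         k_in_liver = {params$k_in[["liver"]] <- value},
         k_in_kidney = {params$k_in[["kidney"]] <- value},
         k_in_rest = {params$k_in[["rest"]] <- value})
  params
}

#' Simulate the typical individual under dietary background exposure and
#' extract target quantities
#'
#' @param params an `al_parameters`.
#' @param targets a targets data.frame (see [calibration_targets()]).
#' @param rtol,atol solver tolerances.
#' @return the targets data.frame with a `predicted` column.
#' @keywords internal
predict_targets <- function(params, targets, rtol = 1e-6, atol = 1e-8) {
  sc <- get_scenario("food_only")
  sim <- simulate_individual(sc, params, out_ages = sort(unique(targets$age)),
                             rtol = rtol, atol = atol)
  targets$predicted <- vapply(seq_len(nrow(targets)), function(i) {
    j <- which(abs(sim$age_y - targets$age[i]) < 1e-9)
    sim$conc[j, targets$tissue[i]]
  }, numeric(1))
  targets
}

#' Calibrate free model parameters against background-exposure targets
#'
#' Weighted least squares on the log scale, minimised with Nelder-Mead
#' from the supplied start values. Targets are medians of the typical
#' (all-multipliers-one) individual, so the objective is deterministic.
#'
#' @param targets data.frame as in [calibration_targets()].
#' @param free character vector of parameter names to fit, subset of
#'   `renal_extraction`, `k_brain_in`, `kappa_bone`, `k_in_liver`,
#'   `k_in_kidney`, `k_in_rest`.
#' @param start an `al_parameters` providing start values and the fixed
#'   parameters.
#' @param maxit maximum Nelder-Mead iterations.
#' @param tol_fail largest acceptable relative deviation of any target
#'   after fitting (default 0.25); exceeding it is an error, never a
#'   silent acceptance.
#' @param rtol,atol solver tolerances used inside the objective.
#' @return list with `params` (fitted `al_parameters`), `report` (targets
#'   with predictions and relative residuals), `convergence`, `value`.
#' @export
calibrate <- function(targets = calibration_targets(),
                      free = c("renal_extraction", "kappa_bone",
                               "k_brain_in", "k_in_liver", "k_in_kidney"),
                      start, maxit = 400, tol_fail = 0.25,
                      rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(start, "al_parameters"), nrow(targets) >= length(free))
  x0 <- log(vapply(free, function(nm) cal_param_get(start, nm), numeric(1)))
  make_params <- function(x) {
    p <- start
    for (i in seq_along(free)) p <- cal_param_set(p, free[i], exp(x[i]))
    p
  }
  obj <- function(x) {
    p <- make_params(x)
    pred <- tryCatch(predict_targets(p, targets, rtol, atol),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred$predicted)) ||
        any(pred$predicted <= 0)) return(1e6)
    sum(pred$weight * (log(pred$predicted) - log(pred$value))^2)
  }
  fit <- stats::optim(x0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  params <- make_params(fit$par)
  report <- predict_targets(params, targets, rtol, atol)
  report$rel_dev <- report$predicted / report$value - 1
  if (any(abs(report$rel_dev) > tol_fail)) {
    bad <- report[abs(report$rel_dev) > tol_fail, ]
    stop("calibration did not reach all targets within ",
         round(100 * tol_fail), "%:\n",
         paste(sprintf("  %s @ %g y: predicted %.3g vs target %.3g (%+.1f%%)",
                       bad$tissue, bad$age, bad$predicted, bad$value,
                       100 * bad$rel_dev), collapse = "\n"))
  }
  list(params = params, report = report, convergence = fit$convergence,
       value = fit$value)
}

#' Write fitted parameters as a JSON fixture
#' @param params an `al_parameters`.
#' @param path output path.
#' @param notes optional character notes stored under `provenance`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path, notes = NULL) {
  obj <- list(renal_extraction = params$renal_extraction,
              k_brain_in = params$k_brain_in,
              kappa_bone = params$kappa_bone,
              k_in = as.list(params$k_in),
              k_out = as.list(params$k_out),
              birth_amounts = as.list(params$birth_amounts),
              scale_uptake_with_mass = params$scale_uptake_with_mass)
  if (!is.null(notes)) obj$provenance <- notes
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
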