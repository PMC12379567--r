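# Evaluation layer: percentile summaries with bootstrap confidence
# intervals for the 95th percentile, percentile ratios between treated and
# baseline scenarios, dry-to-wet-weight conversion, tissue thresholds,
# exceedance fractions and report-table assembly. Thresholds enter only
# here; simulation results never depend on them.

# Quantile convention: linear interpolation between order statistics
# (R type 7), fixed for reproducibility.
al_quantile <- function(x, p) stats::quantile(x, p, names = FALSE, type = 7)

#' Percentile summary of per-individual values
#'
#' Empirical median, 5th and 95th percentiles (linear-interpolation
#' convention, quantile type 7).
#'
#' @param values numeric vector, one value per individual (n >= 2).
#' @param probs probabilities (default 0.05, 0.5, 0.95).
#' @return named list `p5`, `median`, `p95`, `n`.
#' @export
percentile_summary <- function(values, probs = c(0.05, 0.5, 0.95)) {
  if (length(values) < 2) stop("need at least two individuals")
  q <- al_quantile(values, probs)
  list(p5 = q[1], median = q[2], p95 = q[3], n = length(values))
}

#' Bootstrap confidence interval for the 95th percentile
#'
#' Nonparametric bootstrap (percentile method): resamples individuals with
#' replacement, recomputes the p95 and returns the central `level`
#' interval of the bootstrap distribution. Seeded and deterministic.
#'
#' @param values numeric vector (n >= 20).
#' @param B bootstrap replicates (default 1000).
#' @param level confidence level (default 0.90).
#' @param seed integer seed.
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_p95_ci <- function(values, B = 1000, level = 0.90, seed = 1) {
  n <- length(values)
  if (n < 20) stop("bootstrap CI for p95 needs at least 20 individuals")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  stat <- vapply(seq_len(B), function(b) {
    al_quantile(values[sample.int(n, n, replace = TRUE)], 0.95)
  }, numeric(1))
  a <- (1 - level) / 2
  ci <- al_quantile(stat, c(a, 1 - a))
  c(lo = ci[1], hi = ci[2])
}

#' Summarize a population run per tissue and age
#'
#' @param run an `al_population_run` (long per-individual table).
#' @param ci logical: add the 90% bootstrap CI of p95 (default TRUE).
#' @param B,ci_seed bootstrap settings.
#' @return data.frame: `age_y`, `compartment`, `n`, `p5`, `median`, `p95`,
#'   `p95_ci_lo`, `p95_ci_hi`.
#' @export
summarize_run <- function(run, ci = TRUE, B = 1000, ci_seed = 1) {
  key <- interaction(run$age_y, run$compartment, drop = TRUE)
  parts <- split(run, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    s <- percentile_summary(d$conc)
    row <- data.frame(age_y = d$age_y[1], compartment = d$compartment[1],
                      n = s$n, p5 = s$p5, median = s$median, p95 = s$p95,
                      p95_ci_lo = NA_real_, p95_ci_hi = NA_real_,
                      stringsAsFactors = FALSE)
    if (ci && s$n >= 20) {
      b <- bootstrap_p95_ci(d$conc, B = B, seed = ci_seed)
      row$p95_ci_lo <- b[["lo"]]; row$p95_ci_hi <- b[["hi"]]
    }
    row
  }))
  out <- out[order(out$compartment, out$age_y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

conc_at_age <- function(run, tissue, age, tol = 1e-6) {
  d <- run[run$compartment == tissue & abs(run$age_y - age) < tol, ]
  if (nrow(d) == 0) {
    stop("no values for tissue '", tissue, "' at age ", age,
         "; include it in out_ages")
  }
  d$conc[order(d$id)]
}

#' Percentile ratios between a treated and a baseline scenario
#'
#' Three ratios of 95th percentiles for one tissue, computed on the same
#' (paired) population: `ratio_5_5` = treated p95 five years after SCIT
#' start over baseline p95 at the same age; `ratio_5_50` = treated p95
#' five years after start over baseline p95 at age 50; `ratio_50_50` =
#' treated over baseline p95, both at age 50.
#'
#' @param treated,baseline `al_population_run` objects on the identical
#'   population (same seed), containing ages `t_start + 5` and 50.
#' @param t_start age at SCIT start, years.
#' @param tissue compartment name.
#' @return list `ratio_5_5`, `ratio_5_50`, `ratio_50_50`.
#' @export
p95_ratios <- function(treated, baseline, t_start, tissue) {
  if (!identical(attr(treated, "seed"), attr(baseline, "seed"))) {
    stop("treated and baseline runs must use the identical population ",
         "(same seed)")
  }
  a5 <- t_start + 5
  p95 <- function(run, age) al_quantile(conc_at_age(run, tissue, age), 0.95)
  list(ratio_5_5 = p95(treated, a5) / p95(baseline, a5),
       ratio_5_50 = p95(treated, a5) / p95(baseline, 50),
       ratio_50_50 = p95(treated, 50) / p95(baseline, 50))
}

#' Dry-to-wet-weight conversion factors and tissue thresholds
#'
#' Conversion factors: bone 0.497 (dry, marrow-free sample vs wet,
#' marrow-including model tissue), brain 0.23, liver 0.25 (derived from
#' the published paired dry/wet values, not itself a published factor).
#' Wet-weight thresholds (ug/g ww): upper limits of normal bone 5,
#' brain 1, liver 4, kidney 1.6; bone critical level 7 (lowest level
#' associated with osteomalacia); bone disease level 30; normal adult
#' steady state liver 1, kidney 0.5; normal plasma range 1-3 ug/L.
#'
#' @return list with `dw_to_ww`, `uln_ww`, `bone_critical`,
#'   `bone_disease`, `normal_steady_state`, `plasma_normal`.
#' @export
threshold_table <- function() {
  list(
    dw_to_ww = c(bone = 0.497, brain = 0.23, liver = 0.25),
    uln_ww = c(bone = 5, brain = 1, liver = 4, kidney = 1.6),
    bone_critical = 7,
    bone_disease = 30,
    normal_steady_state = c(liver = 1, kidney = 0.5),
    plasma_normal = c(lo = 1, hi = 3)
  )
}

#' Convert a dry-weight tissue concentration to wet weight
#'
#' @param value concentration in ug/g dry weight.
#' @param tissue tissue with a registered conversion factor (`bone`,
#'   `brain`, `liver`).
#' @return concentration in ug/g wet weight.
#' @export
convert_dw_ww <- function(value, tissue) {
  f <- threshold_table()$dw_to_ww
  if (!tissue %in% names(f)) {
    stop("no dry-to-wet conversion factor registered for tissue '",
         tissue, "'")
  }
  value * f[[tissue]]
}

#' Fraction of individuals above a threshold
#'
#' @param values per-individual values.
#' @param threshold positive threshold; strict exceedance is counted.
#' @return fraction in \[0, 1\].
#' @export
exceedance_fraction <- function(values, threshold) {
  stopifnot(threshold > 0)
  mean(values > threshold)
}

#' Margin of safety
#'
#' @param threshold toxic/critical reference level.
#' @param level attained level (> 0).
#' @return fold margin `threshold / level`.
#' @export
margin_of_safety <- function(threshold, level) {
  stopifnot(level > 0)
  threshold / level
}

#' Assemble a scenario comparison table
#'
#' One row per treated scenario and tissue (plasma, bone, brain): median
#' and p95 with 90% bootstrap CI five years after SCIT start and (bone,
#' brain) at age 50, plus the three p95 ratios versus the baseline. The
#' baseline scenario appears with dashes in the ratio columns. Raw
#' (unrounded) values are kept; `digits` controls the displayed rounding.
#'
#' @param runs named list of `al_population_run` objects, all on the
#'   identical population; must include `baseline`.
#' @param start_ages named numeric: age at SCIT start for each treated
#'   scenario.
#' @param baseline name of the baseline run (default `"food_only"`).
#' @param ci_seed seed for the bootstrap CIs.
#' @return data.frame with one row per scenario x tissue x timepoint.
#' @export
build_table1 <- function(runs, start_ages, baseline = "food_only",
                         ci_seed = 1) {
  if (!baseline %in% names(runs)) stop("baseline run '", baseline,
                                       "' missing")
  seeds <- lapply(runs, attr, "seed")
  if (length(unique(seeds)) != 1) {
    stop("all runs must be simulated on the identical population ",
         "(common random numbers); seeds differ")
  }
  base <- runs[[baseline]]
  tissues <- intersect(c("plasma", "bone", "brain"),
                       unique(base$compartment))
  rows <- list()
  add_row <- function(scen, tissue, age_label, age, ratios) {
    vals <- conc_at_age(runs[[scen]], tissue, age)
    s <- percentile_summary(vals)
    b <- bootstrap_p95_ci(vals, seed = ci_seed)
    rows[[length(rows) + 1]] <<- data.frame(
      scenario = scen, tissue = tissue, timepoint = age_label,
      age_y = age, m = s$median, p95 = s$p95,
      p95_ci_lo = b[["lo"]], p95_ci_hi = b[["hi"]],
      ratio_5_5 = ratios$ratio_5_5 %||% NA_real_,
      ratio_5_50 = ratios$ratio_5_50 %||% NA_real_,
      ratio_50_50 = ratios$ratio_50_50 %||% NA_real_,
      stringsAsFactors = FALSE)
  }
  treated <- setdiff(names(runs), baseline)
  base_ages <- sort(unique(c(vapply(treated, function(s)
    start_ages[[s]] + 5, numeric(1)), 50)))
  for (age in base_ages) {
    for (tissue in tissues) {
      ok <- tryCatch({conc_at_age(base, tissue, age); TRUE},
                     error = function(e) FALSE)
      if (ok) add_row(baseline, tissue,
                      if (age == 50) "age 50" else paste0("age ", age),
                      age, list())
    }
  }
  for (scen in treated) {
    t5 <- start_ages[[scen]] + 5
    for (tissue in tissues) {
      r <- p95_ratios(runs[[scen]], base, start_ages[[scen]], tissue)
      add_row(scen, tissue, "5y after SCIT start", t5, r)
      if (tissue != "plasma") add_row(scen, tissue, "age 50", 50, r)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a comparison table to CSV and JSON
#' @param tab table from [build_table1()].
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @return `tab`, invisibly.
#' @export
write_table1 <- function(tab, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) utils::write.csv(tab, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(tab, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(tab)
}
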