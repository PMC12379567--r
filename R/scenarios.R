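# Named scenario registry: the dietary background scenario and the SCIT
# treatment scenarios layered on top of it.

#' Define an exposure scenario
#'
#' A scenario is the continuous dietary background (always on) plus zero
#' or more SCIT maintenance blocks, simulated from birth to `horizon`
#' years of age.
#'
#' @param name scenario name.
#' @param dietary an `al_dietary_scheme`.
#' @param scit_blocks list of `al_scit_schedule` (may be empty).
#' @param horizon simulation horizon in years (default 50).
#' @param sex reference sex, `"female"` default.
#' @return an object of class `al_scenario`.
#' @export
scenario <- function(name, dietary = dietary_scheme(), scit_blocks = list(),
                     horizon = 50, sex = "female") {
  stopifnot(inherits(dietary, "al_dietary_scheme"))
  for (b in scit_blocks) {
    stopifnot(inherits(b, "al_scit_schedule"))
    end <- b$start_age + b$treatment_years * TREATMENT_YEAR_DAYS / DAYS_PER_YEAR
    if (end > horizon) stop("SCIT block extends beyond the scenario horizon")
  }
  structure(list(name = name, dietary = dietary, scit_blocks = scit_blocks,
                 horizon = horizon, sex = sex),
            class = "al_scenario")
}

#' All dose events of a scenario
#' @param sc an `al_scenario`.
#' @return an `al_dose_events` data.frame.
#' @export
scenario_dose_events <- function(sc) {
  if (length(sc$scit_blocks) == 0) return(empty_dose_events())
  do.call(combine_dose_events, lapply(sc$scit_blocks, build_scit_schedule))
}

# Registry of built-in scenarios. Doses are 1.25 mg every 28 days with the
# Ahy adjuvant unless stated; consecutive blocks are back-to-back.
al_registry <- function() {
  blk <- function(start, years, adjuvant = "Ahy", n_parallel = 1) {
    scit_schedule(start, years, adjuvant = adjuvant, n_parallel = n_parallel)
  }
  ty <- TREATMENT_YEAR_DAYS / DAYS_PER_YEAR
  list(
    food_only = list(),
    adult_high_ahy_5 = list(blk(35, 5)),
    adol_high_ahy_5 = list(blk(10, 5)),
    child_high_ahy_5 = list(blk(5, 5)),
    child_high_ains_5 = list(blk(5, 5, adjuvant = "Ains")),
    child_high_ahy_2x5 = list(blk(5, 5), blk(5 + 5 * ty, 5)),
    adol_high_ahy_40 = list(blk(10, 40)),
    child_2xhigh_ahy_5 = list(blk(5, 5, n_parallel = 2))
  )
}

#' Names of the built-in scenarios
#' @return character vector.
#' @export
scenario_names <- function() names(al_registry())

#' Retrieve a built-in scenario
#'
#' Built-ins: `food_only` (dietary background only) and seven FOOD+SCIT
#' scenarios: five-year treatments started at 5 (`child_high_ahy_5`,
#' `child_high_ains_5`), 10 (`adol_high_ahy_5`) or 35 years
#' (`adult_high_ahy_5`); two consecutive five-year treatments
#' (`child_high_ahy_2x5`); a 40-year treatment from age 10
#' (`adol_high_ahy_40`); and two parallel products (`child_2xhigh_ahy_5`).
#'
#' @param name registered scenario name.
#' @param horizon simulation horizon in years (default 50).
#' @param sex reference sex.
#' @return an `al_scenario`.
#' @export
get_scenario <- function(name, horizon = 50, sex = "female") {
  reg <- al_registry()
  if (!name %in% names(reg)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  scenario(name, dietary_scheme(), reg[[name]], horizon = horizon, sex = sex)
}

#' Read a scenario from a YAML or JSON configuration file
#'
#' Fields: `name`, optional `horizon`, `sex`, `oral_bioavailability`, and
#' `scit_blocks`: a list of blocks with `start_age_y`, `years`, and
#' optional `interval_d`, `dose_mg`, `adjuvant`, `n_parallel`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `al_scenario`.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configurations")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$name)) stop("scenario config needs a 'name'")
  diet <- dietary_scheme(
    oral_bioavailability = cfg$oral_bioavailability %||% 0.0017)
  n_blocks <- if (is.data.frame(cfg$scit_blocks)) {
    nrow(cfg$scit_blocks)
  } else {
    length(cfg$scit_blocks)
  }
  blocks <- lapply(seq_len(n_blocks), function(i) {
    b <- if (is.data.frame(cfg$scit_blocks)) {
      as.list(cfg$scit_blocks[i, ])
    } else cfg$scit_blocks[[i]]
    scit_schedule(b$start_age_y, b$years,
                  interval = b$interval_d %||% 28,
                  dose = b$dose_mg %||% 1.25,
                  adjuvant = b$adjuvant %||% "Ahy",
                  n_parallel = b$n_parallel %||% 1)
  })
  scenario(cfg$name, diet, blocks, horizon = cfg$horizon %||% 50,
           sex = cfg$sex %||% "female")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a scenario for a population and persist the results
#'
#' Writes the individual parameters, the long concentration table, a
#' per-tissue summary and a JSON manifest (seed, scenario, package
#' version, file list) to `out_dir`. Deterministic for a fixed population.
#'
#' @param sc an `al_scenario` or registered scenario name.
#' @param pop an `al_population`.
#' @param out_dir output directory (created if needed).
#' @param params an `al_parameters`.
#' @param ... passed to [run_population()].
#' @return the population run, invisibly.
#' @export
run_scenario <- function(sc, pop, out_dir, params = default_parameters(),
                         ...) {
  if (is.character(sc)) sc <- get_scenario(sc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- run_population(pop, sc, params, ...)
  write_population(pop, file.path(out_dir, "population.csv"))
  utils::write.csv(as.data.frame(run),
                   file.path(out_dir, "timeseries.csv"), row.names = FALSE)
  summ <- summarize_run(run)
  utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    scenario = sc$name, n = nrow(pop), seed = attr(pop, "seed"),
    sex = attr(pop, "sex"),
    n_failed = attr(run, "n_failed"),
    package_version = as.character(utils::packageVersion("alupbtk")),
    files = c("population.csv", "timeseries.csv", "summary.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(run)
}
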