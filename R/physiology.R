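# Age-dependent anatomy and renal function for a reference individual,
# evaluable continuously from birth to age 50.

AL_ORGANS <- c("bone", "brain", "liver", "kidney", "rest")
AL_MAX_AGE <- 50

#' Read a growth table from CSV
#'
#' The table gives body weight, wet organ masses and plasma volume at a set
#' of age knots. Columns: `age_y`, `bw_kg`, `bone_g`, `brain_g`, `liver_g`,
#' `kidney_g`, `rest_g`, `plasma_L`. Ages must be strictly ascending and
#' start at 0 (birth); all masses must be positive and organ masses must sum
#' to less than body weight at every knot.
#'
#' @param path path to a CSV file with the columns above.
#' @return a `data.frame` of class `al_growth_table`.
#' @export
read_growth_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_growth_table(tab)
}

#' Validate and classify a growth table
#'
#' @param tab data.frame with growth-table columns (see [read_growth_table()]).
#' @return the validated table with class `al_growth_table`.
#' @export
as_growth_table <- function(tab) {
  needed <- c("age_y", "bw_kg", paste0(AL_ORGANS, "_g"), "plasma_L")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("growth table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (tab$age_y[1] != 0 || any(diff(tab$age_y) <= 0)) {
    stop("growth table ages must start at 0 and be strictly ascending")
  }
  vals <- as.matrix(tab[, setdiff(needed, "age_y")])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("growth table masses and volumes must be positive and finite")
  }
  organ_sum <- rowSums(tab[, paste0(AL_ORGANS, "_g")])
  if (any(organ_sum >= tab$bw_kg * 1000)) {
    stop("organ masses must sum to less than body weight at every knot")
  }
  ped <- tab$age_y <= 20
  if (any(diff(tab$bw_kg[ped]) < 0)) {
    stop("body weight must be non-decreasing up to age 20")
  }
  class(tab) <- c("al_growth_table", "data.frame")
  tab
}

#' Default growth table for a reference individual
#'
#' Packaged reference-anthropometry knots (ages 0, 0.25, 0.5, 1, 2, 5, 10,
#' 12, 15, 20 and 50 years). The female table is the package default
#' (adult body weight 60 kg, constant from age 20 on).
#'
#' @param sex `"female"` (default) or `"male"`.
#' @return an `al_growth_table`.
#' @export
default_growth_table <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  path <- system.file("extdata", paste0("growth_", sex, ".csv"),
                      package = "alupbtk", mustWork = TRUE)
  read_growth_table(path)
}

#' Glomerular filtration rate model
#'
#' GFR is modelled as an adult reference value scaled allometrically by body
#' weight and multiplied by a sigmoid (Hill) maturation function of
#' post-menstrual age, so that filtration is low but non-zero at birth and
#' approaches the size-adjusted adult value within the first years of life:
#' \deqn{GFR(a) = GFR_{adult} \cdot (BW(a)/BW_{adult})^{0.75} \cdot
#'   \frac{a_{pm}^h}{a_{pm}^h + T_{50}^h}}
#' with \eqn{a_{pm} = a + } `birth_offset` the post-menstrual age in years.
#'
#' @param adult_gfr adult reference GFR, mL/min (default 100 for a 60 kg
#'   female).
#' @param maturation_halftime post-menstrual age (years) at which maturation
#'   reaches 50% (default 1.06 y, i.e. about 0.3 y after term birth).
#' @param maturation_hill Hill coefficient of the maturation sigmoid.
#' @param size_scaling_exponent allometric body-weight exponent.
#' @param birth_offset gestational length in years added to postnatal age to
#'   give post-menstrual age (default 0.77 y = 40 weeks).
#' @return an object of class `al_gfr_model`.
#' @export
gfr_model <- function(adult_gfr = 100, maturation_halftime = 1.06,
                      maturation_hill = 3.33, size_scaling_exponent = 0.75,
                      birth_offset = 0.77) {
  stopifnot(adult_gfr > 0, maturation_halftime > 0, maturation_hill > 0,
            birth_offset >= 0)
  structure(list(adult_gfr = adult_gfr,
                 maturation_halftime = maturation_halftime,
                 maturation_hill = maturation_hill,
                 size_scaling_exponent = size_scaling_exponent,
                 birth_offset = birth_offset),
            class = "al_gfr_model")
}

#' Renal maturation fraction
#'
#' @param model an `al_gfr_model`.
#' @param age postnatal age in years (vectorised).
#' @return maturation fraction in (0, 1].
#' @export
gfr_maturation <- function(model, age) {
  a <- age + model$birth_offset
  h <- model$maturation_hill
  a^h / (a^h + model$maturation_halftime^h)
}

#' Assemble a physiology profile
#'
#' Combines a growth table and a GFR model into a profile evaluable at any
#' age in \[0, 50\] years. Masses and volumes are interpolated with a
#' monotone piecewise-cubic Hermite scheme on log mass versus age, which
#' preserves the monotonicity of the knots and has continuous derivatives
#' (the ODE right-hand side uses these curves).
#'
#' @param sex `"female"` (default) or `"male"`; selects the packaged growth
#'   table when `growth` is not supplied.
#' @param growth an `al_growth_table` (default: packaged table for `sex`).
#' @param gfr an `al_gfr_model`.
#' @return an object of class `al_physiology`.
#' @export
physiology_profile <- function(sex = c("female", "male"),
                               growth = default_growth_table(sex),
                               gfr = gfr_model()) {
  sex <- match.arg(sex)
  if (!inherits(growth, "al_growth_table")) growth <- as_growth_table(growth)
  stopifnot(inherits(gfr, "al_gfr_model"))
  cols <- c("bw_kg", paste0(AL_ORGANS, "_g"), "plasma_L")
  interp <- lapply(cols, function(cl) {
    stats::splinefun(growth$age_y, log(growth[[cl]]), method = "monoH.FC")
  })
  names(interp) <- cols
  adult_bw <- interp$bw_kg(20)  # log scale
  structure(list(sex = sex, growth = growth, gfr = gfr, interp = interp,
                 log_adult_bw = adult_bw, interpolation = "monoH.FC-log"),
            class = "al_physiology")
}

check_age <- function(age, what = "age") {
  if (any(!is.finite(age)) || any(age < 0) || any(age > AL_MAX_AGE)) {
    stop(what, " must lie in [0, ", AL_MAX_AGE, "] years")
  }
  age
}

#' Body weight at a given age
#'
#' @param profile an `al_physiology`.
#' @param age age in years (vectorised), in \[0, 50\].
#' @return body weight in kg.
#' @export
body_weight <- function(profile, age) {
  check_age(age)
  exp(profile$interp$bw_kg(age))
}

#' Wet organ mass at a given age
#'
#' @param profile an `al_physiology`.
#' @param organ one of `"bone"`, `"brain"`, `"liver"`, `"kidney"`, `"rest"`.
#' @param age age in years (vectorised), in \[0, 50\].
#' @return organ mass in g.
#' @export
organ_mass <- function(profile, organ, age) {
  organ <- match.arg(organ, AL_ORGANS)
  check_age(age)
  exp(profile$interp[[paste0(organ, "_g")]](age))
}

#' Plasma volume at a given age
#'
#' @param profile an `al_physiology`.
#' @param age age in years (vectorised), in \[0, 50\].
#' @return plasma volume in L.
#' @export
plasma_volume <- function(profile, age) {
  check_age(age)
  exp(profile$interp$plasma_L(age))
}

#' Glomerular filtration rate at a given age
#'
#' @param profile an `al_physiology`.
#' @param age age in years (vectorised), age >= 0.
#' @param individual_scale positive individual multiplier (default 1).
#' @return GFR in mL/min.
#' @export
gfr <- function(profile, age, individual_scale = 1) {
  stopifnot(individual_scale > 0)
  check_age(age)
  m <- profile$gfr
  size <- exp(m$size_scaling_exponent *
                (profile$interp$bw_kg(age) - profile$log_adult_bw))
  m$adult_gfr * size * gfr_maturation(m, age) * individual_scale
}

#' @export
print.al_physiology <- function(x, ...) {
  cat("<al_physiology>", x$sex, "reference individual;",
      nrow(x$growth), "growth knots;",
      "adult GFR", x$gfr$adult_gfr, "mL/min\n")
  invisible(x)
}
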