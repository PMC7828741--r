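# Survey harmonization: city-dialect raw answers -> one harmonized table.

harmonized_levels <- function() {
  list(
    sex = c("male", "female"),
    age_group = c("18-29", "30-49", "ge50"),
    marital = c("single", "partner"),
    education = c("primary", "secondary", "college", "masters_plus"),
    ses3 = ses_levels(),
    car = c("yes", "no"),
    health3 = c("excellent", "good", "fair"),
    bmi_cat = c("under", "normal", "over", "obese"),
    yesno = c("yes", "no"),
    activity = c("cycling", "rollerblading", "walking", "running", "other"),
    time_cat = c("lt3h", "3-4h", "ge4h"),
    freq_cat = c("ge4_per_month", "two_three_per_month", "one_per_month",
                 "ge1_per_year"),
    companion = c("alone", "accompanied"),
    safety3 = c("unsafe", "safe", "neither")
  )
}

#' Load a harmonization codebook
#'
#' The codebook maps each city's raw survey columns and answer codes to the
#' harmonized variables, and records which variables a survey lacks (absent
#' entries are harmonized as explicit missing, never imputed). The bundled
#' default covers the four survey dialects: DANE strata 1-6 (Bogota,
#' Santiago de Cali), the Chilean E/D/C3/C2/ABC1 scheme, and the 3-level
#' Mexican coding, plus birthdate-vs-age differences and per-city variable
#' availability.
#'
#' @param path Path to a codebook YAML; default is the bundled codebook.
#' @return A list with `default_observation_date` and `cities`.
#' @export
default_codebook <- function(path = system.file("extdata", "codebook.yaml",
                                                package = "ciclovia")) {
  cb <- yaml::read_yaml(path)
  if (is.null(cb$cities) || length(cb$cities) == 0) {
    abort("codebook has no `cities` block.", class = "ciclovia_codebook_error")
  }
  for (city in names(cb$cities)) {
    for (v in names(cb$cities[[city]])) {
      spec <- cb$cities[[city]][[v]]
      if (is.null(spec$column) || (is.null(spec$map) && is.null(spec$kind))) {
        abort(sprintf("codebook entry %s/%s needs `column` and `map` or `kind`.",
                      city, v), class = "ciclovia_codebook_error")
      }
    }
  }
  cb
}

map_raw_values <- function(raw, map, city, variable) {
  raw_chr <- as.character(raw)
  out <- unlist(map)[raw_chr]
  bad <- !is.na(raw_chr) & is.na(out)
  if (any(bad)) {
    abort(sprintf("unknown raw %s code(s) for city '%s': %s",
                  variable, city,
                  paste(unique(raw_chr[bad]), collapse = ", ")),
          class = "ciclovia_codebook_error")
  }
  unname(out)
}

#' Harmonize a city-specific SES code
#'
#' Merges city stratification schemes into three ordinal levels: DANE strata
#' 1-2 -> low, 3-4 -> middle, 5-6 -> high (Bogota, Santiago de Cali);
#' Chilean E and D -> low, C3 and C2 -> middle, ABC1 -> high; the Mexican
#' low/middle/high coding passes through.
#'
#' @param raw_code Vector of raw SES codes.
#' @param city Codebook city name (e.g. `"bogota"`).
#' @param codebook A codebook list from [default_codebook()].
#' @return Factor with levels low/middle/high.
#' @examples
#' harmonize_ses(c(3, 5), "bogota")
#' harmonize_ses("C2", "santiago_chile")
#' @export
harmonize_ses <- function(raw_code, city, codebook = default_codebook()) {
  spec <- codebook$cities[[city]]$ses
  if (is.null(spec)) {
    abort(sprintf("city '%s' has no SES mapping in the codebook.", city),
          class = "ciclovia_codebook_error")
  }
  factor(map_raw_values(raw_code, spec$map, city, "SES"), levels = ses_levels())
}

completed_years <- function(birthdate, observation_date) {
  b <- as.POSIXlt(as.Date(birthdate))
  o <- as.POSIXlt(as.Date(observation_date))
  (o$year - b$year) -
    as.integer(o$mon < b$mon | (o$mon == b$mon & o$mday < b$mday))
}

#' Derive the harmonized age group
#'
#' Age is counted in completed years at the observation date (from a
#' birthdate where the survey recorded one, or taken directly where it
#' recorded age) and classified into 18-29, 30-49 or >= 50 years.
#'
#' @param age Vector of ages in completed years (used when `birthdate` is
#'   NULL).
#' @param birthdate Vector of birth dates (`Date` or ISO strings).
#' @param observation_date Observation date used with `birthdate`.
#' @return Factor with levels `18-29`, `30-49`, `ge50` (NA preserved).
#' @examples
#' derive_age_group(age = c(29, 30, 50))
#' derive_age_group(birthdate = "1988-06-04", observation_date = "2018-06-03")
#' @export
derive_age_group <- function(age = NULL, birthdate = NULL,
                             observation_date = NULL) {
  if (is.null(age)) {
    if (is.null(birthdate)) {
      abort("supply `age` or `birthdate`.", class = "ciclovia_argument_error")
    }
    if (is.null(observation_date)) {
      abort("`observation_date` is required with `birthdate`.",
            class = "ciclovia_argument_error")
    }
    if (any(!is.na(birthdate) &
            as.Date(birthdate) > as.Date(observation_date))) {
      abort("birthdate after the observation date.",
            class = "ciclovia_validation_error")
    }
    age <- rep(NA_real_, length(birthdate))
    ok <- !is.na(birthdate)
    age[ok] <- completed_years(birthdate[ok], observation_date)
  }
  if (any(!is.na(age) & age < 18)) {
    abort("participants must be at least 18 years old.",
          class = "ciclovia_validation_error")
  }
  lv <- harmonized_levels()$age_group
  cls <- ifelse(age <= 29, lv[1], ifelse(age <= 49, lv[2], lv[3]))
  factor(cls, levels = lv)
}

#' Classify body mass index
#'
#' BMI = weight / height^2 (kg/m^2), classified as underweight (< 18.5),
#' normal (18.5-24.9), overweight (25.0-29.9) or obese (>= 30.0).
#'
#' @param weight_kg,height_m Positive numeric vectors.
#' @return Factor with levels under/normal/over/obese (NA preserved).
#' @examples
#' classify_bmi(80, 1.60)  # obese (BMI 31.25)
#' @export
classify_bmi <- function(weight_kg, height_m) {
  if (any(!is.na(weight_kg) & weight_kg <= 0) ||
      any(!is.na(height_m) & height_m <= 0)) {
    abort("weight and height must be positive.",
          class = "ciclovia_validation_error")
  }
  bmi <- weight_kg / height_m^2
  lv <- harmonized_levels()$bmi_cat
  cls <- ifelse(bmi < 18.5, lv[1],
         ifelse(bmi < 25, lv[2],
         ifelse(bmi < 30, lv[3], lv[4])))
  factor(cls, levels = lv)
}

#' Collapse 5-point self-rated health to three categories
#'
#' Raw scale: 1 best to 5 worst; 1 -> excellent, 2 -> good, 3-5 -> fair.
#'
#' @param five_point Integer vector in 1..5.
#' @return Factor with levels excellent/good/fair (NA preserved).
#' @export
classify_health <- function(five_point) {
  if (any(!is.na(five_point) & !(five_point %in% 1:5))) {
    abort("health ratings must be integers in 1..5.",
          class = "ciclovia_validation_error")
  }
  lv <- harmonized_levels()$health3
  cls <- ifelse(five_point == 1, lv[1], ifelse(five_point == 2, lv[2], lv[3]))
  factor(cls, levels = lv)
}

#' WHO aerobic physical-activity guideline classification
#'
#' Meets the recommendation with >= 150 min/week of moderate activity,
#' >= 75 min/week of vigorous activity, or an equivalent combination
#' (each vigorous minute counts double): yes iff
#' `moderate + 2 * vigorous >= 150`.
#'
#' @param minutes_moderate_per_week,minutes_vigorous_per_week Non-negative
#'   weekly minutes.
#' @return Factor yes/no (NA where either input is NA).
#' @examples
#' meets_pa(100, 25)  # yes
#' meets_pa(100, 24)  # no
#' @export
meets_pa <- function(minutes_moderate_per_week, minutes_vigorous_per_week) {
  if (any(!is.na(minutes_moderate_per_week) & minutes_moderate_per_week < 0) ||
      any(!is.na(minutes_vigorous_per_week) & minutes_vigorous_per_week < 0)) {
    abort("minutes must be non-negative.", class = "ciclovia_validation_error")
  }
  eq <- minutes_moderate_per_week + 2 * minutes_vigorous_per_week
  factor(ifelse(eq >= 150, "yes", "no"), levels = harmonized_levels()$yesno)
}

#' Guideline classification for activity during the program
#'
#' Time spent doing physical activity at the event is treated as
#' moderate-intensity, so a participant meets the recommendation during the
#' program iff they report at least 150 minutes.
#'
#' @param program_pa_minutes Non-negative minutes of PA during the program.
#' @return Factor yes/no (NA preserved).
#' @export
meets_pa_program <- function(program_pa_minutes) {
  if (any(!is.na(program_pa_minutes) & program_pa_minutes < 0)) {
    abort("minutes must be non-negative.", class = "ciclovia_validation_error")
  }
  factor(ifelse(program_pa_minutes >= 150, "yes", "no"),
         levels = harmonized_levels()$yesno)
}

#' Collapse the 1-5 safety Likert scale to three categories
#'
#' 1-2 -> unsafe, 3 -> neither, 4-5 -> safe (5 = strongly agrees with the
#' positive safety statement).
#'
#' @param likert_1_to_5 Integer vector in 1..5.
#' @return Factor with levels unsafe/safe/neither (NA preserved).
#' @export
classify_safety <- function(likert_1_to_5) {
  if (any(!is.na(likert_1_to_5) & !(likert_1_to_5 %in% 1:5))) {
    abort("safety ratings must be integers in 1..5.",
          class = "ciclovia_validation_error")
  }
  lv <- harmonized_levels()$safety3
  cls <- ifelse(likert_1_to_5 <= 2, lv[1],
         ifelse(likert_1_to_5 == 3, lv[3], lv[2]))
  factor(cls, levels = lv)
}

classify_time_cat <- function(hours) {
  lv <- harmonized_levels()$time_cat
  factor(ifelse(hours < 3, lv[1], ifelse(hours < 4, lv[2], lv[3])),
         levels = lv)
}

get_raw <- function(raw, spec, city, variable,
                    observation_date = NULL) {
  if (is.null(spec)) return(NULL)  # unavailable in this survey
  if (!spec$column %in% names(raw)) {
    abort(sprintf("raw survey for '%s' lacks column '%s' (%s).",
                  city, spec$column, variable),
          class = "ciclovia_codebook_error")
  }
  x <- raw[[spec$column]]
  if (!is.null(spec$map)) {
    return(map_raw_values(x, spec$map, city, variable))
  }
  switch(spec$kind,
    numeric = as.numeric(x) * (spec$scale %||% 1),
    age_years = as.numeric(x),
    birthdate = x,
    likert5_health = as.integer(x),
    likert5_safety = as.integer(x),
    abort(sprintf("unknown codebook kind '%s' (%s/%s).", spec$kind,
                  city, variable), class = "ciclovia_codebook_error")
  )
}

harmonize_city <- function(raw, city, cb, observation_date) {
  spec <- cb$cities[[city]]
  n <- nrow(raw)
  lv <- harmonized_levels()
  blank <- function(levels) factor(rep(NA_character_, n), levels = levels)
  fct <- function(x, levels) {
    if (is.null(x)) blank(levels) else factor(x, levels = levels)
  }

  age_raw <- get_raw(raw, spec$age, city, "age")
  age_group <- if (is.null(age_raw)) {
    blank(lv$age_group)
  } else if ((spec$age$kind %||% "") == "birthdate") {
    derive_age_group(birthdate = age_raw, observation_date = observation_date)
  } else {
    derive_age_group(age = age_raw)
  }

  w <- get_raw(raw, spec$weight_kg, city, "weight")
  h <- get_raw(raw, spec$height_m, city, "height")
  bmi_cat <- if (is.null(w) || is.null(h)) blank(lv$bmi_cat) else classify_bmi(w, h)

  hp <- get_raw(raw, spec$health, city, "health")
  mod <- get_raw(raw, spec$ltpa_moderate_min, city, "ltpa moderate")
  vig <- get_raw(raw, spec$ltpa_vigorous_min, city, "ltpa vigorous")
  trn <- get_raw(raw, spec$transport_min, city, "transport")
  meets_ltpa <- if (is.null(mod) || is.null(vig)) blank(lv$yesno) else meets_pa(mod, vig)
  meets_transport <- if (is.null(trn)) blank(lv$yesno) else meets_pa(trn, 0)
  meets_overall <- factor(
    dplyr::case_when(
      meets_ltpa == "yes" | meets_transport == "yes" ~ "yes",
      meets_ltpa == "no" & meets_transport == "no" ~ "no",
      TRUE ~ NA_character_
    ), levels = lv$yesno)
  prog <- get_raw(raw, spec$pa_program_min, city, "program PA")
  hrs <- get_raw(raw, spec$time_h, city, "time in program")
  saf <- get_raw(raw, spec$safety, city, "safety")

  tibble(
    city = city,
    id = if ("id" %in% names(raw)) as.character(raw$id) else sprintf("%s_%04d", city, seq_len(n)),
    sex = fct(get_raw(raw, spec$sex, city, "sex"), lv$sex),
    age_group = age_group,
    marital = fct(get_raw(raw, spec$marital, city, "marital"), lv$marital),
    education = fct(get_raw(raw, spec$education, city, "education"), lv$education),
    ses3 = fct(get_raw(raw, spec$ses, city, "SES"), lv$ses3),
    car = fct(get_raw(raw, spec$car, city, "car"), lv$car),
    health3 = if (is.null(hp)) blank(lv$health3) else classify_health(hp),
    bmi_cat = bmi_cat,
    meets_pa_program = if (is.null(prog)) blank(lv$yesno) else meets_pa_program(prog),
    meets_ltpa = meets_ltpa,
    meets_overall = meets_overall,
    meets_transport = meets_transport,
    activity = fct(get_raw(raw, spec$activity, city, "activity"), lv$activity),
    time_cat = if (is.null(hrs)) blank(lv$time_cat) else classify_time_cat(hrs),
    freq_cat = fct(get_raw(raw, spec$frequency, city, "frequency"), lv$freq_cat),
    companion = fct(get_raw(raw, spec$companion, city, "companion"), lv$companion),
    safety3 = if (is.null(saf)) blank(lv$safety3) else classify_safety(saf)
  )
}

#' Harmonize raw city surveys into one analysis table
#'
#' Applies the codebook to each city's raw table, derives the
#' classifications (age group, BMI, health, WHO physical-activity guideline
#' indicators, time/frequency/companion/safety recodes) and row-binds the
#' cities. Variables a survey lacks are explicit missing.
#'
#' @param raw_tables Named list of raw survey tibbles; names must be
#'   codebook city names.
#' @param codebook Codebook from [default_codebook()].
#' @param observation_date Date used to derive age from birthdates; defaults
#'   to the per-table `observation_date` attribute, then to the codebook's
#'   `default_observation_date`.
#' @return A harmonized tibble, one row per participant.
#' @export
harmonize_survey <- function(raw_tables, codebook = default_codebook(),
                             observation_date = NULL) {
  if (is.null(names(raw_tables)) ||
      !all(names(raw_tables) %in% names(codebook$cities))) {
    abort("`raw_tables` must be a named list with codebook city names.",
          class = "ciclovia_codebook_error")
  }
  purrr::map_dfr(names(raw_tables), function(city) {
    obs <- observation_date %||%
      attr(raw_tables[[city]], "observation_date") %||%
      codebook$default_observation_date
    harmonize_city(raw_tables[[city]], city, codebook, obs)
  })
}
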