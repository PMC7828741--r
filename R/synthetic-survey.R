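#' Effect specification for the synthetic survey outcome
#'
#' Fixed-effect log-odds-ratios, city random-intercept SD and marginal
#' distributions used by [generate_survey()]. The outcome is meeting the
#' physical-activity recommendation during the program, drawn from a
#' logistic model with a city-level random intercept:
#' \deqn{logit P(y = 1) = \beta_0 + \beta^T x + u_{city}, \quad
#'       u_{city} \sim N(0, \sigma^2).}
#' Defaults reproduce the study conditions the analysis targets: fixed
#' effects at the published odds ratios (sex 0.90; middle/high SES 0.94 and
#' 1.21; secondary/college/masters education 0.92, 1.43, 1.88), city shares
#' at the four surveys' sample-size proportions, and covariate marginals at
#' the pooled descriptive shares.
#'
#' @param intercept Log-odds intercept for the reference profile.
#' @param log_or Named vector of fixed-effect log-odds-ratios; names
#'   `sex_female`, `ses_middle`, `ses_high`, `edu_secondary`, `edu_college`,
#'   `edu_masters` are all required.
#' @param city_sd Standard deviation (>= 0) of the city random intercept.
#' @param city_share Named positive weights over the four survey cities.
#' @param marginals List of marginal distributions for the descriptive
#'   variables; see the default for the expected entries.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(
    intercept = 0,
    log_or = c(sex_female = log(0.90), ses_middle = log(0.94),
               ses_high = log(1.21), edu_secondary = log(0.92),
               edu_college = log(1.43), edu_masters = log(1.88)),
    city_sd = 0.5,
    city_share = c(bogota = 1001, mexico_city = 721,
                   santiago_cali = 1159, santiago_chile = 401) / 3282,
    marginals = list(
      female = 0.477,
      age_group = c(0.321, 0.458, 0.221),
      education = c(primary = 0.030, secondary = 0.327, college = 0.557,
                    masters_plus = 0.086),
      partner = 0.446,
      car = 0.503,
      health = c(excellent = 0.321, good = 0.349, fair = 0.330),
      activity = c(cycling = 0.527, rollerblading = 0.039, walking = 0.222,
                   running = 0.120, other = 0.092),
      time_h = c(lt3h = 0.544, `3-4h` = 0.238, ge4h = 0.218),
      freq = c(ge4_per_month = 0.495, two_three_per_month = 0.240,
               one_per_month = 0.116, ge1_per_year = 0.149),
      alone = 0.626,
      safety = c(unsafe = 0.216, safe = 0.655, neither = 0.129),
      meets_ltpa = 0.652,
      meets_transport = 0.509,
      bmi_mean = 25.4, bmi_sd = 4.0,
      height_mean = 1.66, height_sd = 0.09
    )) {
  needed <- c("sex_female", "ses_middle", "ses_high", "edu_secondary",
              "edu_college", "edu_masters")
  if (!all(needed %in% names(log_or))) {
    abort(paste("missing effect coefficients:",
                paste(setdiff(needed, names(log_or)), collapse = ", ")),
          class = "ciclovia_config_error")
  }
  if (!is.numeric(city_sd) || city_sd < 0) {
    abort("`city_sd` must be >= 0.", class = "ciclovia_config_error")
  }
  structure(list(intercept = intercept, log_or = log_or, city_sd = city_sd,
                 city_share = city_share / sum(city_share),
                 marginals = marginals),
            class = "effect_spec")
}

# sample a raw dialect code uniformly among the codes mapping to `value`
inverse_code <- function(map, value) {
  cand <- names(map)[unlist(map) == value]
  cand[sample.int(length(cand), 1L)]
}

subtract_years <- function(date, years) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year - years
  out <- as.Date(lt)
  bad <- is.na(out)  # Feb 29 in a non-leap target year
  if (any(bad)) out[bad] <- as.Date(as.POSIXlt(date[bad] - 1)) - 365 * years
  out
}

#' Generate raw city-dialect surveys for synthetic participants
#'
#' Emits one raw table per survey city in that city's dialect (column names,
#' answer codes, birthdate vs. age, per-city variable availability), so the
#' harmonization codebook is genuinely exercised on the way back in. The
#' binary meets-PA-during-program outcome is drawn from the two-level
#' logistic model of the [effect_spec()] and then encoded as minutes of
#' program activity (>= 150 iff the outcome is yes). SES dialect codes are
#' consistent with each participant's SES-of-origin.
#'
#' @param participants Tibble with `id` and `ses_of_origin`
#'   (e.g. [generate_participants()]); an optional `city` column fixes the
#'   survey-city assignment, otherwise cities are drawn from
#'   `effects$city_share`.
#' @param effects An [effect_spec()].
#' @param seed Integer seed (substream `"survey"`).
#' @param codebook Codebook whose dialects to emit.
#' @param observation_date Interview date stored on each table.
#' @return Named list of raw survey tibbles (attribute `observation_date`),
#'   plus attribute `truth`: a tibble with the generating covariates,
#'   city intercepts and outcome for each participant.
#' @export
generate_survey <- function(participants, effects = effect_spec(), seed = 1,
                            codebook = default_codebook(),
                            observation_date = NULL) {
  stopifnot(inherits(effects, "effect_spec"))
  if (!all(c("id", "ses_of_origin") %in% names(participants))) {
    abort("`participants` needs `id` and `ses_of_origin` columns.",
          class = "ciclovia_argument_error")
  }
  obs_date <- as.Date(observation_date %||% codebook$default_observation_date)
  n <- nrow(participants)
  m <- effects$marginals
  lo <- effects$log_or
  cities <- names(effects$city_share)

  with_substream(seed, "survey", {
    city <- if ("city" %in% names(participants)) {
      as.character(participants$city)
    } else {
      sample(cities, n, replace = TRUE, prob = effects$city_share)
    }
    sex <- ifelse(runif(n) < m$female, "female", "male")
    edu <- sample(names(m$education), n, replace = TRUE, prob = m$education)
    agegrp <- sample(1:3, n, replace = TRUE, prob = m$age_group)
    age <- floor(c(runif(n, 18, 30), runif(n, 30, 50),
                   runif(n, 50, 76))[(agegrp - 1) * n + seq_len(n)])
    marital <- ifelse(runif(n) < m$partner, "partner", "single")
    car <- ifelse(runif(n) < m$car, "yes", "no")
    health <- sample(names(m$health), n, replace = TRUE, prob = m$health)
    activity <- sample(names(m$activity), n, replace = TRUE, prob = m$activity)
    timec <- sample(names(m$time_h), n, replace = TRUE, prob = m$time_h)
    hours <- c(runif(n, 0.5, 2.99), runif(n, 3, 3.99), runif(n, 4, 7))[
      (match(timec, names(m$time_h)) - 1) * n + seq_len(n)]
    freq <- sample(names(m$freq), n, replace = TRUE, prob = m$freq)
    compan <- ifelse(runif(n) < m$alone, "alone", "accompanied")
    safety <- sample(names(m$safety), n, replace = TRUE, prob = m$safety)
    height <- rnorm(n, m$height_mean, m$height_sd)
    bmi <- pmax(rnorm(n, m$bmi_mean, m$bmi_sd), 15)
    weight <- bmi * height^2
    ltpa_yes <- runif(n) < m$meets_ltpa
    ltpa_eq <- ifelse(ltpa_yes, 150 + rexp(n, 1 / 90), runif(n, 0, 149))
    vig_share <- runif(n, 0, 0.4)
    vig <- vig_share * ltpa_eq / 2
    mod <- ltpa_eq - 2 * vig
    trans_yes <- runif(n) < m$meets_transport
    trans <- ifelse(trans_yes, 150 + rexp(n, 1 / 60), runif(n, 0, 149))

    ses <- as.character(participants$ses_of_origin)
    u_city <- setNames(rnorm(length(cities), 0, effects$city_sd), cities)
    eta <- effects$intercept +
      lo["sex_female"] * (sex == "female") +
      lo["ses_middle"] * (ses == "middle") +
      lo["ses_high"] * (ses == "high") +
      lo["edu_secondary"] * (edu == "secondary") +
      lo["edu_college"] * (edu == "college") +
      lo["edu_masters"] * (edu == "masters_plus") +
      u_city[city]
    y <- rbinom(n, 1, plogis(eta))
    prog_min <- ifelse(y == 1, 150 + rexp(n, 1 / 60), runif(n, 0, 149))
    birthdate <- subtract_years(obs_date, age) - sample(0:330, n, replace = TRUE)

    # encode in each city's dialect via the codebook's inverse maps
    health_raw <- vapply(health, function(hh) {
      switch(hh, excellent = 1L, good = 2L, sample(3:5, 1L))
    }, integer(1), USE.NAMES = FALSE)
    safety_raw <- vapply(safety, function(ss) {
      switch(ss, unsafe = sample(1:2, 1L), neither = 3L, sample(4:5, 1L))
    }, integer(1), USE.NAMES = FALSE)

    out <- lapply(cities, function(ct) {
      idx <- which(city == ct)
      if (length(idx) == 0) return(NULL)
      spec <- codebook$cities[[ct]]
      raw <- tibble(id = participants$id[idx])
      put <- function(raw, vspec, values) {
        if (is.null(vspec)) return(raw)
        raw[[vspec$column]] <- values
        raw
      }
      enc <- function(vspec, values) {
        vapply(values, function(v) inverse_code(vspec$map, v), character(1))
      }
      raw <- put(raw, spec$sex, enc(spec$sex, sex[idx]))
      if (!is.null(spec$age)) {
        raw[[spec$age$column]] <- if ((spec$age$kind %||% "") == "birthdate") {
          as.character(birthdate[idx])
        } else age[idx]
      }
      raw <- put(raw, spec$marital, enc(spec$marital, marital[idx]))
      raw <- put(raw, spec$education, enc(spec$education, edu[idx]))
      raw <- put(raw, spec$ses, enc(spec$ses, ses[idx]))
      raw <- put(raw, spec$car, enc(spec$car, car[idx]))
      if (!is.null(spec$health)) raw[[spec$health$column]] <- health_raw[idx]
      if (!is.null(spec$weight_kg)) {
        raw[[spec$weight_kg$column]] <- round(weight[idx], 1)
      }
      if (!is.null(spec$height_m)) {
        sc <- spec$height_m$scale %||% 1
        raw[[spec$height_m$column]] <- round(height[idx] / sc, 3)
      }
      if (!is.null(spec$pa_program_min)) {
        raw[[spec$pa_program_min$column]] <- round(prog_min[idx], 1)
      }
      if (!is.null(spec$ltpa_moderate_min)) {
        raw[[spec$ltpa_moderate_min$column]] <- round(mod[idx], 1)
        raw[[spec$ltpa_vigorous_min$column]] <- round(vig[idx], 1)
      }
      if (!is.null(spec$transport_min)) {
        raw[[spec$transport_min$column]] <- round(trans[idx], 1)
      }
      raw <- put(raw, spec$activity, enc(spec$activity, activity[idx]))
      if (!is.null(spec$time_h)) raw[[spec$time_h$column]] <- round(hours[idx], 2)
      raw <- put(raw, spec$frequency, enc(spec$frequency, freq[idx]))
      raw <- put(raw, spec$companion, enc(spec$companion, compan[idx]))
      if (!is.null(spec$safety)) raw[[spec$safety$column]] <- safety_raw[idx]
      attr(raw, "observation_date") <- as.character(obs_date)
      raw
    })
    names(out) <- cities
    out <- out[!vapply(out, is.null, logical(1))]
    attr(out, "truth") <- tibble(
      id = participants$id, city = city, sex = sex, ses3 = ses,
      education = edu, eta = as.numeric(eta), y = y
    )
    out
  })
}
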