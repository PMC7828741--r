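# Codebook harmonization, derived classifications, descriptive tables,
# Pearson chi-squared.

test_that("SES merge rules map every dialect correctly", {
  expect_equal(as.character(harmonize_ses(c(1, 2, 3, 4, 5, 6), "bogota")),
               c("low", "low", "middle", "middle", "high", "high"))
  expect_equal(as.character(harmonize_ses(3, "bogota")), "middle")
  expect_equal(as.character(harmonize_ses(c("E", "D", "C3", "C2", "ABC1"),
                                          "santiago_chile")),
               c("low", "low", "middle", "middle", "high"))
  expect_equal(as.character(harmonize_ses("C2", "santiago_chile")), "middle")
  expect_equal(as.character(harmonize_ses("ABC1", "santiago_chile")), "high")
  expect_equal(as.character(harmonize_ses(c("bajo", "medio", "alto"),
                                          "mexico_city")),
               c("low", "middle", "high"))
  err <- expect_error(harmonize_ses("7", "bogota"),
                      class = "ciclovia_codebook_error")
  expect_match(conditionMessage(err), "bogota")
  expect_match(conditionMessage(err), "7")
})

test_that("codebook totality: every legal raw value maps, every other raises", {
  cb <- default_codebook()
  for (city in names(cb$cities)) {
    for (v in names(cb$cities[[city]])) {
      spec <- cb$cities[[city]][[v]]
      if (is.null(spec$map)) next
      raw <- tibble::tibble(x = names(spec$map))
      names(raw) <- spec$column
      expect_silent(out <- ciclovia:::get_raw(raw, spec, city, v))
      expect_false(anyNA(out))
      bad <- raw
      bad[[spec$column]] <- paste0(bad[[spec$column]], "_zz")
      expect_error(ciclovia:::get_raw(bad, spec, city, v),
                   class = "ciclovia_codebook_error")
    }
  }
})

test_that("age groups use completed years with the stated boundaries", {
  expect_equal(as.character(derive_age_group(age = c(18, 29, 30, 49, 50, 80))),
               c("18-29", "18-29", "30-49", "30-49", "ge50", "ge50"))
  # birthdate exactly 30 years before observation -> 30-49
  expect_equal(as.character(derive_age_group(birthdate = "1988-06-03",
                                             observation_date = "2018-06-03")),
               "30-49")
  # 29 years + 364 days old -> still 18-29 under completed years
  expect_equal(as.character(derive_age_group(birthdate = "1988-06-04",
                                             observation_date = "2018-06-02")),
               "18-29")
  expect_error(derive_age_group(age = 17), class = "ciclovia_validation_error")
  expect_error(derive_age_group(birthdate = "2030-01-01",
                                observation_date = "2018-06-03"),
               class = "ciclovia_validation_error")
})

test_that("BMI categories follow the WHO cut-points", {
  expect_equal(as.character(classify_bmi(24.9, 1)), "normal")
  expect_equal(as.character(classify_bmi(25.0, 1)), "over")
  expect_equal(as.character(classify_bmi(80, 1.60)), "obese")  # BMI 31.25
  expect_equal(as.character(classify_bmi(18.4, 1)), "under")
  expect_equal(as.character(classify_bmi(18.5, 1)), "normal")
  expect_error(classify_bmi(-1, 1.7), class = "ciclovia_validation_error")
})

test_that("health and safety recodes collapse the 5-point scales", {
  expect_equal(as.character(classify_health(1:5)),
               c("excellent", "good", "fair", "fair", "fair"))
  expect_error(classify_health(6), class = "ciclovia_validation_error")
  expect_equal(as.character(classify_safety(1:5)),
               c("unsafe", "unsafe", "neither", "safe", "safe"))
  expect_error(classify_safety(0), class = "ciclovia_validation_error")
})

test_that("WHO guideline arithmetic counts vigorous minutes double", {
  expect_equal(as.character(meets_pa(c(150, 0, 100, 100, 0),
                                     c(0, 75, 25, 24, 0))),
               c("yes", "yes", "yes", "no", "no"))
  expect_equal(as.character(meets_pa_program(c(180, 150, 90))),
               c("yes", "yes", "no"))
  expect_error(meets_pa(-5, 0), class = "ciclovia_validation_error")
})

test_that("percentages close to 100 within variable and city", {
  city <- tiny_city(seed = 19)
  parts <- generate_participants(city, 400, seed = 19)
  h <- harmonize_survey(generate_survey(parts, seed = 19))
  tab <- descriptive_table(h)
  closure <- tidy(tab) |>
    dplyr::group_by(variable, city) |>
    dplyr::summarise(total = sum(pct), .groups = "drop")
  expect_equal(closure$total, rep(100, nrow(closure)), tolerance = 0.01)
  # unavailable variables contribute no cells for that city
  cells <- tidy(tab)
  expect_equal(nrow(cells[cells$variable == "bmi_cat" &
                            cells$city == "santiago_chile", ]), 0)
})

test_that("chi-squared matches the textbook formula and known cases", {
  even <- matrix(25, 2, 2)
  res <- pearson_chi2(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  m <- matrix(c(10, 20, 20, 10), 2)
  expect_equal(pearson_chi2(m)$statistic, oracle_chi2(m), tolerance = 1e-9)
  withr::with_seed(13, {
    for (i in 1:200) {
      mm <- matrix(rpois(12, lambda = 30) + 1, nrow = 3)
      expect_equal(suppressWarnings(pearson_chi2(mm)$statistic),
                   oracle_chi2(mm), tolerance = 1e-9)
    }
  })
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)),
               class = "ciclovia_degenerate_error")
  expect_warning(pearson_chi2(matrix(c(2, 3, 3, 2), 2)), "expected")
})

test_that("chi-squared rejection rate is calibrated under independence", {
  withr::with_seed(29, {
    rej <- mean(replicate(2000, {
      m <- matrix(rmultinom(1, 300, rep(1 / 12, 12)), nrow = 3)
      suppressWarnings(pearson_chi2(m)$p_value) < 0.05
    }))
  })
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("pooled descriptive shares reproduce the published counts table", {
  counts <- program_survey_counts()
  pooled <- summarise_counts(counts) |> dplyr::filter(city == "overall")
  get <- function(v, cat) pooled$pct[pooled$variable == v &
                                       pooled$category == cat]
  expect_equal(get("sex", "male"), 52.29, tolerance = 0.005)
  expect_equal(get("meets_pa_program", "yes"), 51.13, tolerance = 0.005)
  expect_equal(get("activity", "cycling"), 52.67, tolerance = 0.005)
  expect_equal(get("companion", "alone"), 62.60, tolerance = 0.005)
  expect_equal(get("safety3", "safe"), 65.51, tolerance = 0.005)
  expect_equal(get("bmi_cat", "normal"), 52.31, tolerance = 0.005)
})
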