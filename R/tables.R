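#' Pearson chi-squared test of independence
#'
#' Classic Pearson statistic \eqn{\sum (O - E)^2 / E} on a contingency table
#' of counts, without continuity correction, with p-value from the
#' chi-squared distribution on (R-1)(C-1) degrees of freedom. A warning is
#' emitted when any expected count is below 5.
#'
#' @param contingency A matrix or table of non-negative counts with at least
#'   2 rows and 2 columns.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `min_expected`.
#' @examples
#' pearson_chi2(matrix(c(10, 20, 20, 10), 2))
#' @export
pearson_chi2 <- function(contingency) {
  m <- as.matrix(contingency)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("contingency table needs at least 2 rows and 2 columns.",
          class = "ciclovia_validation_error")
  }
  if (any(m < 0) || anyNA(m)) {
    abort("counts must be non-negative and non-missing.",
          class = "ciclovia_validation_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("degenerate table: a row or column marginal is zero.",
          class = "ciclovia_degenerate_error")
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  min_exp <- min(res$expected)
  if (min_exp < 5) {
    warn(sprintf("smallest expected count is %.2f (< 5); the chi-squared approximation may be poor.",
                 min_exp))
  }
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value), min_expected = min_exp)
}

# long counts (variable, category, city, n) -> per-city and pooled percentages
percentify_counts <- function(counts) {
  per_city <- counts |>
    dplyr::group_by(.data$variable, .data$city) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  pooled <- counts |>
    dplyr::group_by(.data$variable, .data$category) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop_last") |>
    dplyr::mutate(city = "overall", pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  dplyr::bind_rows(per_city, pooled[, names(per_city)])
}

#' Pooled and per-city percentages from aggregated counts
#'
#' Turns a long table of per-city category counts into per-city and pooled
#' column percentages. Pooled percentages come from summed counts, so each
#' variable's denominator is the participants with a non-missing answer
#' (complete-case, per variable): cities where a variable was not collected
#' simply contribute no rows.
#'
#' @param counts Tibble with columns `variable`, `category`, `city`, `n`.
#' @param variable Optional single variable name to filter on.
#' @return Tibble (`variable`, `category`, `city`, `n`, `pct`) including
#'   `city == "overall"` rows.
#' @examples
#' counts <- tibble::tibble(variable = "sex",
#'   category = rep(c("male", "female"), 2),
#'   city = rep(c("a", "b"), each = 2), n = c(60, 40, 55, 45))
#' summarise_counts(counts)
#' @export
summarise_counts <- function(counts, variable = NULL) {
  req <- c("variable", "category", "city", "n")
  if (!all(req %in% names(counts))) {
    abort(paste("`counts` must have columns", paste(req, collapse = ", ")),
          class = "ciclovia_argument_error")
  }
  if (!is.null(variable)) {
    counts <- counts[counts$variable %in% variable, , drop = FALSE]
  }
  percentify_counts(as_tibble(counts)) |>
    dplyr::arrange(.data$variable, .data$city, .data$category)
}

#' Descriptive table with per-variable chi-squared tests
#'
#' Absolute and relative frequencies of the harmonized categorical
#' variables, per city and pooled, with a Pearson chi-squared test of the
#' variable-by-city contingency table for each variable. Denominators are
#' complete-case per variable and city; cities with no non-missing values
#' for a variable contribute no rows (and no column to its test).
#'
#' @param harmonized Harmonized survey tibble from [harmonize_survey()].
#' @param variables Character vector of harmonized variable names to
#'   tabulate; the default covers every categorical variable.
#' @return A list of class `ciclovia_table`: `cells` (tibble `variable`,
#'   `category`, `city`, `n`, `pct`) and `tests` (tibble `variable`,
#'   `statistic`, `df`, `p_value`, `min_expected`). `tidy()` returns the
#'   cells, `glance()` the tests.
#' @export
descriptive_table <- function(harmonized,
                              variables = c("sex", "age_group", "marital",
                                            "education", "ses3", "car",
                                            "health3", "bmi_cat",
                                            "meets_pa_program", "meets_ltpa",
                                            "meets_overall", "meets_transport",
                                            "activity", "time_cat", "freq_cat",
                                            "companion", "safety3")) {
  if (nrow(harmonized) < 1) {
    abort("no rows to tabulate.", class = "ciclovia_validation_error")
  }
  variables <- intersect(variables, names(harmonized))
  counts <- purrr::map_dfr(variables, function(v) {
    harmonized |>
      dplyr::filter(!is.na(.data[[v]])) |>
      dplyr::count(city = .data$city, category = as.character(.data[[v]])) |>
      dplyr::mutate(variable = v)
  })
  cells <- percentify_counts(counts[, c("variable", "category", "city", "n")])
  tests <- purrr::map_dfr(variables, function(v) {
    sub <- counts[counts$variable == v, , drop = FALSE]
    tab <- tidyr::pivot_wider(sub[, c("category", "city", "n")],
                              names_from = "city", values_from = "n",
                              values_fill = 0)
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (nrow(m) < 2 || ncol(m) < 2) {
      return(tibble(variable = v, statistic = NA_real_, df = NA_real_,
                    p_value = NA_real_, min_expected = NA_real_))
    }
    dplyr::bind_cols(tibble(variable = v),
                     suppressWarnings(pearson_chi2(m)))
  })
  structure(list(cells = cells, tests = tests), class = "ciclovia_table")
}

#' @export
print.ciclovia_table <- function(x, ...) {
  cat(sprintf("<ciclovia_table> %d variables, %d cells\n",
              nrow(x$tests), nrow(x$cells)))
  invisible(x)
}

#' @rdname descriptive_table
#' @param x A `ciclovia_table`.
#' @param ... Unused.
#' @export
tidy.ciclovia_table <- function(x, ...) x$cells

#' @rdname descriptive_table
#' @export
glance.ciclovia_table <- function(x, ...) x$tests

#' Aggregated counts from four open-streets intercept surveys
#'
#' Published per-city participant counts (Bogota, Mexico City, Santiago de
#' Cali, Santiago de Chile; 3282 adults) for the descriptive variables, as a
#' long counts table suitable for [summarise_counts()]. Variables a city did
#' not collect have no rows for that city.
#'
#' @return Tibble with `variable`, `category`, `city`, `n`.
#' @export
program_survey_counts <- function() {
  path <- system.file("extdata", "program_survey_counts.csv",
                      package = "ciclovia")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
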