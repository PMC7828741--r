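#' Generate geographic units for a synthetic city
#'
#' Draws one square geographic unit per grid cell. Each unit's SES
#' composition comes from a Dirichlet distribution whose mean shifts
#' monotonically along the x-axis: low-SES mass is highest at the west edge
#' and high-SES mass at the east edge, with `gradient_strength` controlling
#' the sorting and `mixing_noise` the within-unit diversity. Total population
#' is Poisson and split multinomially by the composition. The unit SES score
#' is the population-weighted mean of the group ranks (1 = low, 2 = middle,
#' 3 = high), and the unit SES category is the dominant group.
#'
#' @param config A [city_config()].
#' @return A tibble with one row per unit: identifiers, grid position,
#'   rectangle bounds in meters, per-group population counts and
#'   proportions, total population, `ses_score` and `ses_category`.
#' @examples
#' units <- generate_units(city_config(grid_rows = 4, grid_cols = 6, seed = 1))
#' @export
generate_units <- function(config) {
  stopifnot(inherits(config, "city_config"))
  R <- config$grid_rows; C <- config$grid_cols; side <- config$unit_side_m
  n <- R * C
  grid <- tidyr::expand_grid(row = seq_len(R), col = seq_len(C))

  # expected composition: multinomial logit in the unit's centered x position
  u <- (grid$col - 0.5) / C
  ranks_centered <- c(-1, 0, 1)
  logits <- outer(2 * u - 1, ranks_centered) * config$gradient_strength
  pmean <- exp(logits)
  pmean <- pmean / rowSums(pmean)

  with_substream(config$seed, "units", {
    alpha <- config$mixing_noise * pmean
    g <- matrix(rgamma(n * 3L, shape = as.vector(alpha)), nrow = n)
    pi_draw <- g / rowSums(g)
    pop <- rpois(n, config$pop_per_unit_mean)
    counts <- t(vapply(seq_len(n), function(i) {
      if (pop[i] == 0) return(c(0, 0, 0))
      as.numeric(rmultinom(1, pop[i], pi_draw[i, ]))
    }, numeric(3)))
  })

  prop <- counts / ifelse(pop > 0, pop, 1)
  prop[pop == 0, ] <- pi_draw[pop == 0, , drop = FALSE]
  score <- as.numeric(prop %*% c(1, 2, 3))
  dominant <- apply(counts, 1, which.max)  # ties go to the lower rank

  tibble(
    unit_id = sprintf("u%04d", seq_len(n)),
    row = grid$row, col = grid$col,
    xmin = (grid$col - 1) * side, xmax = grid$col * side,
    ymin = (grid$row - 1) * side, ymax = grid$row * side,
    pop_low = counts[, 1], pop_middle = counts[, 2], pop_high = counts[, 3],
    pop_total = as.numeric(pop),
    prop_low = prop[, 1], prop_middle = prop[, 2], prop_high = prop[, 3],
    ses_score = score,
    ses_category = factor(ses_levels()[dominant], levels = ses_levels())
  )
}

#' Build a unit table from explicit population counts
#'
#' Deterministic companion to [generate_units()]: lays out square units on a
#' grid and fills compositions from counts you supply. Useful for planted
#' scenarios where the SES landscape must be known exactly (e.g. equal
#' populations with strictly increasing scores along the x-axis).
#'
#' @param counts A data frame with columns `row`, `col`, `pop_low`,
#'   `pop_middle`, `pop_high` (one row per grid cell).
#' @param unit_side_m Side length of each square unit in meters.
#' @return A unit tibble with the same columns as [generate_units()].
#' @examples
#' units_from_counts(data.frame(row = 1, col = 1:4, pop_low = c(9, 6, 3, 0),
#'                              pop_middle = 1, pop_high = c(0, 3, 6, 9)))
#' @export
units_from_counts <- function(counts, unit_side_m = 500) {
  req <- c("row", "col", "pop_low", "pop_middle", "pop_high")
  if (!all(req %in% names(counts))) {
    abort(paste("`counts` must have columns", paste(req, collapse = ", ")),
          class = "ciclovia_argument_error")
  }
  counts <- dplyr::arrange(as_tibble(counts), .data$row, .data$col)
  cm <- as.matrix(counts[, c("pop_low", "pop_middle", "pop_high")])
  if (any(cm < 0)) abort("counts must be non-negative.", class = "ciclovia_argument_error")
  pop <- rowSums(cm)
  prop <- cm / ifelse(pop > 0, pop, 1)
  dominant <- apply(cm, 1, which.max)
  side <- unit_side_m
  tibble(
    unit_id = sprintf("u%04d", seq_len(nrow(counts))),
    row = as.integer(counts$row), col = as.integer(counts$col),
    xmin = (counts$col - 1) * side, xmax = counts$col * side,
    ymin = (counts$row - 1) * side, ymax = counts$row * side,
    pop_low = cm[, 1], pop_middle = cm[, 2], pop_high = cm[, 3],
    pop_total = pop,
    prop_low = prop[, 1], prop_middle = prop[, 2], prop_high = prop[, 3],
    ses_score = as.numeric(prop %*% c(1, 2, 3)),
    ses_category = factor(ses_levels()[dominant], levels = ses_levels())
  )
}
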