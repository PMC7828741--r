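#' Configuration for a synthetic city
#'
#' Defines the geometry and socioeconomic structure of a seeded synthetic
#' city: a rectangular tessellation of square geographic units, a lattice
#' street network over the unit corners, and an open-streets route. Units
#' carry population counts for three ordinal SES groups (low/middle/high)
#' whose expected composition shifts monotonically from low-SES dominance at
#' the west edge to high-SES dominance at the east edge.
#'
#' @param grid_rows,grid_cols Number of unit rows and columns;
#'   `grid_rows * grid_cols` must be at least 4.
#' @param unit_side_m Side length of each square unit, in meters.
#' @param pop_per_unit_mean Mean of the Poisson distribution from which each
#'   unit's total population count is drawn.
#' @param n_ses_groups Number of SES groups. Fixed at 3 (low/middle/high).
#' @param gradient_strength Dimensionless strength (>= 0) of the west-east
#'   SES sorting; 0 gives spatially unstructured compositions, large values
#'   give near-complete sorting (a strongly segregated city).
#' @param mixing_noise Dirichlet concentration (> 0) controlling within-unit
#'   diversity around the expected composition; larger values give
#'   compositions closer to their expectation.
#' @param route_scenario `"crossing"` for a west-east route spanning the SES
#'   gradient, or `"confined"` for a north-south route inside the
#'   high-SES-dominant district.
#' @param seed Integer seed; all generators derive named substreams from it.
#'
#' @return A list of class `city_config`.
#' @examples
#' cfg <- city_config(grid_rows = 4, grid_cols = 6, seed = 7)
#' @export
city_config <- function(grid_rows = 12, grid_cols = 20, unit_side_m = 500,
                        pop_per_unit_mean = 1000, n_ses_groups = 3,
                        gradient_strength = 4, mixing_noise = 5,
                        route_scenario = c("crossing", "confined"),
                        seed = 1L) {
  route_scenario <- match.arg(route_scenario)
  stopifnot_scalar_count(grid_rows, "grid_rows")
  stopifnot_scalar_count(grid_cols, "grid_cols")
  if (grid_rows * grid_cols < 4) {
    abort("`grid_rows * grid_cols` must be at least 4.",
          class = "ciclovia_config_error")
  }
  if (!is.numeric(unit_side_m) || length(unit_side_m) != 1L || unit_side_m <= 0) {
    abort("`unit_side_m` must be a positive length in meters.",
          class = "ciclovia_config_error")
  }
  if (!is.numeric(pop_per_unit_mean) || pop_per_unit_mean <= 0) {
    abort("`pop_per_unit_mean` must be positive.", class = "ciclovia_config_error")
  }
  if (!identical(as.integer(n_ses_groups), 3L)) {
    abort("`n_ses_groups` is fixed at 3 (low/middle/high).",
          class = "ciclovia_config_error")
  }
  if (!is.numeric(gradient_strength) || gradient_strength < 0) {
    abort("`gradient_strength` must be >= 0.", class = "ciclovia_config_error")
  }
  if (!is.numeric(mixing_noise) || mixing_noise <= 0) {
    abort("`mixing_noise` must be > 0.", class = "ciclovia_config_error")
  }
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         unit_side_m = as.numeric(unit_side_m),
         pop_per_unit_mean = as.numeric(pop_per_unit_mean),
         n_ses_groups = 3L,
         gradient_strength = as.numeric(gradient_strength),
         mixing_noise = as.numeric(mixing_noise),
         route_scenario = route_scenario,
         seed = as.integer(seed)),
    class = "city_config"
  )
}

#' @export
print.city_config <- function(x, ...) {
  cat(sprintf("<city_config> %d x %d units of %.0f m, gradient %.2f, noise %.2f, route '%s', seed %d\n",
              x$grid_rows, x$grid_cols, x$unit_side_m, x$gradient_strength,
              x$mixing_noise, x$route_scenario, x$seed))
  invisible(x)
}
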