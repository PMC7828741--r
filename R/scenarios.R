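#' Planted-gradient validation scenario
#'
#' A deterministic one-row city whose SES percentile landscape is known
#' exactly, used to check that the exposure chain (routing, 500-m banding,
#' spatial join, eligibility rule) recovers a planted percentile span.
#' Columns have equal population and strictly increasing SES score, so
#' column `j` of `ncols` sits exactly at percentile `100 * (j - 0.5) /
#' ncols`. The route runs west-east along the southern gridline from the
#' first column to the east edge of column `route_end_col`. Participants
#' whose origins are restricted to the first column (percentile
#' `100 * 0.5 / ncols`) and whose interview points are uniform on the route
#' therefore face a planted span of
#' `delta = 100 * (route_end_col - 1) / ncols` percentile points between
#' their origin baseline and the far end of the route.
#'
#' @param ncols Number of unit columns (>= 4).
#' @param route_end_col Column containing the route's last edge
#'   (2 <= route_end_col <= ncols).
#' @param pop_per_unit Population of every unit.
#' @param unit_side_m Unit side length in meters.
#' @return A list of class `ciclovia_city` (elements `units`, `network`,
#'   `route`, plus `origin_units` naming the origin-cluster unit) with
#'   attribute `planted_delta`.
#' @examples
#' sc <- planted_span_scenario()
#' attr(sc, "planted_delta")  # 40
#' @export
planted_span_scenario <- function(ncols = 20, route_end_col = 9,
                                  pop_per_unit = 1000, unit_side_m = 500) {
  if (ncols < 4 || route_end_col < 2 || route_end_col > ncols) {
    abort("need ncols >= 4 and 2 <= route_end_col <= ncols.",
          class = "ciclovia_argument_error")
  }
  j <- seq_len(ncols)
  # equal totals, strictly increasing score along x
  base <- data.frame(
    row = 1, col = j,
    pop_low = (ncols - j) * pop_per_unit %/% ncols,
    pop_middle = pop_per_unit %/% ncols,
    pop_high = (j - 1) * pop_per_unit %/% ncols
  )
  units <- units_from_counts(base, unit_side_m = unit_side_m)
  cfg <- city_config(grid_rows = 1, grid_cols = ncols,
                     unit_side_m = unit_side_m, seed = 0L)
  network <- generate_network(cfg)
  route <- route_from_nodes(network, seq_len(route_end_col + 1L),
                            scenario = "planted_span")
  out <- structure(
    list(config = cfg, units = units, network = network, route = route,
         origin_units = units$unit_id[1]),
    class = "ciclovia_city")
  attr(out, "planted_delta") <- 100 * (route_end_col - 1) / ncols
  out
}
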