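#' Generate synthetic program participants
#'
#' Samples each participant's home (origin) node with probability
#' proportional to the population of the unit containing it, and an
#' interview (destination) point uniformly among the route's nodes. The
#' participant's SES-of-origin is the harmonized SES category of the origin
#' unit.
#'
#' @param city A `ciclovia_city` from [generate_city()], or a list with
#'   `units`, `network` and `route` elements.
#' @param n Number of participants (>= 1).
#' @param seed Integer seed (named substream `"participants"`).
#' @param origin_units Optional character vector of unit ids restricting the
#'   origin sampling frame (e.g. the catchment of an intercept survey);
#'   sampling stays population-proportional within it.
#' @return A tibble with columns `id`, `origin_unit`, `origin_node`,
#'   `dest_node`, `ses_of_origin`.
#' @examples
#' city <- generate_city(city_config(grid_rows = 4, grid_cols = 8, seed = 3))
#' generate_participants(city, n = 5, seed = 3)
#' @export
generate_participants <- function(city, n, seed, origin_units = NULL) {
  stopifnot_scalar_count(n, "n")
  units <- city$units; network <- city$network; route <- city$route
  node_unit <- locate_unit(network$nodes$x, network$nodes$y, units)
  frame <- units
  if (!is.null(origin_units)) {
    frame <- dplyr::filter(units, .data$unit_id %in% origin_units)
    if (nrow(frame) == 0) {
      abort("`origin_units` matches no unit.", class = "ciclovia_argument_error")
    }
  }
  if (sum(frame$pop_total) <= 0) {
    abort("origin sampling frame has zero population.",
          class = "ciclovia_argument_error")
  }
  nodes_by_unit <- split(network$nodes$node_id, node_unit)
  with_substream(seed, "participants", {
    o_units <- sample(frame$unit_id, n, replace = TRUE,
                      prob = frame$pop_total)
    o_nodes <- vapply(o_units, function(uid) {
      cand <- nodes_by_unit[[uid]]
      cand[sample.int(length(cand), 1L)]
    }, integer(1), USE.NAMES = FALSE)
    d_nodes <- route$node_id[sample.int(nrow(route), n, replace = TRUE)]
  })
  ses <- units$ses_category[match(o_units, units$unit_id)]
  tibble(
    id = sprintf("p%05d", seq_len(n)),
    origin_unit = o_units,
    origin_node = o_nodes,
    dest_node = d_nodes,
    ses_of_origin = ses
  )
}
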