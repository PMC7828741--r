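#' Generate the lattice street network of a synthetic city
#'
#' Builds a planar lattice with one node per unit corner and undirected
#' edges between 4-neighbors. Edge weight is the Euclidean length in meters,
#' so all edges have length `unit_side_m`. The lattice is connected by
#' construction.
#'
#' @param config A [city_config()].
#' @return A list of class `ciclovia_network` with elements `nodes`
#'   (tibble: `node_id`, `x`, `y`) and `edges` (tibble: `from`, `to`,
#'   `length_m`). Node ids are integers in row-major order from the
#'   south-west corner.
#' @examples
#' net <- generate_network(city_config(grid_rows = 2, grid_cols = 2))
#' nrow(net$nodes)  # 9
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "city_config"))
  R <- config$grid_rows; C <- config$grid_cols; side <- config$unit_side_m
  grid <- tidyr::expand_grid(gy = 0:R, gx = 0:C)
  nodes <- tibble(
    node_id = seq_len(nrow(grid)),
    x = grid$gx * side,
    y = grid$gy * side
  )
  id_at <- function(gx, gy) gy * (C + 1L) + gx + 1L
  horiz <- tidyr::expand_grid(gy = 0:R, gx = 0:(C - 1))
  vert <- tidyr::expand_grid(gy = 0:(R - 1), gx = 0:C)
  edges <- tibble(
    from = c(id_at(horiz$gx, horiz$gy), id_at(vert$gx, vert$gy)),
    to = c(id_at(horiz$gx + 1L, horiz$gy), id_at(vert$gx, vert$gy + 1L)),
    length_m = side
  )
  structure(list(nodes = nodes, edges = edges), class = "ciclovia_network")
}

#' @export
print.ciclovia_network <- function(x, ...) {
  cat(sprintf("<ciclovia_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

node_xy <- function(network, ids) {
  idx <- match(ids, network$nodes$node_id)
  if (anyNA(idx)) {
    abort(sprintf("unknown node id(s): %s",
                  paste(ids[is.na(idx)], collapse = ", ")),
          class = "ciclovia_routing_error")
  }
  network$nodes[idx, c("node_id", "x", "y")]
}

#' Build a route along an explicit node sequence
#'
#' Validates that consecutive nodes are adjacent in the network and returns
#' the route as an ordered tibble of node coordinates.
#'
#' @param network A `ciclovia_network`.
#' @param node_ids Integer vector of consecutive, adjacent node ids.
#' @param scenario Optional label stored on the route.
#' @return A tibble (`seq`, `node_id`, `x`, `y`) with attributes
#'   `total_length_m` and `scenario`.
#' @export
route_from_nodes <- function(network, node_ids, scenario = "custom") {
  if (length(node_ids) < 1) {
    abort("a route needs at least one node.", class = "ciclovia_argument_error")
  }
  xy <- node_xy(network, node_ids)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- key(network$edges$from, network$edges$to)
  if (length(node_ids) > 1) {
    want <- key(node_ids[-length(node_ids)], node_ids[-1])
    if (!all(want %in% have)) {
      abort("consecutive route nodes must be adjacent in the network.",
            class = "ciclovia_routing_error")
    }
  }
  len <- if (length(node_ids) > 1) {
    sum(sqrt(diff(xy$x)^2 + diff(xy$y)^2))
  } else 0
  out <- tibble(seq = seq_along(node_ids), node_id = node_ids,
                x = xy$x, y = xy$y)
  attr(out, "total_length_m") <- len
  attr(out, "scenario") <- scenario
  out
}

#' Generate the open-streets route of a synthetic city
#'
#' Two scenarios mirror the contrast between programs whose circuits span
#' the whole city and programs confined to affluent districts:
#' * `"crossing"`: a west-east route along the middle horizontal gridline,
#'   spanning the full SES gradient;
#' * `"confined"`: a north-south route along the west edge of the
#'   high-SES-dominant district, so at least 75% of its length lies in units
#'   whose dominant SES is high (under the half-open boundary-attribution
#'   rule, a gridline belongs to the unit east of it).
#'
#' @param config A [city_config()].
#' @param units Unit tibble from [generate_units()].
#' @param network Network from [generate_network()].
#' @return A route tibble as in [route_from_nodes()].
#' @export
generate_route <- function(config, units, network) {
  stopifnot(inherits(config, "city_config"))
  R <- config$grid_rows; C <- config$grid_cols
  id_at <- function(gx, gy) gy * (C + 1L) + gx + 1L
  if (config$route_scenario == "crossing") {
    gy <- R %/% 2L
    ids <- id_at(0:C, gy)
  } else {
    high_share <- units |>
      dplyr::group_by(.data$col) |>
      dplyr::summarise(share = mean(.data$ses_category == "high")) |>
      dplyr::arrange(.data$col)
    ok <- which(high_share$share >= 0.75)
    if (length(ok) == 0) {
      abort(paste("confined scenario infeasible: no column has >= 75% of its",
                  "units dominated by the high SES group."),
            class = "ciclovia_generation_error")
    }
    c0 <- high_share$col[min(ok)]
    ids <- id_at(rep(c0 - 1L, R + 1L), 0:R)
  }
  route_from_nodes(network, ids, scenario = config$route_scenario)
}

#' Generate a full synthetic city
#'
#' Convenience wrapper running [generate_units()], [generate_network()] and
#' [generate_route()] under one configuration.
#'
#' @param config A [city_config()].
#' @return A list of class `ciclovia_city` with elements `config`, `units`,
#'   `network`, `route`.
#' @examples
#' city <- generate_city(city_config(grid_rows = 4, grid_cols = 8, seed = 2))
#' @export
generate_city <- function(config) {
  units <- generate_units(config)
  network <- generate_network(config)
  route <- generate_route(config, units, network)
  structure(list(config = config, units = units, network = network,
                 route = route),
            class = "ciclovia_city")
}

#' @export
print.ciclovia_city <- function(x, ...) {
  cat(sprintf("<ciclovia_city> %d units, %d nodes, '%s' route of %.1f km\n",
              nrow(x$units), nrow(x$network$nodes),
              attr(x$route, "scenario") %||% "?",
              (attr(x$route, "total_length_m") %||% NA_real_) / 1000))
  invisible(x)
}
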