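# Plain-file handoff: GeoJSON for geometries, CSV for tables, JSON for
# summaries. Unit polygons are axis-aligned rectangles, so the GeoJSON
# features carry the rectangle ring plus the attribute table.

units_to_geojson_list <- function(units) {
  feats <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    ring <- list(c(u$xmin, u$ymin), c(u$xmax, u$ymin), c(u$xmax, u$ymax),
                 c(u$xmin, u$ymax), c(u$xmin, u$ymin))
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(
        id = u$unit_id, row = u$row, col = u$col,
        pop_low = u$pop_low, pop_middle = u$pop_middle, pop_high = u$pop_high,
        ses_score = u$ses_score, ses_category = as.character(u$ses_category)
      )
    )
  })
  list(type = "FeatureCollection", features = feats)
}

#' Write and read unit tessellations as GeoJSON
#'
#' @param units A unit tibble (see [generate_units()]).
#' @param path File path.
#' @return `read_units_geojson()` returns a unit tibble equivalent to the
#'   one written.
#' @export
write_units_geojson <- function(units, path) {
  jsonlite::write_json(units_to_geojson_list(units), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_units_geojson
#' @export
read_units_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- purrr::map_dfr(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    p <- f$properties
    tibble(
      unit_id = p$id, row = as.integer(p$row), col = as.integer(p$col),
      xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys),
      pop_low = as.numeric(p$pop_low), pop_middle = as.numeric(p$pop_middle),
      pop_high = as.numeric(p$pop_high),
      ses_score = as.numeric(p$ses_score),
      ses_category = p$ses_category
    )
  })
  pop <- rows$pop_low + rows$pop_middle + rows$pop_high
  rows$pop_total <- pop
  rows$prop_low <- rows$pop_low / ifelse(pop > 0, pop, 1)
  rows$prop_middle <- rows$pop_middle / ifelse(pop > 0, pop, 1)
  rows$prop_high <- rows$pop_high / ifelse(pop > 0, pop, 1)
  rows$ses_category <- factor(rows$ses_category, levels = ses_levels())
  rows[, c("unit_id", "row", "col", "xmin", "xmax", "ymin", "ymax",
           "pop_low", "pop_middle", "pop_high", "pop_total",
           "prop_low", "prop_middle", "prop_high", "ses_score",
           "ses_category")]
}

#' Write and read a route polyline as GeoJSON
#'
#' @param route A route tibble from [route_from_nodes()].
#' @param path File path.
#' @export
write_route_geojson <- function(route, path) {
  gj <- list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = lapply(seq_len(nrow(route)),
                                         function(i) c(route$x[i], route$y[i]))),
    properties = list(
      scenario = attr(route, "scenario") %||% NA,
      total_length_m = attr(route, "total_length_m") %||% NA,
      node_ids = route$node_id
    )
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_route_geojson
#' @export
read_route_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  coords <- gj$geometry$coordinates
  out <- tibble(
    seq = seq_along(coords),
    node_id = as.integer(unlist(gj$properties$node_ids)),
    x = vapply(coords, function(p) as.numeric(p[[1]]), numeric(1)),
    y = vapply(coords, function(p) as.numeric(p[[2]]), numeric(1))
  )
  attr(out, "scenario") <- gj$properties$scenario
  attr(out, "total_length_m") <- as.numeric(gj$properties$total_length_m)
  out
}

write_trajectories_geojson <- function(trajectories, network, path) {
  feats <- lapply(seq_len(nrow(trajectories)), function(i) {
    xy <- node_xy(network, trajectories$path[[i]])
    list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(xy)),
                                           function(j) c(xy$x[j], xy$y[j]))),
      properties = list(id = trajectories$id[i],
                        ses_of_origin = as.character(trajectories$ses_of_origin[i]),
                        total_length_m = trajectories$total_length_m[i])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
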