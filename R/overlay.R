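# Spatial join of points and polylines onto a rectangle tessellation.
#
# Units are disjoint axis-aligned rectangles covering the city. Containment
# uses half-open rectangles [xmin, xmax) x [ymin, ymax), clamped so points on
# the tessellation's outer east/north edges fall in the last row/column.
# Every point therefore belongs to exactly one unit, which makes length
# attribution deterministic and exactly conservative: a polyline running
# along the shared boundary of two units is attributed to the unit east
# (resp. north) of it.

# Precompute a rectilinear lookup grid for a rectangle tessellation: refine
# the plane at every unit boundary and record which unit covers each cell.
unit_locator <- function(units) {
  xb <- sort(unique(c(units$xmin, units$xmax)))
  yb <- sort(unique(c(units$ymin, units$ymax)))
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  M <- matrix(NA_character_, ny, nx)
  for (i in seq_len(nrow(units))) {
    jx <- which(xb >= units$xmin[i] - 1e-12 & xb < units$xmax[i])
    jy <- which(yb >= units$ymin[i] - 1e-12 & yb < units$ymax[i])
    M[jy, jx] <- units$unit_id[i]
  }
  list(xb = xb, yb = yb, nx = nx, ny = ny, M = M)
}

locate_with <- function(loc, x, y) {
  gxmax <- loc$xb[length(loc$xb)]; gymax <- loc$yb[length(loc$yb)]
  eps <- 1e-9 * max(gxmax, gymax, 1)
  # points on the outer east/north edges clamp into the last cells
  xx <- ifelse(abs(x - gxmax) <= eps, gxmax - eps, x)
  yy <- ifelse(abs(y - gymax) <= eps, gymax - eps, y)
  ix <- findInterval(xx, loc$xb)
  iy <- findInterval(yy, loc$yb)
  ok <- ix >= 1L & ix <= loc$nx & iy >= 1L & iy <= loc$ny
  out <- rep(NA_character_, length(x))
  out[ok] <- loc$M[cbind(iy[ok], ix[ok])]
  out
}

#' Locate points in the unit tessellation
#'
#' @param x,y Numeric coordinate vectors in meters.
#' @param units A unit tibble (see [generate_units()]).
#' @return Character vector of `unit_id`s (`NA` outside the tessellation).
#' @export
locate_unit <- function(x, y, units) {
  locate_with(unit_locator(units), x, y)
}

# Cut a polyline at every unit boundary it crosses and attribute each piece
# to the unit containing its midpoint. Returns one row per piece with the
# distance interval along the path. `loc` allows reusing a prebuilt locator
# across many polylines.
overlay_polyline <- function(x, y, units, loc = unit_locator(units)) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  xs <- loc$xb
  ys <- loc$yb
  starts <- ends <- mx <- my <- vector("list", max(length(x) - 1L, 0L))
  dist0 <- 0
  for (s in seq_len(max(length(x) - 1L, 0L))) {
    x0 <- x[s]; y0 <- y[s]; x1 <- x[s + 1L]; y1 <- y[s + 1L]
    seg_len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    if (seg_len == 0) next
    tx <- if (x1 != x0) (xs - x0) / (x1 - x0) else numeric(0)
    ty <- if (y1 != y0) (ys - y0) / (y1 - y0) else numeric(0)
    tt <- sort(unique(c(0, 1, tx[tx > 0 & tx < 1], ty[ty > 0 & ty < 1])))
    mid_t <- (tt[-length(tt)] + tt[-1]) / 2
    mx[[s]] <- x0 + mid_t * (x1 - x0)
    my[[s]] <- y0 + mid_t * (y1 - y0)
    starts[[s]] <- dist0 + head(tt, -1) * seg_len
    ends[[s]] <- dist0 + tt[-1] * seg_len
    dist0 <- dist0 + seg_len
  }
  st <- unlist(starts) %||% numeric(0)
  en <- unlist(ends) %||% numeric(0)
  if (length(st) == 0) {
    return(tibble(unit_id = character(0), start_m = numeric(0),
                  end_m = numeric(0), length_m = numeric(0)))
  }
  tibble(
    unit_id = locate_with(loc, unlist(mx), unlist(my)),
    start_m = st, end_m = en, length_m = en - st
  )
}

#' Decompose a route's length by SES category and segregation class
#'
#' Overlays a route polyline on the unit tessellation and reports the
#' fraction of route length falling in units of each harmonized SES category
#' and, if unit segregation classes are supplied, of each evenness class.
#'
#' @param route A route tibble (columns `x`, `y`; see [route_from_nodes()]).
#' @param units A unit tibble.
#' @param classes Optional tibble with `unit_id` and `class` (e.g. from
#'   `tidy()` of a [theil_index()] result).
#' @return A tibble with columns `grouping` (`"ses_category"` or
#'   `"segregation_class"`), `category` and `fraction`; fractions sum to 1
#'   within each grouping.
#' @examples
#' units <- units_from_counts(data.frame(row = 1, col = 1:4,
#'   pop_low = c(9, 6, 3, 0), pop_middle = 1, pop_high = c(0, 3, 6, 9)))
#' route <- tibble::tibble(x = c(0, 2000), y = c(250, 250))
#' route_overlay(route, units)
#' @export
route_overlay <- function(route, units, classes = NULL) {
  pieces <- overlay_polyline(route$x, route$y, units)
  if (nrow(pieces) == 0 || all(is.na(pieces$unit_id))) {
    abort("route does not intersect the unit tessellation.",
          class = "ciclovia_overlay_error")
  }
  if (anyNA(pieces$unit_id)) {
    abort("part of the route lies outside the unit tessellation.",
          class = "ciclovia_overlay_error")
  }
  total <- sum(pieces$length_m)
  joined <- dplyr::left_join(pieces, units[, c("unit_id", "ses_category")],
                             by = "unit_id")
  by_ses <- joined |>
    dplyr::group_by(category = .data$ses_category) |>
    dplyr::summarise(fraction = sum(.data$length_m) / total) |>
    tidyr::complete(category = factor(ses_levels(), levels = ses_levels()),
                    fill = list(fraction = 0)) |>
    dplyr::mutate(grouping = "ses_category", category = as.character(.data$category))
  out <- by_ses[, c("grouping", "category", "fraction")]
  if (!is.null(classes)) {
    joined2 <- dplyr::left_join(pieces, classes[, c("unit_id", "class")],
                                by = "unit_id")
    by_class <- joined2 |>
      dplyr::group_by(category = .data$class) |>
      dplyr::summarise(fraction = sum(.data$length_m) / total) |>
      tidyr::complete(category = factor(seg_class_levels(),
                                        levels = seg_class_levels()),
                      fill = list(fraction = 0)) |>
      dplyr::mutate(grouping = "segregation_class",
                    category = as.character(.data$category))
    out <- dplyr::bind_rows(out, by_class[, c("grouping", "category", "fraction")])
  }
  out
}
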