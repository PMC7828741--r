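# Shortest-path trajectories over the street network.
#
# igraph supplies the shortest-path distances; the node sequence itself is
# reconstructed by a greedy walk that always takes the smallest-id neighbor
# still on a shortest path, which yields the lexicographically smallest
# shortest path and makes routing fully deterministic.

network_graph <- function(network) {
  if (any(network$edges$from == network$edges$to)) {
    abort("self-loops are not allowed in the street network.",
          class = "ciclovia_validation_error")
  }
  if (any(network$edges$length_m <= 0)) {
    abort("edge lengths must be positive.", class = "ciclovia_validation_error")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(network$edges$from),
               to = as.character(network$edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes$node_id))
  )
  igraph::E(g)$weight <- network$edges$length_m
  g
}

# adjacency as a list: for each node, tibble of (neighbor, weight)
adjacency_list <- function(network) {
  e <- network$edges
  both <- tibble(a = c(e$from, e$to), b = c(e$to, e$from),
                 w = c(e$length_m, e$length_m))
  split(both[, c("b", "w")], both$a)
}

# greedy lexicographic reconstruction given distances-to-destination
walk_lexicographic <- function(origin, destination, dist_to_dest, adj) {
  path <- origin
  u <- origin
  tol <- 1e-9 * max(dist_to_dest[is.finite(dist_to_dest)], 1)
  while (u != destination) {
    nb <- adj[[as.character(u)]]
    cand <- nb$b[abs(nb$w + dist_to_dest[as.character(nb$b)] -
                       dist_to_dest[as.character(u)]) <= tol]
    u <- min(cand)
    path <- c(path, u)
  }
  path
}

#' Shortest-path trajectory between two nodes
#'
#' Returns the minimum-length path through the street network from a
#' participant's origin to their destination. Among equally short paths the
#' lexicographically smallest node sequence is returned, so results are
#' deterministic.
#'
#' @param network A `ciclovia_network` (lists `nodes` and `edges`).
#' @param origin,destination Node ids.
#' @return A tibble (`seq`, `node_id`, `x`, `y`) with attribute
#'   `total_length_m`. A trajectory with `origin == destination` has one row
#'   and length 0.
#' @examples
#' net <- generate_network(city_config(grid_rows = 2, grid_cols = 2))
#' attr(shortest_path_trajectory(net, 1, 9), "total_length_m")
#' @export
shortest_path_trajectory <- function(network, origin, destination) {
  node_xy(network, c(origin, destination))  # validates existence
  if (origin == destination) {
    xy <- node_xy(network, origin)
    out <- tibble(seq = 1L, node_id = origin, x = xy$x, y = xy$y)
    attr(out, "total_length_m") <- 0
    return(out)
  }
  g <- network_graph(network)
  d <- igraph::distances(g, v = as.character(destination))[1, ]
  if (!is.finite(d[as.character(origin)])) {
    abort(sprintf("nodes %s and %s are not connected in the street network.",
                  origin, destination),
          class = "ciclovia_routing_error")
  }
  adj <- adjacency_list(network)
  ids <- walk_lexicographic(origin, destination, d, adj)
  xy <- node_xy(network, ids)
  out <- tibble(seq = seq_along(ids), node_id = ids, x = xy$x, y = xy$y)
  attr(out, "total_length_m") <- unname(d[as.character(origin)])
  out
}

#' Build trajectories for a roster of participants
#'
#' Vectorized routing from each participant's origin node to their
#' destination node on the route. Distances are computed once per distinct
#' destination, so rosters sharing interview points are cheap.
#'
#' @param network A `ciclovia_network`.
#' @param participants Tibble with `id`, `origin_node`, `dest_node` and
#'   (optionally) `ses_of_origin`.
#' @return A tibble with one row per participant: `id`, `origin_node`,
#'   `dest_node`, `ses_of_origin` (if present), `total_length_m` and a
#'   list-column `path` of node-id vectors.
#' @export
build_trajectories <- function(network, participants) {
  g <- network_graph(network)
  adj <- adjacency_list(network)
  dests <- sort(unique(participants$dest_node))
  dmat <- igraph::distances(g, v = as.character(dests))
  rownames(dmat) <- as.character(dests)
  paths <- vector("list", nrow(participants))
  lens <- numeric(nrow(participants))
  for (i in seq_len(nrow(participants))) {
    o <- participants$origin_node[i]; dst <- participants$dest_node[i]
    dvec <- dmat[as.character(dst), ]
    if (!is.finite(dvec[as.character(o)])) {
      abort(sprintf("nodes %s and %s are not connected in the street network.",
                    o, dst), class = "ciclovia_routing_error")
    }
    lens[i] <- unname(dvec[as.character(o)])
    paths[[i]] <- if (o == dst) o else walk_lexicographic(o, dst, dvec, adj)
  }
  out <- tibble(
    id = participants$id,
    origin_node = participants$origin_node,
    dest_node = participants$dest_node,
    total_length_m = lens,
    path = paths
  )
  if ("ses_of_origin" %in% names(participants)) {
    out$ses_of_origin <- participants$ses_of_origin
    out <- out[, c("id", "origin_node", "dest_node", "ses_of_origin",
                   "total_length_m", "path")]
  }
  out
}

trajectory_coords <- function(network, path_ids) {
  node_xy(network, path_ids)
}
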