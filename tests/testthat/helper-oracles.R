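# Independent brute-force oracles used to cross-check the implementation.

# term-by-term entropy summation
oracle_entropy <- function(p) {
  total <- 0
  for (pi in p) {
    if (pi > 0) total <- total + pi * log(1 / pi)
  }
  total
}

# double-loop Theil index on a counts matrix (units x groups)
oracle_theil <- function(cm) {
  t_i <- rowSums(cm)
  T_pop <- sum(t_i)
  P <- colSums(cm) / T_pop
  E <- oracle_entropy(P)
  H <- 0
  for (i in seq_len(nrow(cm))) {
    if (t_i[i] == 0) next
    E_i <- oracle_entropy(cm[i, ] / t_i[i])
    H <- H + t_i[i] * (E - E_i) / (E * T_pop)
  }
  H
}

# textbook Pearson chi-squared statistic
oracle_chi2 <- function(m) {
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      stat <- stat + (m[i, j] - e)^2 / e
    }
  }
  stat
}

# exhaustive simple-path enumeration for shortest-path lengths
oracle_shortest_length <- function(edges, from, to) {
  if (from == to) return(0)
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges$from[i]); b <- as.character(edges$to[i])
    adj[[a]] <- rbind(adj[[a]], data.frame(v = edges$to[i], w = edges$length_m[i]))
    adj[[b]] <- rbind(adj[[b]], data.frame(v = edges$from[i], w = edges$length_m[i]))
  }
  best <- Inf
  recurse <- function(u, visited, len) {
    if (len >= best) return()
    if (u == to) { best <<- len; return() }
    nb <- adj[[as.character(u)]]
    if (is.null(nb)) return()
    for (j in seq_len(nrow(nb))) {
      v <- nb$v[j]
      if (!(v %in% visited)) recurse(v, c(visited, v), len + nb$w[j])
    }
  }
  recurse(from, from, 0)
  best
}

# random connected weighted graph on n nodes (spanning tree + extra edges)
random_connected_graph <- function(n, extra = n) {
  perm <- sample(n)
  edges <- data.frame(from = integer(0), to = integer(0), length_m = numeric(0))
  for (i in 2:n) {
    j <- perm[sample.int(i - 1, 1)]
    edges <- rbind(edges, data.frame(from = perm[i], to = j,
                                     length_m = round(runif(1, 1, 100), 3)))
  }
  for (k in seq_len(extra)) {
    uv <- sample(n, 2)
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (!(paste(min(uv), max(uv)) %in% key)) {
      edges <- rbind(edges, data.frame(from = uv[1], to = uv[2],
                                       length_m = round(runif(1, 1, 100), 3)))
    }
  }
  xy <- matrix(runif(2 * n), ncol = 2)
  list(nodes = tibble::tibble(node_id = 1:n, x = xy[, 1], y = xy[, 2]),
       edges = tibble::as_tibble(edges))
}

# random composition table for entropy checks
random_composition <- function(n_units, max_pop = 500) {
  m <- matrix(rpois(n_units * 3, lambda = runif(n_units * 3, 5, max_pop)),
              ncol = 3)
  tibble::tibble(unit_id = sprintf("u%03d", seq_len(n_units)),
                 pop_low = m[, 1], pop_middle = m[, 2], pop_high = m[, 3])
}
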