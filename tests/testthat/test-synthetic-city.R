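# Synthetic-city generator: determinism, composition structure, lattice
# combinatorics, route scenarios, participant sampling, survey dialects.

test_that("identical (config, seed) gives identical artifacts", {
  cfg <- city_config(grid_rows = 4, grid_cols = 6, seed = 11)
  a <- generate_city(cfg)
  b <- generate_city(cfg)
  expect_identical(a$units, b$units)
  expect_identical(a$network, b$network)
  expect_identical(a$route, b$route)
  p1 <- generate_participants(a, 20, seed = 5)
  p2 <- generate_participants(b, 20, seed = 5)
  expect_identical(p1, p2)
  s1 <- generate_survey(p1, seed = 5)
  s2 <- generate_survey(p2, seed = 5)
  expect_identical(s1, s2)
})

test_that("substreams are isolated: drawing participants does not change units", {
  cfg <- city_config(grid_rows = 4, grid_cols = 6, seed = 11)
  a <- generate_units(cfg)
  invisible(generate_participants(generate_city(cfg), 50, seed = 11))
  b <- generate_units(cfg)
  expect_identical(a, b)
})

test_that("unit compositions close: counts sum to totals, proportions to 1", {
  units <- generate_units(city_config(grid_rows = 5, grid_cols = 8, seed = 2))
  expect_equal(units$pop_low + units$pop_middle + units$pop_high,
               units$pop_total)
  expect_equal(units$prop_low + units$prop_middle + units$prop_high,
               rep(1, nrow(units)), tolerance = 1e-9)
  expect_true(all(units$ses_score >= 1 & units$ses_score <= 3))
})

test_that("zero gradient with high mixing noise gives near-uniform compositions", {
  cfg <- city_config(grid_rows = 6, grid_cols = 6, gradient_strength = 0,
                     mixing_noise = 1e5, pop_per_unit_mean = 5000, seed = 4)
  units <- generate_units(cfg)
  expect_equal(mean(units$prop_low), 1 / 3, tolerance = 0.02)
  expect_equal(mean(units$prop_high), 1 / 3, tolerance = 0.02)
  expect_lt(sd(units$prop_low), 0.02)
})

test_that("strong gradient puts low dominance west and high dominance east", {
  for (s in 1:20) {
    units <- generate_units(city_config(grid_rows = 3, grid_cols = 10,
                                        gradient_strength = 12, seed = s))
    west <- units$ses_category[units$col == 1]
    east <- units$ses_category[units$col == 10]
    expect_true(all(west == "low"))
    expect_true(all(east == "high"))
  }
})

test_that("lattice network has the expected combinatorics and geometry", {
  cfg <- city_config(grid_rows = 2, grid_cols = 2, seed = 1)
  net <- generate_network(cfg)
  expect_equal(nrow(net$nodes), 9)
  expect_equal(nrow(net$edges), 12)
  expect_true(all(net$edges$length_m == cfg$unit_side_m))
  # edge weights equal endpoint Euclidean distance
  xy <- net$nodes
  d <- sqrt((xy$x[net$edges$from] - xy$x[net$edges$to])^2 +
              (xy$y[net$edges$from] - xy$y[net$edges$to])^2)
  expect_equal(d, net$edges$length_m)
  g <- igraph::graph_from_edgelist(as.matrix(net$edges[, 1:2]), directed = FALSE)
  expect_true(igraph::is_connected(g))
})

test_that("route length equals the sum of its edge lengths", {
  city <- tiny_city(seed = 3)
  r <- city$route
  expect_equal(attr(r, "total_length_m"),
               sum(sqrt(diff(r$x)^2 + diff(r$y)^2)))
})

test_that("crossing route on a strong gradient intersects all three dominant categories", {
  city <- generate_city(city_config(grid_rows = 6, grid_cols = 12,
                                    gradient_strength = 4,
                                    route_scenario = "crossing", seed = 8))
  ov <- route_overlay(city$route, city$units)
  ses <- ov[ov$grouping == "ses_category", ]
  expect_true(all(ses$fraction > 0))
  expect_equal(sum(ses$fraction), 1, tolerance = 1e-9)
})

test_that("confined route stays at least 75% inside high-SES-dominant units", {
  for (s in 1:5) {
    city <- generate_city(city_config(grid_rows = 6, grid_cols = 12,
                                      gradient_strength = 6,
                                      route_scenario = "confined", seed = s))
    pieces <- ciclovia:::overlay_polyline(city$route$x, city$route$y, city$units)
    cat_by_unit <- city$units$ses_category[match(pieces$unit_id,
                                                 city$units$unit_id)]
    share_high <- sum(pieces$length_m[cat_by_unit == "high"]) /
      sum(pieces$length_m)
    expect_gte(share_high, 0.75)
  }
})

test_that("confined scenario without a high-SES district fails loudly", {
  cfg <- city_config(grid_rows = 2, grid_cols = 3,
                     route_scenario = "confined", seed = 1)
  units <- units_from_counts(
    data.frame(row = rep(1:2, each = 3), col = rep(1:3, 2),
               pop_low = 50, pop_middle = 30, pop_high = 20))
  net <- generate_network(cfg)
  expect_error(generate_route(cfg, units, net),
               class = "ciclovia_generation_error")
})

test_that("participant origins follow unit populations (chi-square GOF)", {
  counts <- data.frame(row = rep(1:2, each = 2), col = rep(1:2, 2),
                       pop_low = 250, pop_middle = 250, pop_high = 250)
  units <- units_from_counts(counts)
  cfg <- city_config(grid_rows = 2, grid_cols = 2, seed = 1)
  city <- structure(list(config = cfg, units = units,
                         network = generate_network(cfg),
                         route = route_from_nodes(generate_network(cfg), 1:3)),
                    class = "ciclovia_city")
  parts <- generate_participants(city, 1000, seed = 42)
  tab <- table(factor(parts$origin_unit, levels = units$unit_id))
  gof <- suppressWarnings(chisq.test(tab, p = rep(1 / 4, 4)))
  expect_gt(gof$p.value, 0.01)
  # destinations all on the route
  expect_true(all(parts$dest_node %in% city$route$node_id))
  # SES-of-origin matches the origin unit's category
  expect_equal(as.character(parts$ses_of_origin),
               as.character(units$ses_category[match(parts$origin_unit,
                                                     units$unit_id)]))
})

test_that("invalid configurations and arguments are rejected", {
  expect_error(city_config(grid_rows = 1, grid_cols = 2),
               class = "ciclovia_config_error")
  expect_error(city_config(unit_side_m = -5), class = "ciclovia_config_error")
  expect_error(city_config(mixing_noise = 0), class = "ciclovia_config_error")
  city <- tiny_city()
  expect_error(generate_participants(city, 0, seed = 1),
               class = "ciclovia_argument_error")
})

test_that("raw survey dialects validate against the codebook and flag availability", {
  city <- tiny_city(seed = 6)
  parts <- generate_participants(city, 300, seed = 6)
  raw <- generate_survey(parts, seed = 6)
  cb <- default_codebook()
  expect_setequal(names(raw), names(cb$cities))
  for (ct in names(raw)) {
    spec <- cb$cities[[ct]]
    for (v in names(spec)) {
      expect_true(spec[[v]]$column %in% names(raw[[ct]]),
                  label = sprintf("%s/%s column present", ct, v))
      if (!is.null(spec[[v]]$map)) {
        expect_true(all(as.character(raw[[ct]][[spec[[v]]$column]]) %in%
                          names(spec[[v]]$map)),
                    label = sprintf("%s/%s legal codes", ct, v))
      }
    }
  }
  # availability: no weight/height outside the three cities that measured BMI
  expect_false("peso_kg" %in% names(raw$santiago_chile))
  expect_false("salud" %in% names(raw$mexico_city) ||
                 "salud_5pt" %in% names(raw$mexico_city))
  # harmonization round-trip preserves SES-of-origin
  h <- harmonize_survey(raw)
  merged <- merge(h, parts, by = "id")
  expect_equal(as.character(merged$ses3), as.character(merged$ses_of_origin))
})

test_that("null logistic model yields ~50% outcome prevalence", {
  parts <- tibble::tibble(id = sprintf("p%04d", 1:4000),
                          ses_of_origin = sample(c("low", "middle", "high"),
                                                 4000, replace = TRUE))
  eff <- effect_spec(intercept = 0,
                     log_or = c(sex_female = 0, ses_middle = 0, ses_high = 0,
                                edu_secondary = 0, edu_college = 0,
                                edu_masters = 0),
                     city_sd = 0)
  raw <- generate_survey(parts, eff, seed = 21)
  truth <- attr(raw, "truth")
  expect_equal(mean(truth$y), 0.5, tolerance = 0.03)
  h <- harmonize_survey(raw)
  expect_equal(mean(h$meets_pa_program == "yes"), mean(truth$y),
               tolerance = 1e-9)
})

test_that("missing effect coefficients raise a configuration error", {
  expect_error(effect_spec(log_or = c(sex_female = 0.1)),
               class = "ciclovia_config_error")
})
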