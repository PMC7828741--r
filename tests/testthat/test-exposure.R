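# Percentile map, banding and spatial join, profiles, maximum differences,
# overlays and shares.

two_unit_strip <- function() {
  units_from_counts(data.frame(row = 1, col = 1:2,
                               pop_low = c(10, 0), pop_middle = 0,
                               pop_high = c(0, 10)))
}

test_that("percentile map follows the midpoint formula and tie rule", {
  u <- two_unit_strip()
  pm <- ses_percentile_map(u)
  expect_equal(pm$percentile, c(25, 75))
  # all units tied -> all at 50
  tied <- units_from_counts(data.frame(row = 1, col = 1:4, pop_low = 5,
                                       pop_middle = 5, pop_high = 5))
  expect_true(all(ses_percentile_map(tied)$percentile == 50))
  # population-weighted mean percentile is 50
  withr::with_seed(2, tab <- random_composition(30))
  tab$row <- 1; tab$col <- seq_len(30)
  u2 <- units_from_counts(tab)
  pm2 <- ses_percentile_map(u2)
  wmean <- sum(pm2$percentile * u2$pop_total) / sum(u2$pop_total)
  expect_equal(wmean, 50, tolerance = 0.5)
  expect_error(ses_percentile_map(dplyr::mutate(u, pop_total = 0)),
               class = "ciclovia_validation_error")
})

test_that("band values reproduce hand-computed joins", {
  # 1200-m path inside one percentile-80 unit (rank 3 of 4 equal units)
  units <- units_from_counts(data.frame(row = 1, col = 1:4,
                                        pop_low = c(9, 6, 3, 0),
                                        pop_middle = 1,
                                        pop_high = c(0, 3, 6, 9)),
                             unit_side_m = 2000)
  pmap <- ses_percentile_map(units)
  expect_equal(sort(pmap$percentile), c(12.5, 37.5, 62.5, 87.5))
  inside <- tibble::tibble(x = c(4100, 5300), y = c(1000, 1000))  # unit 3
  bt <- segment_trajectory(inside, units, pmap)
  expect_equal(bt$k, 0:2)
  expect_equal(bt$value, rep(62.5, 3))
  # 1000-m path: 500 m in one unit, 500 m in the next
  units2 <- two_unit_strip()
  pm2 <- ses_percentile_map(units2)
  straddle <- tibble::tibble(x = c(0, 1000), y = c(100, 100))
  bt2 <- segment_trajectory(straddle, units2, pm2)
  expect_equal(bt2$value, c(25, 75))
  # mid-band crossing: length-weighted mean by hand
  units3 <- units_from_counts(data.frame(row = 1, col = 1:3,
                                         pop_low = c(4, 2, 0), pop_middle = 2,
                                         pop_high = c(0, 2, 4)),
                              unit_side_m = 200)
  pm3 <- ses_percentile_map(units3)
  p <- pm3$percentile  # 100/6, 50, 500/6
  path3 <- tibble::tibble(x = c(50, 550), y = c(10, 10))
  bt3 <- segment_trajectory(path3, units3, pm3)
  hand <- (150 * p[1] + 200 * p[2] + 150 * p[3]) / 500
  expect_equal(bt3$value, hand, tolerance = 1e-9)
  # midpoint join variant: the unit under the band midpoint
  bt3m <- segment_trajectory(path3, units3, pm3, join = "midpoint")
  expect_equal(bt3m$value, p[2])
})

test_that("short final bands are dropped and long ones kept", {
  units <- two_unit_strip()
  pmap <- ses_percentile_map(units)
  # 540 m: the 40-m tail is below the 50-m minimum
  bt <- segment_trajectory(tibble::tibble(x = c(0, 540), y = c(1, 1)),
                           units, pmap)
  expect_equal(bt$k, 0L)
  # 560 m: the 60-m tail is kept
  bt2 <- segment_trajectory(tibble::tibble(x = c(0, 560), y = c(1, 1)),
                            units, pmap)
  expect_equal(bt2$k, c(0L, 1L))
  expect_equal(bt2$length_m, c(500, 60))
})

test_that("profiles aggregate mean, variance and attrition correctly", {
  bands <- tibble::tibble(
    id = c("a", "a", "b"),
    ses_of_origin = factor("low", levels = c("low", "middle", "high")),
    k = c(0L, 1L, 0L), value = c(20, 35, 40), length_m = 500)
  prof <- suppressWarnings(exposure_profile(bands))
  expect_equal(prof$mean_percentile, c(30, 35))
  expect_equal(prof$variance, c(200, 0))
  expect_equal(prof$n_participants, c(2L, 1L))
  expect_equal(prof$distance_km, c(0.25, 0.75))
  expect_warning(exposure_profile(bands), "middle")
  # n_participants never increases with distance
  chain <- exposure_chain(tiny_city(seed = 4), n = 150, seed = 4)
  drops <- chain$profile |>
    dplyr::group_by(ses_of_origin) |>
    dplyr::summarise(mono = all(diff(n_participants) <= 0))
  expect_true(all(drops$mono))
})

test_that("maximum percentile difference picks the right band, sign and distance", {
  prof <- tibble::tibble(k = 0:2, mean_percentile = c(10, 30, 55),
                         n_participants = c(50L, 50L, 50L))
  res <- max_percentile_difference(prof, baseline = 10, min_n = 10)
  expect_equal(res$max_diff, 45)
  expect_equal(res$distance_km, 1.25)
  # flat profile: zero difference at the first band midpoint
  flat <- tibble::tibble(k = 0:3, mean_percentile = 40,
                         n_participants = 20L)
  res0 <- max_percentile_difference(flat, baseline = 40)
  expect_equal(res0$max_diff, 0)
  expect_equal(res0$distance_km, 0.25)
  # bands below min_n are ineligible; none eligible -> undefined
  thin <- tibble::tibble(k = 0:1, mean_percentile = c(10, 90),
                         n_participants = c(3L, 2L))
  expect_warning(und <- max_percentile_difference(thin, baseline = 10),
                 "undefined")
  expect_false(und$defined)
  # distances are odd multiples of 0.25 km
  chain <- exposure_chain(tiny_city(seed = 12), n = 200, seed = 12)
  d <- chain$maxdiff$distance_km[chain$maxdiff$defined]
  expect_true(all(abs(d / 0.25 - round(d / 0.25)) < 1e-9))
  expect_true(all(round(d / 0.25) %% 2 == 1))
})

test_that("gradient city: low-origin difference positive, high-origin negative", {
  for (s in 1:10) {
    chain <- exposure_chain(tiny_city(seed = s, rows = 6, cols = 12),
                            n = 300, seed = s)
    md <- chain$maxdiff
    lo <- md[md$ses_of_origin == "low", ]
    hi <- md[md$ses_of_origin == "high", ]
    if (lo$defined) expect_gt(lo$max_diff, 0)
    if (hi$defined) expect_lt(hi$max_diff, 0)
  }
})

test_that("per-participant SES shares and route overlays are conservative", {
  city <- tiny_city(seed = 14)
  parts <- generate_participants(city, 60, seed = 14)
  trajs <- build_trajectories(city$network, parts)
  per <- suppressWarnings(
    trajectory_ses_shares(trajs, city$network, city$units, by = "participant"))
  sums <- per |>
    dplyr::group_by(id) |>
    dplyr::summarise(s = sum(share))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)
  ov <- route_overlay(city$route, city$units,
                      classes = tidy(theil_index(city$units)))
  expect_equal(sum(ov$fraction[ov$grouping == "ses_category"]), 1,
               tolerance = 1e-9)
  expect_equal(sum(ov$fraction[ov$grouping == "segregation_class"]), 1,
               tolerance = 1e-9)
})

test_that("trajectory wholly inside one category yields a degenerate share", {
  units <- units_from_counts(data.frame(row = 1, col = 1:4,
                                        pop_low = c(10, 10, 0, 0),
                                        pop_middle = 0,
                                        pop_high = c(0, 0, 10, 10)))
  cfg <- city_config(grid_rows = 1, grid_cols = 4, seed = 1)
  net <- generate_network(cfg)
  trajs <- tibble::tibble(id = "a", origin_node = 1, dest_node = 2,
                          ses_of_origin = factor("low", ses_levels()),
                          total_length_m = 500, path = list(c(1, 2)))
  sh <- trajectory_ses_shares(trajs, net, units, by = "participant")
  expect_equal(sh$share[sh$ses_category == "low"], 1)
  expect_equal(sum(sh$share), 1)
})

test_that("permutation p-values follow the add-one formula", {
  sc <- planted_span_scenario(ncols = 8, route_end_col = 5)
  parts <- generate_participants(sc, 80, seed = 31)
  trajs <- build_trajectories(sc$network, parts)
  pmap <- ses_percentile_map(sc$units)
  bands <- suppressWarnings(
    segment_trajectories(trajs, sc$network, sc$units, pmap))
  origins <- dplyr::mutate(
    parts, origin_percentile = pmap$percentile[match(origin_unit,
                                                     pmap$unit_id)])
  res <- permutation_test_maxdiff(bands, origins, "low", B = 99, seed = 2,
                                  min_n = 5)
  expect_true(res$p_value >= 1 / 100 && res$p_value <= 1)
  expect_equal(res$p_value * 100, round(res$p_value * 100))
  expect_error(permutation_test_maxdiff(bands, origins, "low", B = 10),
               class = "ciclovia_argument_error")
  single <- dplyr::mutate(origins, ses_of_origin = "low")
  expect_error(permutation_test_maxdiff(bands, single, "low", B = 99),
               class = "ciclovia_degenerate_error")
})
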