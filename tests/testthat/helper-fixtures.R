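# Small reusable fixtures built in code.

tiny_city <- function(seed = 1, scenario = "crossing", rows = 6, cols = 10) {
  generate_city(city_config(grid_rows = rows, grid_cols = cols,
                            route_scenario = scenario, seed = seed))
}

# full exposure chain on a city; returns the intermediate tables
exposure_chain <- function(city, n = 200, seed = 1, origin_units = NULL,
                           min_n = 10) {
  parts <- generate_participants(city, n, seed = seed,
                                 origin_units = origin_units)
  trajs <- build_trajectories(city$network, parts)
  pmap <- ses_percentile_map(city$units)
  bands <- suppressWarnings(
    segment_trajectories(trajs, city$network, city$units, pmap))
  profile <- suppressWarnings(exposure_profile(bands))
  baselines <- origin_baselines(parts, pmap)
  list(participants = parts, trajectories = trajs, pmap = pmap,
       bands = bands, profile = profile, baselines = baselines,
       maxdiff = suppressWarnings(
         max_diff_by_group(profile, baselines, min_n = min_n)))
}
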