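#' Run the full analysis pipeline on a synthetic city
#'
#' Orchestrates the stages simulate -> entropy -> trajectories -> exposure
#' -> survey with plain-file handoff (GeoJSON/CSV/JSON) and a
#' machine-readable run report with per-file MD5 digests. Stages form a
#' fixed DAG; disabling a stage also skips its dependents' outputs that
#' cannot be computed. Re-running with the same configuration and seed
#' reproduces identical digests.
#'
#' @param config A [city_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_participants Number of synthetic participants.
#' @param effects An [effect_spec()] for the survey stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "entropy", "trajectories", "exposure", "survey")`.
#'   `"simulate"` is always required.
#' @param segment_len_m,min_n Exposure parameters (band length in meters and
#'   minimum participants per band).
#' @param permutations Number of label permutations for the per-group
#'   maximum-difference test.
#' @param seed Seed for all stages; defaults to `config$seed`.
#' @return Invisibly, the run report (also written to `report.json`).
#' @export
run_pipeline <- function(config = city_config(), out_dir = tempfile("ciclovia_run_"),
                         n_participants = 500, effects = effect_spec(),
                         stages = c("simulate", "entropy", "trajectories",
                                    "exposure", "survey"),
                         segment_len_m = 500, min_n = 10, permutations = 199,
                         seed = config$seed) {
  all_stages <- c("simulate", "entropy", "trajectories", "exposure", "survey")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!"simulate" %in% stages) {
    abort("the `simulate` stage is required.", class = "ciclovia_config_error")
  }
  if (("exposure" %in% stages) && !("trajectories" %in% stages)) {
    abort("`exposure` requires the `trajectories` stage.",
          class = "ciclovia_dependency_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }
  report <- list(seed = seed, stages = stages,
                 parameters = list(segment_len_m = segment_len_m, min_n = min_n,
                                   permutations = permutations,
                                   n_participants = n_participants),
                 config = unclass(config))

  # --- simulate ------------------------------------------------------------
  city <- generate_city(config)
  participants <- generate_participants(city, n_participants, seed)
  write_units_geojson(city$units, emit(file.path(out_dir, "units.geojson")))
  write.csv(city$network$nodes, emit(file.path(out_dir, "network_nodes.csv")),
            row.names = FALSE)
  write.csv(city$network$edges, emit(file.path(out_dir, "network_edges.csv")),
            row.names = FALSE)
  write_route_geojson(city$route, emit(file.path(out_dir, "route.geojson")))
  write.csv(participants, emit(file.path(out_dir, "participants.csv")),
            row.names = FALSE)

  # --- entropy -------------------------------------------------------------
  ent <- NULL
  if ("entropy" %in% stages) {
    ent <- theil_index(city$units)
    write.csv(tidy(ent), emit(file.path(out_dir, "entropy.csv")),
              row.names = FALSE)
    jsonlite::write_json(
      c(as.list(glance(ent)), list(cutpoints = unname(ent$cutpoints))),
      emit(file.path(out_dir, "entropy_summary.json")),
      auto_unbox = TRUE, digits = NA)
    report$entropy <- list(H = glance(ent)$H, mean_e = glance(ent)$mean_e)
  }

  # --- trajectories ----------------------------------------------------------
  trajs <- NULL
  if ("trajectories" %in% stages) {
    trajs <- build_trajectories(city$network, participants)
    write_trajectories_geojson(trajs, city$network,
                               emit(file.path(out_dir, "trajectories.geojson")))
  }

  # --- exposure --------------------------------------------------------------
  if ("exposure" %in% stages) {
    pmap <- ses_percentile_map(city$units)
    bands <- suppressWarnings(
      segment_trajectories(trajs, city$network, city$units, pmap,
                           segment_len_m = segment_len_m))
    write.csv(bands, emit(file.path(out_dir, "segments.csv")),
              row.names = FALSE)
    profile <- suppressWarnings(exposure_profile(bands, segment_len_m))
    write.csv(profile, emit(file.path(out_dir, "profiles.csv")),
              row.names = FALSE)
    baselines <- origin_baselines(participants, pmap)
    maxdiff <- max_diff_by_group(profile, baselines, min_n, segment_len_m)
    origins <- dplyr::mutate(
      participants,
      origin_percentile = pmap$percentile[match(.data$origin_unit,
                                                pmap$unit_id)])
    pvals <- purrr::map_dfr(maxdiff$ses_of_origin[maxdiff$defined],
                            function(gr) {
      permutation_test_maxdiff(bands, origins, gr, B = permutations,
                               seed = seed, min_n = min_n)
    })
    maxdiff <- dplyr::left_join(
      maxdiff, dplyr::rename(pvals, ses_of_origin = "group"),
      by = "ses_of_origin")
    jsonlite::write_json(maxdiff, emit(file.path(out_dir, "maxdiff.json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
    shares <- suppressWarnings(
      trajectory_ses_shares(trajs, city$network, city$units, by = "group"))
    overlay <- route_overlay(city$route, city$units,
                             classes = if (!is.null(ent)) tidy(ent) else NULL)
    jsonlite::write_json(list(route_overlay = overlay,
                              trajectory_shares = shares),
                         emit(file.path(out_dir, "overlay.json")),
                         auto_unbox = TRUE, digits = NA)
    report$exposure <- list(
      max_diff = setNames(as.list(maxdiff$max_diff), maxdiff$ses_of_origin))
  }

  # --- survey ----------------------------------------------------------------
  if ("survey" %in% stages) {
    raw <- generate_survey(participants, effects, seed)
    for (ct in names(raw)) {
      write.csv(raw[[ct]],
                emit(file.path(out_dir, sprintf("survey_%s.csv", ct))),
                row.names = FALSE)
    }
    harmonized <- harmonize_survey(raw)
    write.csv(harmonized, emit(file.path(out_dir, "harmonized.csv")),
              row.names = FALSE)
    tab <- descriptive_table(harmonized)
    write.csv(dplyr::left_join(tidy(tab),
                               glance(tab)[, c("variable", "p_value")],
                               by = "variable"),
              emit(file.path(out_dir, "descriptive_table.csv")),
              row.names = FALSE)
    fit <- fit_two_level_logistic(harmonized)
    jsonlite::write_json(list(odds_ratios = tidy(fit),
                              ranef_var = glance(fit)$ranef_var,
                              n = fit$n),
                         emit(file.path(out_dir, "model.json")),
                         auto_unbox = TRUE, digits = NA)
    report$survey <- list(n = fit$n, ranef_var = glance(fit)$ranef_var)
  }

  report$outputs <- as.list(tools::md5sum(sort(written)))
  names(report$outputs) <- basename(sort(written))
  report$package_version <- as.character(utils::packageVersion("ciclovia"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
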