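#' Population-weighted SES percentile of each unit
#'
#' Ranks units by SES score and assigns each the midpoint percentile of its
#' population block: `100 * (cum_pop_below + 0.5 * own_pop) / T`. Units tied
#' on the score share their tied block's midpoint percentile. The
#' population-weighted mean percentile is 50 by construction (up to
#' discreteness), and the map is invariant to monotone rescaling of the
#' score.
#'
#' @param units A unit tibble with `unit_id`, `ses_score` and `pop_total`.
#' @return A tibble (`unit_id`, `percentile`) with percentiles in \[0, 100\].
#' @examples
#' u <- units_from_counts(data.frame(row = 1, col = 1:2,
#'   pop_low = c(10, 0), pop_middle = 0, pop_high = c(0, 10)))
#' ses_percentile_map(u)  # 25 and 75
#' @export
ses_percentile_map <- function(units) {
  if (nrow(units) < 1 || sum(units$pop_total) <= 0) {
    abort("at least one unit with positive population is required.",
          class = "ciclovia_validation_error")
  }
  blocks <- units |>
    dplyr::group_by(.data$ses_score) |>
    dplyr::summarise(block_pop = sum(.data$pop_total)) |>
    dplyr::arrange(.data$ses_score) |>
    dplyr::mutate(
      cum_below = cumsum(.data$block_pop) - .data$block_pop,
      percentile = 100 * (.data$cum_below + 0.5 * .data$block_pop) /
        sum(.data$block_pop)
    )
  tibble(
    unit_id = units$unit_id,
    percentile = blocks$percentile[match(units$ses_score, blocks$ses_score)]
  )
}

#' Cut a trajectory into distance bands and join SES percentiles
#'
#' Divides a trajectory polyline into half-open bands
#' `[k * L, (k + 1) * L)` of length `L = segment_len_m` measured along the
#' path from the origin (k is 0-based), spatially joins the traversed units,
#' and summarises each band. With `join = "length_weighted"` (default) the
#' band value is the length-weighted mean of the percentiles of the units
#' the band's sub-polyline crosses; with `join = "midpoint"` it is the
#' percentile of the unit containing the band's midpoint. A final partial
#' band is kept only if it is at least `min_tail_m` long.
#'
#' @param traj A trajectory tibble with `x`, `y` columns (ordered along the
#'   path), e.g. from [shortest_path_trajectory()].
#' @param units A unit tibble.
#' @param pmap Percentile map from [ses_percentile_map()].
#' @param segment_len_m Band length in meters (default 500).
#' @param min_tail_m Minimum length for the final partial band (default 50).
#' @param join Band-value rule, `"length_weighted"` or `"midpoint"`.
#' @return A tibble (`k`, `start_m`, `end_m`, `length_m`, `value`).
#' @export
segment_trajectory <- function(traj, units, pmap, segment_len_m = 500,
                               min_tail_m = 50,
                               join = c("length_weighted", "midpoint"),
                               loc = unit_locator(units)) {
  join <- match.arg(join)
  pieces <- overlay_polyline(traj$x, traj$y, units, loc = loc)
  if (nrow(pieces) == 0) {
    abort("trajectory has zero length.", class = "ciclovia_validation_error")
  }
  if (all(is.na(pieces$unit_id))) {
    abort("trajectory lies outside the unit tessellation.",
          class = "ciclovia_join_error")
  }
  pieces$percentile <- pmap$percentile[match(pieces$unit_id, pmap$unit_id)]
  if (anyNA(pieces$percentile)) {
    abort("trajectory crosses space outside the unit tessellation.",
          class = "ciclovia_join_error")
  }
  total <- max(pieces$end_m)
  # split pieces at band boundaries
  brk <- if (total > segment_len_m) {
    seq(segment_len_m, total, by = segment_len_m)
  } else numeric(0)
  cuts <- sort(unique(c(pieces$start_m, pieces$end_m, brk)))
  starts <- head(cuts, -1); ends <- cuts[-1]
  mid <- (starts + ends) / 2
  idx <- findInterval(mid, pieces$start_m)
  k <- floor(mid / segment_len_m)
  plen <- ends - starts
  pct <- pieces$percentile[idx]
  ks <- sort(unique(k))
  len_k <- as.numeric(rowsum(plen, k)[, 1])
  val_k <- as.numeric(rowsum(plen * pct, k)[, 1]) / len_k
  out <- tibble(
    k = as.integer(ks),
    start_m = ks * segment_len_m,
    end_m = pmin((ks + 1) * segment_len_m, total),
    length_m = len_k,
    value = val_k
  )
  if (join == "midpoint") {
    band_mid <- (out$start_m + out$end_m) / 2
    pt <- point_along_path(traj$x, traj$y, band_mid)
    uid <- locate_with(loc, pt$x, pt$y)
    out$value <- pmap$percentile[match(uid, pmap$unit_id)]
  }
  # drop a short final partial band
  last <- nrow(out)
  if (out$length_m[last] < segment_len_m - 1e-9 &&
      out$length_m[last] < min_tail_m) {
    out <- out[-last, , drop = FALSE]
  }
  out
}

# coordinates of points at given distances along a polyline
point_along_path <- function(x, y, at) {
  seg_len <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg_len))
  at <- pmin(pmax(at, 0), max(cum))
  i <- pmax(findInterval(at, cum, rightmost.closed = TRUE), 1L)
  frac <- ifelse(seg_len[i] > 0, (at - cum[i]) / seg_len[i], 0)
  list(x = x[i] + frac * (x[i + 1L] - x[i]),
       y = y[i] + frac * (y[i + 1L] - y[i]))
}

#' Band tables for a roster of trajectories
#'
#' Applies [segment_trajectory()] to every trajectory in a roster built by
#' [build_trajectories()], returning one tidy band table. Zero-length
#' trajectories (origin at the interview point) are skipped with a warning.
#'
#' @param trajectories Output of [build_trajectories()].
#' @param network A `ciclovia_network`.
#' @param units A unit tibble.
#' @param pmap Percentile map from [ses_percentile_map()].
#' @inheritParams segment_trajectory
#' @return A tibble (`id`, `ses_of_origin` if available, `k`, `value`,
#'   `length_m`).
#' @export
segment_trajectories <- function(trajectories, network, units, pmap,
                                 segment_len_m = 500, min_tail_m = 50,
                                 join = "length_weighted") {
  zero <- trajectories$total_length_m <= 0
  if (any(zero)) {
    warn(sprintf("%d zero-length trajectories skipped.", sum(zero)))
  }
  keep <- which(!zero)
  loc <- unit_locator(units)
  res <- lapply(keep, function(i) {
    coords <- trajectory_coords(network, trajectories$path[[i]])
    bt <- segment_trajectory(coords, units, pmap, segment_len_m,
                             min_tail_m, join, loc = loc)
    bt$id <- trajectories$id[i]
    bt
  })
  out <- dplyr::bind_rows(res)
  if ("ses_of_origin" %in% names(trajectories)) {
    out$ses_of_origin <- trajectories$ses_of_origin[
      match(out$id, trajectories$id)]
    out <- out[, c("id", "ses_of_origin", "k", "value", "length_m")]
  } else {
    out <- out[, c("id", "k", "value", "length_m")]
  }
  out
}

#' Group exposure profile over distance bands
#'
#' For each SES-of-origin group and 0-based band index `k`, the mean and
#' sample variance (0 when a single participant is present) of the band
#' values across participants whose trajectory reaches band `k`, and the
#' number of such participants. Participants shorter than a band simply drop
#' out of it.
#'
#' @param bands Band table from [segment_trajectories()] (columns `id`,
#'   `ses_of_origin`, `k`, `value`).
#' @param segment_len_m Band length used when building `bands`.
#' @return A tibble of class `ciclovia_profile` (`ses_of_origin`, `k`,
#'   `distance_km` = band midpoint, `mean_percentile`, `variance`,
#'   `n_participants`).
#' @export
exposure_profile <- function(bands, segment_len_m = 500) {
  present <- unique(bands$ses_of_origin)
  missing_groups <- setdiff(ses_levels(), as.character(present))
  if (length(missing_groups) > 0) {
    warn(sprintf("no participants with SES-of-origin: %s; group(s) skipped.",
                 paste(missing_groups, collapse = ", ")))
  }
  out <- bands |>
    dplyr::group_by(.data$ses_of_origin, .data$k) |>
    dplyr::summarise(
      mean_percentile = mean(.data$value),
      variance = if (dplyr::n() > 1) var(.data$value) else 0,
      n_participants = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(distance_km = (.data$k + 0.5) * segment_len_m / 1000) |>
    dplyr::arrange(.data$ses_of_origin, .data$k) |>
    dplyr::select("ses_of_origin", "k", "distance_km", "mean_percentile",
                  "variance", "n_participants")
  class(out) <- c("ciclovia_profile", class(out))
  out
}

#' Mean origin percentile per SES-of-origin group
#'
#' The baseline against which band exposures are compared: the average SES
#' percentile of the participants' units of origin, per group.
#'
#' @param participants Tibble with `origin_unit` and `ses_of_origin`.
#' @param pmap Percentile map from [ses_percentile_map()].
#' @return A tibble (`ses_of_origin`, `baseline`).
#' @export
origin_baselines <- function(participants, pmap) {
  participants |>
    dplyr::mutate(p = pmap$percentile[match(.data$origin_unit, pmap$unit_id)]) |>
    dplyr::group_by(.data$ses_of_origin) |>
    dplyr::summarise(baseline = mean(.data$p), .groups = "drop")
}

#' Maximum SES percentile difference of an exposure profile
#'
#' Over bands with at least `min_n` participants, finds the band whose mean
#' exposure deviates most (in absolute value) from the group's origin
#' baseline; ties go to the smallest band index. Returns the signed
#' difference and the distance at which it is achieved, reported at the band
#' midpoint `(k + 0.5) * segment_len_m / 1000` km (odd multiples of 0.25 km
#' for 500-m bands).
#'
#' @param profile One group's rows of an [exposure_profile()] (columns `k`,
#'   `mean_percentile`, `n_participants`).
#' @param baseline The group's origin mean percentile.
#' @param min_n Minimum participants for a band to be eligible (default 10).
#' @param segment_len_m Band length in meters.
#' @return A one-row tibble (`baseline`, `max_diff`, `k`, `distance_km`,
#'   `n_at_band`, `defined`). When no band meets `min_n`, `defined` is FALSE
#'   and the statistics are NA.
#' @export
max_percentile_difference <- function(profile, baseline, min_n = 10,
                                      segment_len_m = 500) {
  stopifnot_scalar_count(min_n, "min_n")
  if (nrow(profile) == 0) {
    abort("empty exposure profile.", class = "ciclovia_validation_error")
  }
  elig <- profile[profile$n_participants >= min_n, , drop = FALSE]
  if (nrow(elig) == 0) {
    warn(sprintf("no band has >= %d participants; maximum difference undefined.",
                 min_n))
    return(tibble(baseline = baseline, max_diff = NA_real_, k = NA_integer_,
                  distance_km = NA_real_, n_at_band = NA_integer_,
                  defined = FALSE))
  }
  diffs <- elig$mean_percentile - baseline
  star <- which.max(abs(diffs))  # first max: smallest k on ties
  tibble(
    baseline = baseline,
    max_diff = diffs[star],
    k = as.integer(elig$k[star]),
    distance_km = (elig$k[star] + 0.5) * segment_len_m / 1000,
    n_at_band = as.integer(elig$n_participants[star]),
    defined = TRUE
  )
}

#' Maximum percentile differences for all SES-of-origin groups
#'
#' @param profile An [exposure_profile()] covering one or more groups.
#' @param baselines Tibble from [origin_baselines()].
#' @inheritParams max_percentile_difference
#' @return A tibble with one row per group.
#' @export
max_diff_by_group <- function(profile, baselines, min_n = 10,
                              segment_len_m = 500) {
  groups <- intersect(as.character(unique(profile$ses_of_origin)),
                      as.character(baselines$ses_of_origin))
  purrr::map_dfr(groups, function(gr) {
    pf <- profile[profile$ses_of_origin == gr, , drop = FALSE]
    b <- baselines$baseline[baselines$ses_of_origin == gr]
    res <- max_percentile_difference(pf, b, min_n, segment_len_m)
    dplyr::bind_cols(tibble(ses_of_origin = gr), res)
  })
}

#' Permutation test for a group's maximum percentile difference
#'
#' Tests whether a group's maximum SES percentile difference could arise if
#' SES-of-origin labels were unrelated to trajectories. Labels (together
#' with each participant's origin percentile, since the baseline travels
#' with the label) are permuted across participants `B` times; the
#' add-one p-value is `(1 + #permuted |max_diff| >= observed) / (B + 1)`.
#'
#' @param bands Band table from [segment_trajectories()].
#' @param origins Tibble with `id`, `ses_of_origin` and `origin_percentile`
#'   per participant (see [origin_baselines()] for the group version).
#' @param group Which SES-of-origin group to test.
#' @param B Number of permutations (>= 99).
#' @param seed Integer seed (substream `"permutation"`).
#' @param min_n Band eligibility threshold, as in
#'   [max_percentile_difference()].
#' @return A one-row tibble (`group`, `observed`, `B`, `p_value`).
#' @export
permutation_test_maxdiff <- function(bands, origins, group, B = 999, seed = 1,
                                     min_n = 10) {
  if (B < 99) {
    abort("at least 99 permutations are required.",
          class = "ciclovia_argument_error")
  }
  labs <- as.character(origins$ses_of_origin)
  if (length(unique(labs)) < 2) {
    abort("permutation test needs at least two distinct SES-of-origin labels.",
          class = "ciclovia_degenerate_error")
  }
  if (!group %in% labs) {
    abort(sprintf("no participant has SES-of-origin '%s'.", group),
          class = "ciclovia_argument_error")
  }
  ids <- origins$id
  ks <- sort(unique(bands$k))
  M <- matrix(NA_real_, nrow = length(ids), ncol = length(ks),
              dimnames = list(ids, ks))
  M[cbind(match(bands$id, ids), match(bands$k, ks))] <- bands$value
  opct <- origins$origin_percentile
  present <- !is.na(M)

  stat_for <- function(member) {
    n_k <- colSums(present[member, , drop = FALSE])
    ok <- n_k >= min_n
    if (!any(ok)) return(NA_real_)
    means <- colSums(M[member, , drop = FALSE] * present[member, , drop = FALSE],
                     na.rm = TRUE)[ok] / n_k[ok]
    max(abs(means - mean(opct[member])))
  }

  member_obs <- labs == group
  observed <- stat_for(member_obs)
  if (is.na(observed)) {
    abort("observed maximum difference is undefined (no eligible band).",
          class = "ciclovia_degenerate_error")
  }
  n_g <- sum(member_obs)
  n <- length(labs)
  perm_stats <- with_substream(seed, "permutation", {
    vapply(seq_len(B), function(b) {
      member <- logical(n)
      member[sample.int(n, n_g)] <- TRUE
      stat_for(member)
    }, numeric(1))
  })
  perm_stats[is.na(perm_stats)] <- -Inf
  p <- (1 + sum(perm_stats >= observed - 1e-12)) / (B + 1)
  tibble(group = group, observed = observed, B = as.integer(B), p_value = p)
}

#' Share of trajectory length by unit SES category
#'
#' Per participant, the fraction of trajectory length spent in units of each
#' harmonized SES category (shares sum to 1); optionally averaged within
#' SES-of-origin groups. Zero-length trajectories are excluded with a
#' warning.
#'
#' @param trajectories Output of [build_trajectories()].
#' @param network A `ciclovia_network`.
#' @param units A unit tibble (carries `ses_category`).
#' @param by `"group"` for per-group means, `"participant"` for raw shares.
#' @return A tibble (`ses_of_origin` or `id`, `ses_category`, `share`).
#' @export
trajectory_ses_shares <- function(trajectories, network, units,
                                  by = c("group", "participant")) {
  by <- match.arg(by)
  zero <- trajectories$total_length_m <= 0
  if (any(zero)) {
    warn(sprintf("%d zero-length trajectories excluded.", sum(zero)))
  }
  keep <- which(!zero)
  loc <- unit_locator(units)
  per <- purrr::map_dfr(keep, function(i) {
    coords <- trajectory_coords(network, trajectories$path[[i]])
    pieces <- overlay_polyline(coords$x, coords$y, units, loc = loc)
    pieces$ses_category <- units$ses_category[
      match(pieces$unit_id, units$unit_id)]
    sh <- pieces |>
      dplyr::group_by(.data$ses_category) |>
      dplyr::summarise(len = sum(.data$length_m), .groups = "drop") |>
      tidyr::complete(ses_category = factor(ses_levels(), levels = ses_levels()),
                      fill = list(len = 0))
    tibble(id = trajectories$id[i],
           ses_of_origin = trajectories$ses_of_origin[i],
           ses_category = sh$ses_category,
           share = sh$len / sum(sh$len))
  })
  if (by == "participant") return(per)
  per |>
    dplyr::group_by(.data$ses_of_origin, .data$ses_category) |>
    dplyr::summarise(share = mean(.data$share), .groups = "drop")
}
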