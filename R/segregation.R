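#' Entropy score of a composition
#'
#' Shannon entropy (natural log) of a vector of group proportions,
#' with the convention that empty groups contribute nothing
#' (\eqn{0 \log(1/0) = 0}). For a unit inhabited by a single SES group the
#' score is 0; for equal group shares it is \eqn{\log r}.
#'
#' @param proportions Numeric vector of group proportions summing to 1
#'   (within 1e-9).
#' @return Entropy in nats.
#' @examples
#' entropy_score(c(1, 0, 0))        # 0
#' entropy_score(rep(1 / 3, 3))     # log(3)
#' @export
entropy_score <- function(proportions) {
  if (any(is.na(proportions)) || any(proportions < 0)) {
    abort("proportions must be non-negative and non-missing.",
          class = "ciclovia_validation_error")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort(sprintf("proportions must sum to 1 (got %.12f).", sum(proportions)),
          class = "ciclovia_validation_error")
  }
  p <- proportions[proportions > 0]
  sum(p * log(1 / p))
}

#' Classify units into evenness quartile classes
#'
#' Cuts normalized local entropies at their empirical quartiles (linear
#' interpolation). Ascending classes: `highly_segregated` (< Q1),
#' `segregated` ([Q1, Q2)), `integrated` ([Q2, Q3)), `highly_integrated`
#' (>= Q3). Low local entropy means the unit is dominated by one SES group.
#'
#' @param e Numeric vector of normalized local entropies in \[0, 1\] (at
#'   least 4 non-missing values).
#' @return A factor with the four class levels (NA where `e` is NA). If all
#'   values are identical a single-class factor is returned with a warning.
#' @export
classify_by_quantiles <- function(e) {
  ok <- !is.na(e)
  if (sum(ok) < 4) {
    abort("at least 4 units are needed for quartile classification.",
          class = "ciclovia_validation_error")
  }
  qs <- quantile(e[ok], probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (max(e[ok]) - min(e[ok]) < .Machine$double.eps^0.5) {
    warn("all local entropies are identical; quartile classes collapse to one.")
  }
  lev <- seg_class_levels()
  cls <- ifelse(e < qs[1], lev[1],
         ifelse(e < qs[2], lev[2],
         ifelse(e < qs[3], lev[3], lev[4])))
  structure(factor(cls, levels = lev), cutpoints = qs)
}

#' Theil evenness index of urban segregation
#'
#' Computes, for a table of geographic units with per-SES-group population
#' counts, the per-unit entropy score \eqn{E_i}, the normalized local
#' entropy \eqn{e_i = E_i / \log r \in [0,1]}, the metropolitan entropy
#' \eqn{E}, and the Theil index
#' \deqn{H = \sum_i t_i (E - E_i) / (E \, T),}
#' the population-weighted average shortfall of unit entropy relative to the
#' metropolitan entropy. \eqn{H = 0} when every unit mirrors the
#' metropolitan composition (no segregation) and \eqn{H = 1} when no two SES
#' groups share a unit (complete separation). Because the index is built
#' from diversity shortfalls, a city-level summary of the local entropies
#' themselves (`mean_e`, `sd_e`) is reported alongside `H`: the two answer
#' different questions (average local diversity vs. city-wide evenness) and
#' both unweighted and population-weighted summaries are emitted.
#'
#' @param units A data frame with `unit_id` and per-group count columns.
#' @param groups Names of the count columns, ordered low/middle/high.
#' @return An object of class `ciclovia_entropy`: list with `units`
#'   (tibble: `unit_id`, `t_i`, `E_i`, `e_i`, `class`), `summary` (tibble:
#'   `E`, `H`, `mean_e`, `sd_e`, `mean_e_weighted`, `sd_e_weighted`,
#'   `n_units`, `total_pop`) and `cutpoints`. Use [tidy()] / [glance()] to
#'   extract them.
#' @examples
#' tab <- data.frame(unit_id = c("a", "b"),
#'                   pop_low = c(100, 0), pop_middle = c(0, 0),
#'                   pop_high = c(0, 100))
#' glance(theil_index(tab))$H  # 1: complete separation
#' @export
theil_index <- function(units, groups = c("pop_low", "pop_middle", "pop_high")) {
  if (!all(groups %in% names(units))) {
    abort(paste("missing count columns:",
                paste(setdiff(groups, names(units)), collapse = ", ")),
          class = "ciclovia_validation_error")
  }
  cm <- as.matrix(units[, groups])
  if (any(cm < 0) || anyNA(cm)) {
    abort("group counts must be non-negative and non-missing.",
          class = "ciclovia_validation_error")
  }
  t_i <- rowSums(cm)
  T_pop <- sum(t_i)
  if (T_pop <= 0) {
    abort("total population must be positive.", class = "ciclovia_validation_error")
  }
  r <- length(groups)
  P <- colSums(cm) / T_pop
  E <- entropy_score(P)
  if (E <= 0) {
    abort(paste("metropolitan entropy is zero (a single SES group inhabits",
                "the whole city); the Theil index H is undefined."),
          class = "ciclovia_degenerate_error")
  }
  E_i <- rep(NA_real_, nrow(cm))
  pos <- t_i > 0
  E_i[pos] <- vapply(which(pos), function(i) entropy_score(cm[i, ] / t_i[i]),
                     numeric(1))
  e_i <- E_i / log(r)
  H <- sum(t_i[pos] * (E - E_i[pos])) / (E * T_pop)
  cls <- classify_by_quantiles(e_i)
  unit_tab <- tibble(
    unit_id = as.character(units$unit_id),
    t_i = t_i, E_i = E_i, e_i = e_i, class = cls
  )
  w <- t_i[pos] / T_pop
  mw <- sum(w * e_i[pos])
  summary_tab <- tibble(
    E = E, H = H,
    mean_e = mean(e_i, na.rm = TRUE), sd_e = sd(e_i, na.rm = TRUE),
    mean_e_weighted = mw,
    sd_e_weighted = sqrt(sum(w * (e_i[pos] - mw)^2)),
    n_units = nrow(cm), total_pop = T_pop
  )
  structure(list(units = unit_tab, summary = summary_tab,
                 cutpoints = attr(cls, "cutpoints")),
            class = "ciclovia_entropy")
}

#' @export
print.ciclovia_entropy <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ciclovia_entropy> %d units | H = %.4f | mean e_i = %.3f (sd %.3f)\n",
              s$n_units, s$H, s$mean_e, s$sd_e))
  invisible(x)
}

#' @rdname theil_index
#' @param x A `ciclovia_entropy` object.
#' @param ... Unused.
#' @export
tidy.ciclovia_entropy <- function(x, ...) x$units

#' @rdname theil_index
#' @export
glance.ciclovia_entropy <- function(x, ...) x$summary
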