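#' Two-level logistic model for meeting the PA recommendation
#'
#' Fits a random-intercept logistic regression by maximum likelihood
#' (Laplace approximation via [lme4::glmer()]): participants at level one,
#' survey city at level two. Reference levels follow the reporting
#' convention: male sex, low SES, primary education. Odds ratios carry Wald
#' 95% confidence intervals.
#'
#' @param data Harmonized tibble (e.g. from [harmonize_survey()]).
#' @param outcome Name of a yes/no outcome column (default
#'   `"meets_pa_program"`).
#' @param covariates Fixed-effect covariate names (factors).
#' @param group Grouping column for the random intercept (default `"city"`).
#' @return Object of class `ciclovia_mlm`: list with `or_table` (tibble:
#'   `term`, `estimate` = odds ratio, `conf_low`, `conf_high`, `p_value`),
#'   `ranef_var` (city-level intercept variance), `fit` (the `glmerMod`),
#'   `n`, `n_groups`, `dropped` (constant covariates removed). `tidy()`
#'   returns the OR table, `glance()` the variance components.
#' @export
fit_two_level_logistic <- function(data, outcome = "meets_pa_program",
                                   covariates = c("sex", "ses3", "education"),
                                   group = "city") {
  need <- c(outcome, covariates, group)
  if (!all(need %in% names(data))) {
    abort(paste("missing columns:",
                paste(setdiff(need, names(data)), collapse = ", ")),
          class = "ciclovia_argument_error")
  }
  df <- data[stats::complete.cases(data[, need]), need, drop = FALSE]
  y <- df[[outcome]]
  y <- if (is.factor(y)) as.integer(y == "yes") else as.integer(y)
  if (length(unique(y)) < 2) {
    abort("outcome does not vary.", class = "ciclovia_fit_error")
  }
  if (length(unique(df[[group]])) < 2) {
    abort("at least two groups are required for a random intercept.",
          class = "ciclovia_fit_error")
  }
  keep <- covariates[vapply(covariates, function(v) {
    length(unique(df[[v]])) > 1
  }, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped) > 0) {
    warn(paste("dropping constant covariate(s):",
               paste(dropped, collapse = ", ")))
  }
  if (length(keep) == 0) {
    abort("no non-constant covariates left.", class = "ciclovia_fit_error")
  }
  # reference levels: male, low SES, primary education
  refs <- c(sex = "male", ses3 = "low", education = "primary")
  for (v in keep) {
    df[[v]] <- droplevels(factor(df[[v]]))
    if (v %in% names(refs) && refs[[v]] %in% levels(df[[v]])) {
      df[[v]] <- stats::relevel(df[[v]], ref = refs[[v]])
    }
  }
  df$.y <- y
  fml <- as.formula(paste(".y ~", paste(keep, collapse = " + "),
                          "+ (1 |", group, ")"))
  fit <- withCallingHandlers(
    lme4::glmer(fml, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("failed to converge|Model failed", conditionMessage(w))) {
        abort(paste("two-level logistic fit did not converge:",
                    conditionMessage(w)),
              class = "ciclovia_fit_error")
      }
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)[rownames(sm) != "(Intercept)"]
  est <- sm[terms, "Estimate"]
  se <- sm[terms, "Std. Error"]
  if (any(se > 50)) {
    abort("fit is unstable (enormous standard errors suggest separation).",
          class = "ciclovia_fit_error")
  }
  z <- qnorm(0.975)
  or_table <- tibble(
    term = terms,
    estimate = exp(est),
    conf_low = exp(est - z * se),
    conf_high = exp(est + z * se),
    p_value = sm[terms, "Pr(>|z|)"]
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    or_table = or_table,
    ranef_var = vc$vcov[1],
    fit = fit,
    n = nrow(df),
    n_groups = length(unique(df[[group]])),
    dropped = dropped
  ), class = "ciclovia_mlm")
}

#' @export
print.ciclovia_mlm <- function(x, ...) {
  cat(sprintf("<ciclovia_mlm> n = %d in %d groups | random-intercept var %.4f\n",
              x$n, x$n_groups, x$ranef_var))
  print(x$or_table)
  invisible(x)
}

#' @rdname fit_two_level_logistic
#' @param x A `ciclovia_mlm` object.
#' @param ... Unused.
#' @export
tidy.ciclovia_mlm <- function(x, ...) x$or_table

#' @rdname fit_two_level_logistic
#' @export
glance.ciclovia_mlm <- function(x, ...) {
  tibble(ranef_var = x$ranef_var, ranef_sd = sqrt(x$ranef_var),
         n = x$n, n_groups = x$n_groups,
         logLik = as.numeric(stats::logLik(x$fit)),
         AIC = stats::AIC(x$fit))
}
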