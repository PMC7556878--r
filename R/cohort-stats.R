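# Mixed-effects treatment comparison for nested vessel measurements
# (vessels within animals), Bonferroni correction, and auxiliary tests.

# fractional (default) or raw-um diameter change per vessel
delta_d <- function(table, scale = c("fractional", "um")) {
  scale <- match.arg(scale)
  if (!all(c("animal_id", "d_vehicle_um", "d_treatment_um") %in%
           names(table)))
    stop_invalid("cohort table needs animal_id, d_vehicle_um, d_treatment_um")
  if (scale == "fractional")
    table$d_treatment_um / table$d_vehicle_um - 1
  else table$d_treatment_um - table$d_vehicle_um
}

#' Mixed-effects estimate of a treatment effect on vessel diameter
#'
#' Fits the random-intercept model `dD[n, a] = gamma + beta[a]` by REML,
#' where `dD` is the per-vessel diameter change between vehicle and
#' treatment (fractional change, i.e. treatment / vehicle - 1, by
#' default), `gamma` the fixed treatment effect, and `beta[a] ~ N(0,
#' sigma_animal^2)` the per-animal random intercept that absorbs
#' within-animal correlation. Significance of `gamma != 0` uses the
#' Satterthwaite degrees-of-freedom approximation (via lmerTest), which
#' keeps the test calibrated at the small animal counts typical of these
#' designs.
#'
#' @param table cohort data.frame with columns `animal_id`,
#'   `d_vehicle_um`, `d_treatment_um` (e.g. from [make_cohort()]).
#' @param scale `"fractional"` (default, percent-change style) or `"um"`.
#' @param n_groups number of comparison groups for the Bonferroni
#'   correction (default 1 = no correction).
#' @param conf_level confidence level for the CI on gamma.
#' @return a `mixed_model_result`: list with `gamma`, `gamma_se`, `df`,
#'   `p_raw`, `p_corrected`, `ci`, `beta_a` (random intercepts),
#'   `sigma_animal`, `sigma_resid`, `n_animals`, `n_vessels`, `model`.
#' @export
fit_lme_delta <- function(table, scale = c("fractional", "um"),
                          n_groups = 1, conf_level = 0.95) {
  scale <- match.arg(scale)
  dd <- delta_d(table, scale)
  df <- data.frame(dd = dd, animal = factor(table$animal_id))
  if (nlevels(df$animal) < 2)
    stop_invalid("degenerate-design: a single animal cannot support a ",
                 "random intercept; use a one-sample test on its vessels")
  if (nrow(df) < 2) stop_invalid("need at least 2 vessels")
  if (var(df$dd) == 0) {
    # no variation at all: the effect equals the common value and the
    # mixed model is degenerate (0/0 t-statistic)
    g <- df$dd[1]
    return(structure(
      list(gamma = g, gamma_se = 0, df = nlevels(df$animal) - 1,
           p_raw = if (g == 0) 1 else 0,
           p_corrected = bonferroni_correct(if (g == 0) 1 else 0, n_groups),
           ci = c(g, g),
           beta_a = setNames(rep(0, nlevels(df$animal)),
                             levels(df$animal)),
           sigma_animal = 0, sigma_resid = 0,
           n_animals = nlevels(df$animal), n_vessels = nrow(df),
           scale = scale, model = "dD ~ gamma + (1 | animal)"),
      class = "mixed_model_result"))
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(dd ~ 1 + (1 | animal), data = df, REML = TRUE)))
  sm <- summary(fit)$coefficients
  gamma <- sm[1, "Estimate"]
  se <- sm[1, "Std. Error"]
  dof <- sm[1, "df"]
  p <- sm[1, "Pr(>|t|)"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  tcrit <- qt(1 - (1 - conf_level) / 2, dof)
  structure(
    list(gamma = gamma, gamma_se = se, df = dof, p_raw = p,
         p_corrected = bonferroni_correct(p, n_groups),
         ci = c(gamma - tcrit * se, gamma + tcrit * se),
         beta_a = setNames(lme4::ranef(fit)$animal[, 1],
                           rownames(lme4::ranef(fit)$animal)),
         sigma_animal = vc$sdcor[vc$grp == "animal"],
         sigma_resid = vc$sdcor[vc$grp == "Residual"],
         n_animals = nlevels(df$animal), n_vessels = nrow(df),
         scale = scale, model = "dD ~ gamma + (1 | animal)"),
    class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(
    "<mixed_model_result> %s\n  gamma = %.4g +/- %.3g (df %.1f), p = %.3g (corrected %.3g)\n  %d animals, %d vessels\n",
    x$model, x$gamma, x$gamma_se, x$df, x$p_raw, x$p_corrected,
    x$n_animals, x$n_vessels))
  if (!is.null(x$alpha))
    cat(sprintf("  baseline slope alpha = %.4g (p = %.3g)\n",
                x$alpha, x$alpha_p))
  invisible(x)
}

#' Mixed-effects model with a baseline-diameter covariate
#'
#' Fits `dD[n, a] = gamma + beta[a] + alpha * D[n]`, where `D[n]` is the
#' vessel's diameter in the vehicle (control) condition; used for
#' baseline-versus-effect regression lines. A single shared `alpha` is
#' estimated (a per-vessel coefficient vector would be unidentifiable
#' with one observation per vessel).
#'
#' @inheritParams fit_lme_delta
#' @return a `mixed_model_result` with `alpha`, `alpha_se`, `alpha_p`,
#'   `alpha_ci` added.
#' @export
fit_lme_with_baseline <- function(table, scale = c("fractional", "um"),
                                  n_groups = 1, conf_level = 0.95) {
  scale <- match.arg(scale)
  dd <- delta_d(table, scale)
  if (is.null(table$d_vehicle_um) || all(is.na(table$d_vehicle_um)))
    stop_invalid("empty baseline covariate column")
  df <- data.frame(dd = dd, d0 = table$d_vehicle_um,
                   animal = factor(table$animal_id))
  if (nlevels(df$animal) < 2)
    stop_invalid("degenerate-design: need at least 2 animals")
  if (var(df$d0) == 0)
    stop_invalid("baseline covariate has no variance")
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(dd ~ 1 + d0 + (1 | animal), data = df, REML = TRUE)))
  sm <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  g <- sm["(Intercept)", ]; a <- sm["d0", ]
  tg <- qt(1 - (1 - conf_level) / 2, g[["df"]])
  ta <- qt(1 - (1 - conf_level) / 2, a[["df"]])
  structure(
    list(gamma = g[["Estimate"]], gamma_se = g[["Std. Error"]],
         df = g[["df"]], p_raw = g[["Pr(>|t|)"]],
         p_corrected = bonferroni_correct(g[["Pr(>|t|)"]], n_groups),
         ci = g[["Estimate"]] + c(-1, 1) * tg * g[["Std. Error"]],
         alpha = a[["Estimate"]], alpha_se = a[["Std. Error"]],
         alpha_p = a[["Pr(>|t|)"]],
         alpha_ci = a[["Estimate"]] + c(-1, 1) * ta * a[["Std. Error"]],
         beta_a = setNames(lme4::ranef(fit)$animal[, 1],
                           rownames(lme4::ranef(fit)$animal)),
         sigma_animal = vc$sdcor[vc$grp == "animal"],
         sigma_resid = vc$sdcor[vc$grp == "Residual"],
         n_animals = nlevels(df$animal), n_vessels = nrow(df),
         scale = scale, model = "dD ~ gamma + alpha * D0 + (1 | animal)"),
    class = "mixed_model_result")
}

#' Bonferroni correction for a family of comparisons
#'
#' `p_corrected = min(1, p_raw * n_groups)`: corrected values exceeding 1
#' are rounded down to 1.
#'
#' @param p_raw raw p-value(s).
#' @param n_groups number of comparisons in the family (e.g. 7 chemogenetic
#'   groups or 6 infusion conditions).
#' @return corrected p-value(s).
#' @export
bonferroni_correct <- function(p_raw, n_groups) {
  if (n_groups < 1) stop_invalid("n_groups must be >= 1")
  pmin(1, p_raw * n_groups)
}

#' Paired t-test for per-animal vehicle vs treatment values
#'
#' Two-sided paired t-test (e.g. on per-animal gamma-band power). Pairs
#' with zero variance in their differences are degenerate and flagged
#' rather than tested.
#'
#' @param x_vehicle,x_treatment paired per-animal values.
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_power_ttest <- function(x_vehicle, x_treatment) {
  stopifnot(length(x_vehicle) == length(x_treatment))
  d <- x_treatment - x_vehicle
  if (length(d) < 2) stop_invalid("need at least 2 pairs")
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, df = length(d) - 1, mean_diff = 0,
                  degenerate = FALSE))
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(x_treatment, x_vehicle, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Regression of diameter change on gamma-power change across conditions
#'
#' Ordinary least-squares fit of per-condition mean diameter changes on
#' per-condition mean gamma-power changes. With only two points the fit is
#' exact and the p-value undefined (flagged).
#'
#' @param diameter_changes,gamma_changes per-condition means.
#' @return list with `slope`, `intercept`, `p`, `r_squared`,
#'   `degenerate`.
#' @export
cross_condition_regression <- function(diameter_changes, gamma_changes) {
  stopifnot(length(diameter_changes) == length(gamma_changes))
  n <- length(diameter_changes)
  if (n < 2) stop_invalid("need at least 2 conditions")
  fit <- lm(diameter_changes ~ gamma_changes)
  sm <- summary(fit)
  if (n == 2)
    return(list(slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
                p = NA_real_, r_squared = 1, degenerate = TRUE))
  list(slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
       p = sm$coefficients["gamma_changes", "Pr(>|t|)"],
       r_squared = sm$r.squared, degenerate = FALSE)
}
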