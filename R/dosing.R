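# Dose-regimen simulation against the AGNP therapeutic reference range
# for escitalopram: trough window 15-80 ng/ml, laboratory alert level
# 160 ng/ml.

.WINDOW_BANDS <- c("<15", "15-80", "80-160", ">=160")

#' Dosing regimen
#'
#' @param dose Dose per administration (mg).
#' @param tau Dosing interval (h); 24 for once daily (qd), 12 for twice
#'   daily (bid).
#' @param label Optional display label (default e.g. `"10 mg qd"`).
#' @return A list of class `"pk_regimen"` with `dose`, `tau`, `label`
#'   and the implied `daily_dose`.
#' @examples
#' regimen(10, 24)
#' regimen(5, 12)   # 5 mg bid = 10 mg/day
#' @export
regimen <- function(dose, tau = 24, label = NULL) {
  stopifnot(dose > 0, tau > 0)
  lab <- label %||% sprintf("%g mg %s", dose,
                            if (tau == 24) "qd"
                            else if (tau == 12) "bid"
                            else sprintf("q%gh", tau))
  structure(list(dose = dose, tau = tau, label = lab,
                 daily_dose = dose * 24 / tau),
            class = "pk_regimen")
}

#' @export
print.pk_regimen <- function(x, ...) {
  cat(sprintf("Regimen: %s (%g mg/day)\n", x$label, x$daily_dose))
  invisible(x)
}

#' Classify a concentration against the therapeutic window
#'
#' Bands follow the reference-range conventions: below 15 ng/ml
#' (subtherapeutic), 15-80 ng/ml inclusive (therapeutic), above 80 and
#' below 160 (high), at or above 160 ng/ml (laboratory alert).
#'
#' @param c Concentration(s) in ng/ml, `>= 0`.
#' @param lower,upper,alert Band boundaries (ng/ml).
#' @return Factor with levels `"<15"`, `"15-80"`, `"80-160"`, `">=160"`
#'   (labels follow the boundaries supplied).
#' @examples
#' classify_concentration(c(14.9, 15, 80, 80.1, 160))
#' @export
classify_concentration <- function(c, lower = 15, upper = 80,
                                   alert = 160) {
  if (any(c < 0)) stop("concentrations must be >= 0")
  bands <- band_labels(lower, upper, alert)
  out <- ifelse(c < lower, bands[1],
                ifelse(c <= upper, bands[2],
                       ifelse(c < alert, bands[3], bands[4])))
  factor(out, levels = bands)
}

band_labels <- function(lower, upper, alert) {
  c(sprintf("<%g", lower), sprintf("%g-%g", lower, upper),
    sprintf("%g-%g", upper, alert), sprintf(">=%g", alert))
}

#' Therapeutic-window report
#'
#' Counts and percentages of concentrations per window band; percentages
#' are `100 * count / total` reported to 2 decimals.
#'
#' @param concentrations Non-empty numeric vector (ng/ml).
#' @inheritParams classify_concentration
#' @return A data frame with columns `band`, `count`, `percent`.
#' @examples
#' window_report(c(10, 20, 50, 90, 170))
#' @export
window_report <- function(concentrations, lower = 15, upper = 80,
                          alert = 160) {
  if (length(concentrations) == 0) stop("empty concentration list")
  cls <- classify_concentration(concentrations, lower, upper, alert)
  counts <- table(cls)
  data.frame(band = names(counts),
             count = as.integer(counts),
             percent = round(100 * as.integer(counts) /
                               length(concentrations), 2),
             row.names = NULL)
}

#' Typical-subject steady-state trough
#'
#' Steady-state trough concentration for the covariate-adjusted typical
#' subject (random effects at zero) of a given age and CYP2C19
#' phenotype under a regimen, using the closed-form accumulation
#' formula.
#'
#' @param pop A [pk_params()] object.
#' @param age Age in years.
#' @param phenotype `"EM"`, `"IM"` or `"PM"`.
#' @param reg A [regimen()].
#' @return Trough concentration (ng/ml).
#' @examples
#' simulate_typical_trough(pk_params(), 45, "PM", regimen(20, 24))
#' @export
simulate_typical_trough <- function(pop, age, phenotype, reg) {
  stopifnot(inherits(reg, "pk_regimen"))
  ind <- individual_parameters(pop, list(age = age, phenotype = phenotype))
  steady_state_trough(reg$dose, reg$tau, ind$cl_i, ind$v_i, pop$ka)
}

#' Population trough distribution under a regimen
#'
#' Samples virtual subjects of a given age and phenotype with random
#' effects from `N(0, Omega)`, computes their steady-state troughs, and
#' summarizes the distribution and the fraction in each therapeutic
#' band. Residual (assay) error is excluded by default so the troughs
#' describe biological exposure; set `include_residual = TRUE` to add a
#' proportional residual draw per subject for predictive-interval use.
#'
#' @inheritParams simulate_typical_trough
#' @param n_subjects Number of virtual subjects.
#' @param seed Optional RNG seed.
#' @param include_residual Add proportional residual error.
#' @param lower,upper,alert Window boundaries (ng/ml).
#' @return An object of class `"pk_sim"`: list with `troughs`,
#'   `typical`, `quantiles` (5/25/50/75/95%), `window_fraction`, and
#'   the regimen/covariate metadata.
#' @export
simulate_population_troughs <- function(pop, age, phenotype, reg,
                                        n_subjects = 1000, seed = NULL,
                                        include_residual = FALSE,
                                        lower = 15, upper = 80,
                                        alert = 160) {
  stopifnot(inherits(reg, "pk_regimen"), n_subjects >= 1)
  validate_pk_params(pop)
  with_seed(seed, {
    eta_cl <- rnorm(n_subjects, 0, sqrt(pop$omega2_cl))
    eta_v <- rnorm(n_subjects, 0, sqrt(pop$omega2_v))
    ind <- individual_parameters(pop, list(age = age,
                                           phenotype = phenotype),
                                 eta_cl = eta_cl, eta_v = eta_v)
    tr <- steady_state_trough(reg$dose, reg$tau, ind$cl_i, ind$v_i,
                              pop$ka)
    if (include_residual)
      tr <- pmax(tr * (1 + rnorm(n_subjects, 0, sqrt(pop$sigma2_prop))),
                 0)
    cls <- classify_concentration(tr, lower, upper, alert)
    structure(list(
      troughs = tr,
      typical = simulate_typical_trough(pop, age, phenotype, reg),
      quantiles = quantile(tr, c(0.05, 0.25, 0.5, 0.75, 0.95)),
      window_fraction = as.vector(table(cls)) / n_subjects,
      bands = levels(cls),
      age = age, phenotype = phenotype, regimen = reg,
      n_subjects = n_subjects, include_residual = include_residual),
      class = "pk_sim")
  })
}

#' @export
print.pk_sim <- function(x, ...) {
  cat(sprintf("Simulated troughs: %s, age %g, %s (n = %d)\n",
              x$regimen$label, x$age, x$phenotype, x$n_subjects))
  cat(sprintf("  typical %.1f ng/ml; median %.1f [5-95%%: %.1f-%.1f]\n",
              x$typical, x$quantiles[["50%"]], x$quantiles[["5%"]],
              x$quantiles[["95%"]]))
  cat("  window fractions:",
      paste(sprintf("%s %.1f%%", x$bands, 100 * x$window_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Regimen x age x phenotype trough table
#'
#' Evaluates typical troughs (and, when `n_subjects > 0`, population
#' percentiles and window fractions) over a grid of regimens,
#' representative ages and phenotypes. The default ages 16 / 45 / 65
#' stand for adolescent, adult (cohort median), and elderly patients.
#'
#' @inheritParams simulate_population_troughs
#' @param regimens List of [regimen()] objects; the default covers the
#'   labelled daily doses 5/10/15/20 mg once daily.
#' @param ages Representative ages (years).
#' @param phenotypes CYP2C19 phenotypes.
#' @return A data frame, one row per grid cell, with the typical trough
#'   and (if simulated) percentile bands and window fractions.
#' @export
trough_table <- function(pop = pk_params(),
                         regimens = lapply(c(5, 10, 15, 20), regimen),
                         ages = c(16, 45, 65),
                         phenotypes = c("EM", "IM", "PM"),
                         n_subjects = 0, seed = NULL,
                         lower = 15, upper = 80, alert = 160) {
  rows <- list()
  k <- 0L
  for (reg in regimens) for (age in ages) for (ph in phenotypes) {
    k <- k + 1L
    row <- data.frame(regimen = reg$label, daily_dose = reg$daily_dose,
                      age = age, phenotype = ph,
                      typical_trough = simulate_typical_trough(pop, age,
                                                               ph, reg))
    if (n_subjects > 0) {
      sim <- simulate_population_troughs(
        pop, age, ph, reg, n_subjects = n_subjects,
        seed = if (is.null(seed)) NULL else seed + k,
        lower = lower, upper = upper, alert = alert)
      qs <- sim$quantiles
      row$p5 <- qs[["5%"]]; row$p25 <- qs[["25%"]]
      row$p50 <- qs[["50%"]]; row$p75 <- qs[["75%"]]
      row$p95 <- qs[["95%"]]
      wf <- setNames(sim$window_fraction, sim$bands)
      row$frac_below <- wf[[1]]; row$frac_window <- wf[[2]]
      row$frac_high <- wf[[3]]; row$frac_alert <- wf[[4]]
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
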