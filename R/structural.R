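# One-compartment oral structural model, closed forms.
#
# Doses are in mg, volumes in L, times in hours; the factor 1000 converts
# mg/L to ug/L = ng/ml and is applied exactly once, here.

# relative tolerance below which ka and ke are treated as equal and the
# analytic limit kernel is used
.KA_KE_EPS <- 1e-9

#' Concentration after a single oral dose
#'
#' Closed-form one-compartment model with first-order absorption and
#' elimination:
#' \deqn{C(t) = \frac{1000\,D}{V}\,\frac{k_a}{k_a-k_e}
#'   \left(e^{-k_e t} - e^{-k_a t}\right), \quad k_e = CL/V.}
#' When `ka` and `ke` coincide (relative difference below 1e-9) the
#' analytic limit `1000 D/V * ka * t * exp(-ka t)` is evaluated instead.
#'
#' @param t Time since the dose (h); vectorized, must be `>= 0`.
#' @param dose Dose amount (mg).
#' @param cl Apparent clearance CL/F (L/h).
#' @param v Apparent volume V/F (L).
#' @param ka Absorption rate constant (1/h).
#' @return Concentration in ng/ml, same length as `t`.
#' @examples
#' single_dose_concentration(24, dose = 10, cl = 16.3, v = 815, ka = 0.6)
#' @export
single_dose_concentration <- function(t, dose, cl, v, ka) {
  if (any(t < 0)) stop("t must be >= 0")
  stopifnot(dose >= 0, cl > 0, v > 0, ka > 0)
  ke <- cl / v
  a <- 1000 * dose / v
  if (abs(ka - ke) < .KA_KE_EPS * ka) {
    return(a * ka * t * exp(-ka * t))
  }
  a * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
}

#' Concentration profile under a dosing history
#'
#' Linear superposition of [single_dose_concentration()] over all doses
#' administered at or before each evaluation time.
#'
#' @param dose_times Administration times (h since first dose).
#' @param dose_amts Dose amounts (mg), same length as `dose_times`.
#' @param times Evaluation times (h), sorted ascending.
#' @inheritParams single_dose_concentration
#' @return Concentrations (ng/ml) at `times`. An empty dosing history
#'   yields an all-zero profile.
#' @export
concentration_profile <- function(dose_times, dose_amts, times, cl, v, ka) {
  if (length(dose_times) != length(dose_amts))
    stop("dose_times and dose_amts must have equal length")
  if (is.unsorted(times)) stop("times must be sorted ascending")
  if (length(dose_times) == 0) return(numeric(length(times)) * 0 + 0)
  if (any(dose_amts <= 0)) stop("dose amounts must be > 0")
  if (any(dose_times < 0)) stop("dose times must be >= 0")
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    dt <- times[i] - dose_times
    keep <- dt >= 0
    if (any(keep)) {
      out[i] <- sum(single_dose_concentration(dt[keep], dose_amts[keep],
                                              cl, v, ka))
    }
  }
  out
}

#' Steady-state trough concentration
#'
#' Closed-form pre-dose (trough) concentration for repeated oral dosing
#' of `dose` mg every `tau` hours at steady state:
#' \deqn{C_{ss,min} = \frac{1000\,D}{V}\,\frac{k_a}{k_a-k_e}
#'   \left[\frac{e^{-k_e\tau}}{1-e^{-k_e\tau}} -
#'         \frac{e^{-k_a\tau}}{1-e^{-k_a\tau}}\right].}
#' Strictly increasing in dose and strictly decreasing in clearance.
#'
#' @param dose Dose per administration (mg).
#' @param tau Dosing interval (h), `> 0`.
#' @inheritParams single_dose_concentration
#' @return Steady-state trough concentration (ng/ml).
#' @examples
#' # adult PM on 20 mg q24h at the reference estimates
#' steady_state_trough(20, 24, cl = 16.3 * 0.479, v = 815, ka = 0.6)
#' @export
steady_state_trough <- function(dose, tau, cl, v, ka) {
  if (any(tau <= 0)) stop("tau must be > 0")
  stopifnot(all(dose >= 0), all(cl > 0), all(v > 0), all(ka > 0))
  ke <- cl / v
  a <- 1000 * dose / v
  ee <- exp(-ke * tau)
  ea <- exp(-ka * tau)
  deg <- abs(ka - ke) < .KA_KE_EPS * ka
  if (any(deg)) {
    # limit ke -> ka of the accumulation form: a * ka * tau * x/(1-x)^2
    lim <- a * ka * tau * ea / (1 - ea)^2
    reg <- a * ka / (ka - ke) * (ee / (1 - ee) - ea / (1 - ea))
    return(ifelse(deg, lim, reg))
  }
  a * ka / (ka - ke) * (ee / (1 - ee) - ea / (1 - ea))
}
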