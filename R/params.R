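#' Population pharmacokinetic parameters
#'
#' Container for the fixed effects, covariate coefficients, and variance
#' components of the one-compartment escitalopram population model. All
#' disposition parameters are apparent (CL/F, V/F): bioavailability is not
#' a separate parameter. The defaults are the final-model estimates for
#' Chinese psychiatric inpatients: typical CL/F 16.3 L/h for an extensive
#' metabolizer aged 45, V/F 815 L, absorption rate constant fixed at
#' 0.6 h^-1, an age slope of 0.0077 per year on CL/F (clearance declines
#' with age), CYP2C19 multipliers 0.847 (intermediate metabolizer, IM) and
#' 0.479 (poor metabolizer, PM) with the extensive metabolizer (EM) as
#' reference, log-normal inter-individual variances 0.0877 (CL/F) and
#' 0.235 (V/F), and a proportional residual variance of 0.0287 with the
#' additive component fixed at 0.
#'
#' @param tvcl Typical apparent clearance CL/F (L/h) at the reference
#'   covariates (EM phenotype, age equal to `age_center`).
#' @param tvv Typical apparent volume of distribution V/F (L).
#' @param ka First-order absorption rate constant (1/h); conventionally
#'   fixed because trough-dominated sampling carries almost no absorption
#'   information.
#' @param theta_age Age coefficient on CL/F per year. With
#'   `age_decreasing = TRUE` (default) the covariate multiplier is
#'   `1 - theta_age * (age - age_center)`, so a positive value means
#'   clearance falls with age.
#' @param theta_im,theta_pm CL/F multipliers for IM and PM phenotypes
#'   (EM multiplier is identically 1).
#' @param omega2_cl,omega2_v Variances of the log-normal inter-individual
#'   random effects on CL/F and V/F.
#' @param sigma2_prop Proportional residual-error variance.
#' @param sigma2_add Additive residual-error variance (ng/ml)^2;
#'   fixed at 0 in the reference model.
#' @param age_center Centering age in years for the age covariate.
#' @param age_decreasing Logical; if `TRUE` the age multiplier is
#'   `1 - theta_age * (age - age_center)` (clearance decreasing in age),
#'   if `FALSE` the textbook `1 + theta * (age - age_center)` form is used.
#' @param cov_floor Positive floor applied to any linear covariate
#'   multiplier; extreme covariate values are clamped here (with a
#'   warning) rather than producing non-positive parameters.
#'
#' @return An object of class `"pk_params"` (a named list).
#' @examples
#' p <- pk_params()
#' individual_parameters(p, list(age = 45, phenotype = "PM"))
#' @export
pk_params <- function(tvcl = 16.3, tvv = 815, ka = 0.6,
                      theta_age = 0.0077, theta_im = 0.847,
                      theta_pm = 0.479,
                      omega2_cl = 0.0877, omega2_v = 0.235,
                      sigma2_prop = 0.0287, sigma2_add = 0,
                      age_center = 45, age_decreasing = TRUE,
                      cov_floor = 0.05) {
  p <- structure(list(tvcl = tvcl, tvv = tvv, ka = ka,
                      theta_age = theta_age, theta_im = theta_im,
                      theta_pm = theta_pm,
                      omega2_cl = omega2_cl, omega2_v = omega2_v,
                      sigma2_prop = sigma2_prop, sigma2_add = sigma2_add,
                      age_center = age_center,
                      age_decreasing = isTRUE(age_decreasing),
                      cov_floor = cov_floor),
                 class = "pk_params")
  validate_pk_params(p)
  p
}

validate_pk_params <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("tvcl", "tvv", "ka", "theta_age", "theta_im", "theta_pm",
              "omega2_cl", "omega2_v", "sigma2_prop", "sigma2_add",
              "age_center", "cov_floor")) {
    if (!num1(p[[f]])) stop("pk_params field '", f, "' must be a finite number")
  }
  if (p$tvcl <= 0) stop("tvcl must be > 0")
  if (p$tvv <= 0) stop("tvv must be > 0")
  if (p$ka <= 0) stop("ka must be > 0")
  if (p$theta_im <= 0) stop("theta_im must be > 0")
  if (p$theta_pm <= 0) stop("theta_pm must be > 0")
  if (p$omega2_cl < 0 || p$omega2_v < 0) stop("omega2 variances must be >= 0")
  if (p$sigma2_prop < 0) stop("sigma2_prop must be >= 0")
  if (p$sigma2_add < 0) stop("sigma2_add must be >= 0")
  if (p$cov_floor <= 0) stop("cov_floor must be > 0")
  invisible(p)
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Population PK parameters (one-compartment oral, apparent)\n")
  cat(sprintf("  CL/F %.4g L/h   V/F %.4g L   ka %.3g /h\n",
              x$tvcl, x$tvv, x$ka))
  cat(sprintf("  age slope %.4g /y (%s, centred at %g y)\n",
              x$theta_age,
              if (x$age_decreasing) "decreasing" else "increasing",
              x$age_center))
  cat(sprintf("  CYP2C19 multipliers: EM 1, IM %.3g, PM %.3g\n",
              x$theta_im, x$theta_pm))
  cat(sprintf("  omega2: CL %.4g, V %.4g;  sigma2: prop %.4g, add %.4g\n",
              x$omega2_cl, x$omega2_v, x$sigma2_prop, x$sigma2_add))
  invisible(x)
}

#' CYP2C19 phenotype from diplotype
#'
#' Maps CYP2C19 diplotypes over the alleles *1 (normal function), *2 and
#' *3 (no function) to predicted metabolizer phenotypes: two functional
#' alleles give an extensive metabolizer (EM), one a reduced/intermediate
#' metabolizer (IM), none a poor metabolizer (PM).
#'
#' @param genotype Character vector of diplotypes such as `"*1/*2"`.
#' @return Character vector with values `"EM"`, `"IM"`, `"PM"`.
#' @examples
#' cyp2c19_phenotype(c("*1/*1", "*1/*3", "*2/*2"))
#' @export
cyp2c19_phenotype <- function(genotype) {
  parts <- strsplit(as.character(genotype), "/", fixed = TRUE)
  vapply(parts, function(al) {
    if (length(al) != 2 || !all(al %in% c("*1", "*2", "*3")))
      stop("unknown CYP2C19 diplotype: ", paste(al, collapse = "/"))
    n_null <- sum(al != "*1")
    c("EM", "IM", "PM")[n_null + 1L]
  }, character(1))
}

# Linear covariate multiplier with positivity floor.
# value = 1 + sign * theta * (x - center), clamped below at `floor`.
linear_cov_effect <- function(x, theta, center, sign = 1, floor = 0.05,
                              warn = TRUE) {
  e <- 1 + sign * theta * (x - center)
  clamped <- e < floor
  if (any(clamped) && warn) {
    warning(sprintf(
      "covariate multiplier clamped at floor %.3g for %d value(s)",
      floor, sum(clamped)), call. = FALSE)
  }
  e[clamped] <- floor
  structure(e, clamped = sum(clamped))
}

phenotype_multiplier <- function(phenotype, theta_im, theta_pm) {
  m <- c(EM = 1, IM = theta_im, PM = theta_pm)[as.character(phenotype)]
  if (anyNA(m)) {
    bad <- unique(as.character(phenotype)[is.na(m)])
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "),
         " (expected EM, IM or PM)")
  }
  unname(m)
}

#' Individual parameters from covariates and random effects
#'
#' Applies the covariate and random-effect model to the population
#' parameters: `cl_i = tvcl * g_pheno * g_age(age) * exp(eta_cl)` with
#' `g_pheno` in \{1, theta_im, theta_pm\} and
#' `g_age = 1 - theta_age * (age - age_center)` (in the default
#' decreasing-with-age convention), and `v_i = tvv * exp(eta_v)`. With
#' both etas at 0 the result is the covariate-adjusted typical subject.
#'
#' @param pop A [pk_params()] object.
#' @param subject A list or one-row data frame with at least `age`
#'   (years) and `phenotype` (`"EM"`, `"IM"` or `"PM"`); alternatively a
#'   `genotype` diplotype from which the phenotype is derived.
#' @param eta_cl,eta_v Subject-level random effects (default 0).
#' @return A list of class `"pk_indiv"` with `cl_i` (L/h), `v_i` (L),
#'   the etas, and `clamped` (number of clamped covariate multipliers).
#' @examples
#' individual_parameters(pk_params(), list(age = 45, phenotype = "EM"))
#' @export
individual_parameters <- function(pop, subject, eta_cl = 0, eta_v = 0) {
  validate_pk_params(pop)
  subject <- as.list(subject)
  names(subject) <- tolower(names(subject))
  age <- subject$age
  if (is.null(age) || !is.finite(age) || age <= 0)
    stop("subject must have a positive age")
  phen <- subject$phenotype
  if (is.null(phen)) {
    if (is.null(subject$genotype)) stop("subject needs phenotype or genotype")
    phen <- cyp2c19_phenotype(subject$genotype)
  }
  g_ph <- phenotype_multiplier(phen, pop$theta_im, pop$theta_pm)
  g_age <- linear_cov_effect(age, pop$theta_age, pop$age_center,
                             sign = if (pop$age_decreasing) -1 else 1,
                             floor = pop$cov_floor)
  cl_i <- pop$tvcl * g_ph * as.numeric(g_age) * exp(eta_cl)
  v_i <- pop$tvv * exp(eta_v)
  structure(list(cl_i = cl_i, v_i = v_i,
                 eta_cl = eta_cl, eta_v = eta_v,
                 clamped = attr(g_age, "clamped")),
            class = "pk_indiv")
}

#' @export
print.pk_indiv <- function(x, ...) {
  cat(sprintf("Individual PK parameters: CL/F %.4g L/h, V/F %.4g L (eta_cl %.3g, eta_v %.3g)\n",
              x$cl_i, x$v_i, x$eta_cl, x$eta_v))
  invisible(x)
}
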