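# Covariate model specification: which covariates act on which
# disposition parameter, and how fit parameters are packed/unpacked.

#' Covariate model terms
#'
#' Constructors for the covariate terms a [pk_model_spec()] is built
#' from. `cov_continuous()` uses the linear-calibrator form
#' `1 + theta * (x - center)` (or `1 - theta * (x - center)` when
#' `decreasing = TRUE`, the convention used for age on clearance);
#' `cov_categorical()` uses `1 + theta * x` for a 0/1 covariate;
#' `cov_phenotype()` is the three-level CYP2C19 metabolizer term, which
#' expands to the two free multipliers `theta_im` and `theta_pm` with EM
#' as reference (2 degrees of freedom).
#'
#' @param name Covariate column name in the dataset (case-insensitive,
#'   e.g. `"AGE"`, `"WT"`, `"SEX"`).
#' @param parameter Disposition parameter the term acts on: `"cl"` or
#'   `"v"` (phenotype acts on `"cl"` only).
#' @param center Centering value for a continuous covariate; `NULL`
#'   means the dataset median, recomputed per dataset.
#' @param decreasing Sign convention for a continuous term (see above).
#' @return A term object of class `"pk_cov_term"`.
#' @export
cov_continuous <- function(name, parameter = "cl", center = NULL,
                           decreasing = FALSE) {
  new_cov_term(kind = "continuous", name = toupper(name),
               parameter = match.arg(parameter, c("cl", "v")),
               center = center, decreasing = isTRUE(decreasing))
}

#' @rdname cov_continuous
#' @export
cov_categorical <- function(name, parameter = "cl") {
  new_cov_term(kind = "categorical", name = toupper(name),
               parameter = match.arg(parameter, c("cl", "v")))
}

#' @rdname cov_continuous
#' @export
cov_phenotype <- function(parameter = "cl") {
  if (!identical(parameter, "cl"))
    stop("the CYP2C19 phenotype term is supported on clearance only")
  new_cov_term(kind = "phenotype", name = "PHENOTYPE", parameter = "cl")
}

new_cov_term <- function(kind, name, parameter, center = NULL,
                         decreasing = FALSE) {
  structure(list(kind = kind, name = name, parameter = parameter,
                 center = center, decreasing = decreasing),
            class = "pk_cov_term")
}

term_label <- function(term) {
  if (term$kind == "phenotype") "cl:PHENOTYPE"
  else paste0(term$parameter, ":", term$name)
}

term_par_names <- function(term) {
  if (term$kind == "phenotype") c("theta_im", "theta_pm")
  else paste0("theta_", term$parameter, "_", tolower(term$name))
}

term_df <- function(term) if (term$kind == "phenotype") 2L else 1L

#' @export
print.pk_cov_term <- function(x, ...) {
  cat(sprintf("covariate term %s (%s%s)\n", term_label(x), x$kind,
              if (x$kind == "continuous" && x$decreasing) ", decreasing"
              else ""))
  invisible(x)
}

#' Model specification
#'
#' Declares the covariate structure of the population model. The default
#' is the reference final model: CYP2C19 phenotype and age (decreasing,
#' centred at 45 years) on CL/F, no covariates on V/F.
#'
#' @param terms List of [cov_continuous()] / [cov_categorical()] /
#'   [cov_phenotype()] terms; may be empty for the base model.
#' @return An object of class `"pk_model_spec"`.
#' @examples
#' pk_model_spec()                 # final covariate model
#' pk_model_spec(list())           # base model, no covariates
#' @export
pk_model_spec <- function(terms = list(cov_phenotype(),
                                       cov_continuous("AGE", center = 45,
                                                      decreasing = TRUE))) {
  stopifnot(is.list(terms))
  for (tm in terms) stopifnot(inherits(tm, "pk_cov_term"))
  labs <- vapply(terms, term_label, character(1))
  if (anyDuplicated(labs)) stop("duplicate covariate terms: ",
                                paste(labs[duplicated(labs)], collapse = ", "))
  structure(list(terms = terms), class = "pk_model_spec")
}

#' @export
print.pk_model_spec <- function(x, ...) {
  if (length(x$terms) == 0) {
    cat("PK model specification: base model (no covariates)\n")
  } else {
    cat("PK model specification with covariate terms:\n")
    for (tm in x$terms) cat("  -", term_label(tm), "\n")
  }
  invisible(x)
}

spec_add_term <- function(spec, term) {
  pk_model_spec(c(spec$terms, list(term)))
}

spec_drop_term <- function(spec, label) {
  keep <- vapply(spec$terms, function(tm) term_label(tm) != label, logical(1))
  pk_model_spec(spec$terms[keep])
}

spec_labels <- function(spec) {
  vapply(spec$terms, term_label, character(1))
}

# --- parameter packing ------------------------------------------------------

# Full natural-scale parameter table for a spec. `start` supplies initial
# values for the canonical names; unknown covariate thetas start at 0.
par_table <- function(spec, start) {
  nm <- c("tvcl", "tvv")
  init <- c(start$tvcl, start$tvv)
  trans <- c("log", "log")
  for (tm in spec$terms) {
    pn <- term_par_names(tm)
    if (tm$kind == "phenotype") {
      init <- c(init, start$theta_im, start$theta_pm)
      trans <- c(trans, "log", "log")
    } else if (tm$kind == "continuous" && tm$name == "AGE" &&
               tm$parameter == "cl") {
      init <- c(init, start$theta_age)
      trans <- c(trans, "id")
    } else {
      init <- c(init, 0)
      trans <- c(trans, "id")
    }
    nm <- c(nm, pn)
  }
  nm <- c(nm, "omega2_cl", "omega2_v", "sigma2_prop")
  init <- c(init, start$omega2_cl, start$omega2_v, start$sigma2_prop)
  trans <- c(trans, "log", "log", "log")
  data.frame(name = nm, init = init, trans = trans,
             stringsAsFactors = FALSE)
}

trans_par <- function(x, trans) {
  out <- x
  L <- trans == "log"
  out[L] <- log(x[L])
  out
}
untrans_par <- function(x, trans) {
  out <- x
  L <- trans == "log"
  out[L] <- exp(x[L])
  out
}

# Resolve term centering values against a dataset's subject table.
resolve_centers <- function(spec, subjects) {
  lapply(spec$terms, function(tm) {
    if (tm$kind == "continuous" && is.null(tm$center)) {
      x <- subject_covariate(subjects, tm$name)
      tm$center <- median(x, na.rm = TRUE)
    }
    tm
  })
}

subject_covariate <- function(subjects, name) {
  idx <- match(toupper(name), toupper(names(subjects)))
  if (is.na(idx)) stop("covariate '", name, "' not found in the dataset")
  x <- subjects[[idx]]
  if (toupper(name) == "PHENOTYPE") return(as.character(x))
  if (!is.numeric(x)) stop("covariate '", name, "' must be numeric")
  x
}

# Per-subject baseline (eta = 0) parameters for a natural parameter vector.
# Returns list(cl_base, v_base, clamped).
baseline_parameters <- function(pars, terms, subjects, cov_floor = 0.05) {
  cl <- rep(pars[["tvcl"]], nrow(subjects))
  v <- rep(pars[["tvv"]], nrow(subjects))
  clamped <- 0L
  for (tm in terms) {
    if (tm$kind == "phenotype") {
      mult <- phenotype_multiplier(subjects$PHENOTYPE,
                                   pars[["theta_im"]], pars[["theta_pm"]])
    } else {
      x <- subject_covariate(subjects, tm$name)
      th <- pars[[term_par_names(tm)]]
      if (tm$kind == "continuous") {
        e <- linear_cov_effect(x, th, tm$center,
                               sign = if (tm$decreasing) -1 else 1,
                               floor = cov_floor, warn = FALSE)
      } else {
        e <- linear_cov_effect(x, th, 0, sign = 1,
                               floor = cov_floor, warn = FALSE)
      }
      clamped <- clamped + attr(e, "clamped")
      mult <- as.numeric(e)
    }
    if (tm$parameter == "cl") cl <- cl * mult else v <- v * mult
  }
  list(cl_base = cl, v_base = v, clamped = clamped)
}

# Map a fitted natural parameter vector for the canonical spec back to a
# pk_params object (used by simulate/predict and reporting).
coef_to_params <- function(pars, terms, template = pk_params()) {
  age_term <- NULL
  for (tm in terms)
    if (tm$kind == "continuous" && tm$name == "AGE" && tm$parameter == "cl")
      age_term <- tm
  pk_params(
    tvcl = pars[["tvcl"]], tvv = pars[["tvv"]], ka = template$ka,
    theta_age = if (!is.null(age_term)) {
      th <- pars[["theta_cl_age"]]
      if (is.na(th)) th <- pars[["theta_age"]] # not reached; safety
      th
    } else 0,
    theta_im = if ("theta_im" %in% names(pars)) pars[["theta_im"]] else 1,
    theta_pm = if ("theta_pm" %in% names(pars)) pars[["theta_pm"]] else 1,
    omega2_cl = pars[["omega2_cl"]], omega2_v = pars[["omega2_v"]],
    sigma2_prop = pars[["sigma2_prop"]], sigma2_add = template$sigma2_add,
    age_center = if (!is.null(age_term)) age_term$center else
      template$age_center,
    age_decreasing = if (!is.null(age_term)) age_term$decreasing else
      template$age_decreasing,
    cov_floor = template$cov_floor)
}
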