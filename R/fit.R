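# Population fit: outer parameter search over the FOCE-I objective.

#' Control settings for [pkfit()]
#'
#' @param interaction Use the FOCE-I eta-epsilon interaction residual
#'   variance (default); `FALSE` gives plain FOCE.
#' @param se Run the covariance step (finite-difference Hessian of the
#'   objective) after estimation.
#' @param inner_gtol Gradient tolerance of the inner (empirical Bayes)
#'   Newton search.
#' @param inner_maxit Maximum inner Newton iterations.
#' @param rel_tol Relative convergence tolerance of the outer
#'   quasi-Newton search ([stats::nlminb()]); the default stops when the
#'   objective changes by less than about 1e-4 in absolute terms at
#'   typical OFV magnitudes.
#' @param eval_max,iter_max Outer search budget.
#' @param trace Print outer iterations (passed to `nlminb`).
#' @return A list of class `"pkfit_control"`.
#' @export
pkfit_control <- function(interaction = TRUE, se = TRUE,
                          inner_gtol = 1e-8, inner_maxit = 100L,
                          rel_tol = 1e-8, eval_max = 2000L,
                          iter_max = 500L, trace = 0) {
  structure(list(interaction = interaction, se = se,
                 inner_gtol = inner_gtol, inner_maxit = inner_maxit,
                 rel_tol = rel_tol, eval_max = eval_max,
                 iter_max = iter_max, trace = trace),
            class = "pkfit_control")
}

#' Fit the population PK model by FOCE-I
#'
#' Estimates the population parameters of the one-compartment
#' escitalopram model by minimizing the FOCE-I approximate -2 log
#' marginal likelihood. Positive parameters (typical values, phenotype
#' multipliers, variances) are searched on the log scale; linear
#' covariate coefficients on the natural scale. The absorption rate
#' constant and the additive residual variance are fixed by default, the
#' usual choice for trough-dominated designs.
#'
#' @param data A [pk_dataset()]. BLQ observations are excluded.
#' @param model A [pk_model_spec()] covariate structure; the default is
#'   the final reference model (CYP2C19 phenotype and age on CL/F).
#' @param start A [pk_params()] object giving initial values (and the
#'   values of fixed parameters).
#' @param fix Character vector of parameter names to hold at their
#'   starting values, in addition to `ka` and `sigma2_add` which are
#'   always fixed (at `start$ka` and `start$sigma2_add`).
#' @param init Optional named numeric vector overriding individual
#'   starting values from `start` (e.g. warm starts for covariate-search
#'   refits).
#' @param control A [pkfit_control()] list.
#' @return An object of class `"pkfit"` with methods `print`, `summary`,
#'   `coef`, `logLik`, `vcov`, `predict`, `fitted`, `residuals`,
#'   `simulate`, `plot`; see also [gof_table()], [npde()],
#'   [bootstrap_pkfit()].
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_subjects = 40), seed = 1)
#' ds <- simulate_pkdata(cohort, truth = pk_params(), seed = 2)
#' fit <- pkfit(ds, control = pkfit_control(se = FALSE))
#' coef(fit)
#' }
#' @export
pkfit <- function(data, model = pk_model_spec(), start = pk_params(),
                  fix = character(), init = NULL,
                  control = pkfit_control()) {
  stopifnot(inherits(data, "pk_dataset"), inherits(model, "pk_model_spec"))
  validate_pk_params(start)
  terms <- resolve_centers(model, data$subjects)
  ptab <- par_table(model, start)
  if (!is.null(init)) {
    hit <- match(names(init), ptab$name)
    if (anyNA(hit)) stop("unknown parameter(s) in init: ",
                         paste(names(init)[is.na(hit)], collapse = ", "))
    ptab$init[hit] <- init
  }
  free <- !(ptab$name %in% fix)
  if (!any(free)) stop("no free parameters")
  design <- build_design(data)
  if (any(tabulate(design$obs_sub, design$n_sub) == 0))
    stop("subject(s) without quantifiable observations: ",
         paste(data$subjects$ID[tabulate(design$obs_sub,
                                         design$n_sub) == 0],
               collapse = ", "))
  nat0 <- setNames(ptab$init, ptab$name)
  tp_full <- trans_par(ptab$init, ptab$trans)
  warm <- new.env(parent = emptyenv())
  warm$eta <- NULL
  warm$n_eval <- 0L
  warm$clamped <- 0L

  unpack <- function(tp_free) {
    tp <- tp_full
    tp[free] <- tp_free
    setNames(untrans_par(tp, ptab$trans), ptab$name)
  }
  objective <- function(tp_free, eta_start, update_warm = FALSE) {
    nat <- unpack(tp_free)
    if (any(!is.finite(nat))) return(1e10)
    base <- baseline_parameters(nat, terms, data$subjects,
                                cov_floor = start$cov_floor)
    warm$clamped <- base$clamped
    Omega <- diag(c(nat[["omega2_cl"]], nat[["omega2_v"]]))
    if (any(diag(Omega) <= 0)) return(1e10)
    # extreme trial parameters can overflow the model kernel; any
    # non-finite result is mapped to a large objective below, so the
    # arithmetic warnings carry no information
    res <- tryCatch(
      suppressWarnings(
        pk_marginal_ofv(design, base$cl_base, base$v_base, start$ka,
                        Omega, nat[["sigma2_prop"]], start$sigma2_add,
                        interaction = control$interaction,
                        eta_start = eta_start,
                        gtol = control$inner_gtol,
                        maxit = control$inner_maxit)),
      error = function(e) NULL)
    warm$n_eval <- warm$n_eval + 1L
    if (is.null(res) || !is.finite(res$ofv)) return(1e10)
    if (update_warm) warm$eta <- res$inner$eta
    res$ofv
  }
  outer_obj <- function(tp_free)
    objective(tp_free, eta_start = warm$eta, update_warm = TRUE)

  opt <- nlminb(tp_full[free], outer_obj,
                control = list(rel.tol = control$rel_tol,
                               eval.max = control$eval_max,
                               iter.max = control$iter_max,
                               trace = control$trace))
  # a fresh PORT restart from the incumbent often clears spurious
  # "false convergence" stops on flat likelihood regions
  for (round in 1:2) {
    if (opt$convergence == 0) break
    opt2 <- nlminb(opt$par, outer_obj,
                   control = list(rel.tol = control$rel_tol,
                                  eval.max = control$eval_max,
                                  iter.max = control$iter_max,
                                  trace = control$trace))
    if (opt2$objective <= opt$objective) opt <- opt2 else break
  }
  est <- unpack(opt$par)

  # final state, cold-started for reproducibility
  base <- baseline_parameters(est, terms, data$subjects,
                              cov_floor = start$cov_floor)
  Omega <- diag(c(est[["omega2_cl"]], est[["omega2_v"]]))
  final <- pk_marginal_ofv(design, base$cl_base, base$v_base, start$ka,
                           Omega, est[["sigma2_prop"]], start$sigma2_add,
                           interaction = control$interaction,
                           eta_start = NULL,
                           gtol = control$inner_gtol,
                           maxit = control$inner_maxit)

  coefs <- c(est, ka = start$ka, sigma2_add = start$sigma2_add)
  fixed <- c(ptab$name[!free], "ka", "sigma2_add")
  se <- rse <- setNames(rep(NA_real_, length(coefs)), names(coefs))
  vc <- NULL
  cov_ok <- FALSE
  if (isTRUE(control$se)) {
    # every Hessian evaluation starts the inner search from the same
    # converged eta: deterministic, fast, and free of warm-start
    # path-dependence that would break the finite-difference symmetry
    H <- tryCatch(fd_hessian(function(p)
      objective(p, eta_start = final$inner$eta), opt$par, eps = 1e-3),
      error = function(e) NULL)
    if (!is.null(H) && all(is.finite(H))) {
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      vct <- if (all(ev > 1e-10 * max(abs(ev))))
        tryCatch(2 * solve(H), error = function(e) NULL) else NULL
      if (!is.null(vct)) {
        D <- diag(ifelse(ptab$trans[free] == "log", est[free], 1),
                  nrow = sum(free))
        vc <- D %*% vct %*% D
        dimnames(vc) <- list(ptab$name[free], ptab$name[free])
        se[ptab$name[free]] <- sqrt(diag(vc))
        rse <- 100 * se / abs(coefs)
        cov_ok <- TRUE
      }
    }
    if (!cov_ok)
      message("covariance step failed (objective Hessian not positive ",
              "definite); standard errors not reported")
  }

  structure(list(
    coefficients = coefs,
    se = se, rse = rse, vcov = vc, cov_ok = cov_ok,
    ofv = final$ofv,
    per_subject_ofv = final$per_subject,
    eta = data.frame(ID = data$subjects$ID,
                     eta_cl = final$inner$eta[, 1],
                     eta_v = final$inner$eta[, 2]),
    inner = final$inner,
    converged = opt$convergence == 0 && all(final$inner$converged),
    message = opt$message,
    n_function_evals = warm$n_eval,
    n_clamped = warm$clamped,
    data = data, model = model, terms = terms, design = design,
    start = start, fix = fixed, free = ptab$name[free],
    par_table = ptab, control = control,
    n_sub = design$n_sub, n_obs = design$n_obs),
    class = "pkfit")
}

# baseline parameters at the fitted estimates
fit_baseline <- function(object, subjects = object$data$subjects) {
  baseline_parameters(object$coefficients, object$terms, subjects,
                      cov_floor = object$start$cov_floor)
}

#' @export
print.pkfit <- function(x, digits = 4, ...) {
  cat("Population PK model fit (FOCE",
      if (x$control$interaction) "-I" else "", ")\n", sep = "")
  cat(sprintf("  %d subjects, %d observations; OFV = %.3f%s\n",
              x$n_sub, x$n_obs, x$ofv,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- x$coefficients[setdiff(names(x$coefficients), x$fix)]
  print(signif(est, digits))
  cat("  fixed:", paste(sprintf("%s = %.3g", x$fix,
                                x$coefficients[x$fix]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.pkfit <- function(object, ...) {
  cf <- object$coefficients
  tab <- data.frame(estimate = cf,
                    se = object$se[names(cf)],
                    rse_pct = object$rse[names(cf)],
                    fixed = names(cf) %in% object$fix)
  eta_sd <- apply(as.matrix(object$eta[, c("eta_cl", "eta_v")]), 2, sd)
  shr <- 1 - eta_sd / sqrt(c(cf[["omega2_cl"]], cf[["omega2_v"]]))
  out <- list(table = tab, ofv = object$ofv,
              n_sub = object$n_sub, n_obs = object$n_obs,
              n_blq = object$data$n_blq,
              converged = object$converged,
              shrinkage = setNames(100 * shr, c("eta_cl", "eta_v")),
              iiv_cv = setNames(
                100 * sqrt(exp(c(cf[["omega2_cl"]], cf[["omega2_v"]])) - 1),
                c("cl", "v")))
  class(out) <- "summary.pkfit"
  out
}

#' @export
print.summary.pkfit <- function(x, digits = 4, ...) {
  cat(sprintf("FOCE-I fit: %d subjects, %d observations (%d BLQ excluded)\n",
              x$n_sub, x$n_obs, x$n_blq))
  cat(sprintf("OFV (incl. 2*pi constant): %.3f   converged: %s\n",
              x$ofv, x$converged))
  tb <- x$table
  tb$estimate <- signif(tb$estimate, digits)
  tb$se <- signif(tb$se, 3)
  tb$rse_pct <- round(tb$rse_pct, 1)
  print(tb)
  cat(sprintf("IIV CV%%: CL %.1f, V %.1f;  eta shrinkage%%: CL %.1f, V %.1f\n",
              x$iiv_cv[["cl"]], x$iiv_cv[["v"]],
              x$shrinkage[["eta_cl"]], x$shrinkage[["eta_v"]]))
  invisible(x)
}

#' @export
coef.pkfit <- function(object, ...) object$coefficients

#' @export
logLik.pkfit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$free),
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.pkfit <- function(object, ...) object$vcov

#' @export
nobs.pkfit <- function(object, ...) object$n_obs

#' Model predictions
#'
#' `type = "pred"` gives population predictions (random effects at 0);
#' `type = "ipred"` gives individual predictions at the empirical-Bayes
#' modes. With `newdata`, empirical-Bayes modes are re-estimated for the
#' new subjects at the fitted population parameters.
#'
#' @param object A fitted [pkfit()] model.
#' @param newdata Optional [pk_dataset()]; default is the training data.
#' @param type `"ipred"` (default) or `"pred"`.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (ng/ml), one per
#'   quantifiable observation record, in dataset order.
#' @export
predict.pkfit <- function(object, newdata = NULL,
                          type = c("ipred", "pred"), ...) {
  type <- match.arg(type)
  data <- newdata %||% object$data
  design <- if (is.null(newdata)) object$design else build_design(data)
  base <- fit_baseline(object, data$subjects)
  mfun <- pk_eta_model(design, base$cl_base, base$v_base,
                       object$coefficients[["ka"]])
  if (type == "pred") {
    eta <- matrix(0, design$n_sub, 2)
  } else if (is.null(newdata)) {
    eta <- as.matrix(object$eta[, c("eta_cl", "eta_v")])
  } else {
    cf <- object$coefficients
    Omega <- diag(c(cf[["omega2_cl"]], cf[["omega2_v"]]))
    inner <- pk_inner(design, base$cl_base, base$v_base, cf[["ka"]],
                      Omega, cf[["sigma2_prop"]], cf[["sigma2_add"]],
                      interaction = object$control$interaction)
    eta <- inner$eta
  }
  mfun(eta, deriv = FALSE)$f
}

#' @export
fitted.pkfit <- function(object, ...) predict(object, type = "ipred")

#' Residuals of a population PK fit
#'
#' `"cwres"` (default) returns conditional weighted residuals from the
#' first-order expansion about the empirical-Bayes modes (see
#' [cwres()]); `"iwres"` returns individual weighted residuals
#' `(y - ipred) / sd(ipred)`; `"response"` returns raw `y - ipred`.
#'
#' @param object A fitted [pkfit()] model.
#' @param type Residual type.
#' @param ... Unused.
#' @export
residuals.pkfit <- function(object,
                            type = c("cwres", "iwres", "response"), ...) {
  type <- match.arg(type)
  if (type == "cwres") return(cwres(object))
  ip <- object$inner$f
  y <- object$design$y
  if (type == "response") return(y - ip)
  cf <- object$coefficients
  (y - ip) / sqrt(cf[["sigma2_prop"]] * ip^2 + cf[["sigma2_add"]])
}

#' Simulate observations from a fitted model
#'
#' Draws new random effects and residual errors from the fitted
#' variance components and returns replicate observation vectors under
#' the original design (same subjects, doses, sampling times; BLQ rows
#' excluded). Used by [npde()].
#'
#' @param object A fitted [pkfit()] model.
#' @param nsim Number of replicate datasets.
#' @param seed Optional RNG seed (caller's RNG state is preserved).
#' @param ... Unused.
#' @return A `n_obs x nsim` matrix of simulated concentrations.
#' @export
simulate.pkfit <- function(object, nsim = 1, seed = NULL, ...) {
  cf <- object$coefficients
  design <- object$design
  base <- fit_baseline(object)
  mfun <- pk_eta_model(design, base$cl_base, base$v_base, cf[["ka"]])
  with_seed(seed, {
    out <- matrix(NA_real_, design$n_obs, nsim)
    for (s in seq_len(nsim)) {
      eta <- cbind(rnorm(design$n_sub, 0, sqrt(cf[["omega2_cl"]])),
                   rnorm(design$n_sub, 0, sqrt(cf[["omega2_v"]])))
      f <- mfun(eta, deriv = FALSE)$f
      out[, s] <- f * (1 + rnorm(design$n_obs, 0,
                                 sqrt(cf[["sigma2_prop"]]))) +
        rnorm(design$n_obs, 0, sqrt(cf[["sigma2_add"]]))
    }
    out
  })
}

#' Goodness-of-fit plots
#'
#' Four standard panels: observed vs population predictions, observed vs
#' individual predictions, CWRES vs population predictions, CWRES vs
#' time after last dose.
#'
#' @param x A fitted [pkfit()] model.
#' @param which Subset of panels `1:4`.
#' @param ... Unused.
#' @export
plot.pkfit <- function(x, which = 1:4, ...) {
  g <- gof_table(x)
  old <- par(mfrow = c(ceiling(length(which) / 2),
                       min(2, length(which))),
             mar = c(4, 4, 2, 1))
  on.exit(par(old))
  if (1 %in% which) {
    plot(g$PRED, g$DV, xlab = "Population prediction (ng/ml)",
         ylab = "Observed (ng/ml)", main = "DV vs PRED")
    abline(0, 1, col = 2)
  }
  if (2 %in% which) {
    plot(g$IPRED, g$DV, xlab = "Individual prediction (ng/ml)",
         ylab = "Observed (ng/ml)", main = "DV vs IPRED")
    abline(0, 1, col = 2)
  }
  if (3 %in% which) {
    plot(g$PRED, g$CWRES, xlab = "Population prediction (ng/ml)",
         ylab = "CWRES", main = "CWRES vs PRED")
    abline(h = 0, col = 2)
  }
  if (4 %in% which) {
    plot(g$TAD, g$CWRES, xlab = "Time after last dose (h)",
         ylab = "CWRES", main = "CWRES vs TAD")
    abline(h = 0, col = 2)
  }
  invisible(x)
}
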