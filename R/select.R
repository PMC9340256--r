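# Stepwise covariate search on likelihood-ratio (delta OFV) thresholds:
# forward inclusion at delta OFV > 6.63 (p < 0.01), backward elimination
# at a rise < 10.83 (p < 0.001) on removal. The CYP2C19 phenotype term
# is tested as a single 2-df block (both multipliers together).

#' Candidate covariates for the stepwise search
#'
#' Builds a candidate list from dataset columns. Continuous candidates
#' are centred at the dataset median (recomputed per dataset);
#' categorical candidates must be 0/1; the phenotype candidate expands
#' to the IM/PM multipliers with EM as reference.
#'
#' @param continuous Character vector of continuous covariate columns
#'   (e.g. `c("AGE", "WT")`); the age term uses the
#'   clearance-decreasing sign convention.
#' @param categorical Character vector of 0/1 covariate columns.
#' @param phenotype Include the CYP2C19 phenotype block on CL/F.
#' @param parameter Disposition parameter targeted by the continuous and
#'   categorical candidates (`"cl"` or `"v"`).
#' @return Named list of [cov_continuous()]-style terms, named by their
#'   labels (e.g. `"cl:AGE"`).
#' @export
covariate_candidates <- function(continuous = c("AGE"),
                                 categorical = character(),
                                 phenotype = TRUE,
                                 parameter = "cl") {
  cand <- list()
  if (phenotype) cand <- c(cand, list(cov_phenotype()))
  for (nm in continuous)
    cand <- c(cand, list(cov_continuous(nm, parameter = parameter,
                                        decreasing = toupper(nm) == "AGE")))
  for (nm in categorical)
    cand <- c(cand, list(cov_categorical(nm, parameter = parameter)))
  names(cand) <- vapply(cand, term_label, character(1))
  cand[order(names(cand))]
}

refit_with_spec <- function(data, spec, base_fit, control) {
  init <- base_fit$coefficients[
    intersect(names(base_fit$coefficients), par_table(spec,
                                                      base_fit$start)$name)]
  init <- init[setdiff(names(init), c("ka", "sigma2_add"))]
  fit <- pkfit(data, model = spec, start = base_fit$start,
               fix = setdiff(base_fit$fix, c("ka", "sigma2_add")),
               init = init, control = control)
  if (!fit$converged) {
    # warm starts occasionally strand the outer search; retry cold
    # from the default starting values and keep the better result
    fit2 <- tryCatch(
      pkfit(data, model = spec, start = base_fit$start,
            fix = setdiff(base_fit$fix, c("ka", "sigma2_add")),
            control = control),
      error = function(e) NULL)
    if (!is.null(fit2) &&
        (fit2$converged || fit2$ofv < fit$ofv)) fit <- fit2
  }
  fit
}

#' Likelihood-ratio evaluation of one covariate candidate
#'
#' Fits the base model extended by `candidate` and returns
#' `delta OFV = OFV(base) - OFV(base + candidate)` with the extra
#' degrees of freedom (1 for continuous/binary, 2 for the phenotype
#' block) as attribute `"df"` and the extended fit as attribute
#' `"fit"`. A non-converging candidate fit gives `NA` with a reason.
#'
#' @param base_fit A converged [pkfit()].
#' @param candidate A covariate term ([cov_continuous()] etc.).
#' @param data Dataset; defaults to the base fit's data.
#' @param control Control for the candidate fit; defaults to the base
#'   fit's control without the covariance step.
#' @export
evaluate_candidate <- function(base_fit, candidate,
                               data = base_fit$data, control = NULL) {
  stopifnot(inherits(base_fit, "pkfit"), inherits(candidate, "pk_cov_term"))
  if (!base_fit$converged) stop("base fit has not converged")
  if (is.null(control)) {
    control <- base_fit$control
    control$se <- FALSE
  }
  if (term_label(candidate) %in% spec_labels(base_fit$model)) {
    # already in the model: no information to add
    return(structure(0, df = term_df(candidate), fit = base_fit,
                     reason = "already included"))
  }
  spec <- spec_add_term(base_fit$model, candidate)
  fit2 <- tryCatch(refit_with_spec(data, spec, base_fit, control),
                   error = function(e) e)
  if (inherits(fit2, "error") || !fit2$converged) {
    reason <- if (inherits(fit2, "error")) conditionMessage(fit2)
              else "candidate fit did not converge"
    return(structure(NA_real_, df = term_df(candidate), fit = NULL,
                     reason = reason))
  }
  structure(base_fit$ofv - fit2$ofv, df = term_df(candidate), fit = fit2)
}

new_search_log <- function() {
  data.frame(step = integer(), phase = character(),
             candidate = character(), dofv = numeric(), df = integer(),
             decision = character(), stringsAsFactors = FALSE)
}

log_row <- function(step, phase, candidate, dofv, df, decision) {
  data.frame(step = step, phase = phase, candidate = candidate,
             dofv = dofv, df = df, decision = decision,
             stringsAsFactors = FALSE)
}

#' Forward covariate inclusion
#'
#' Iteratively adds the candidate with the largest delta OFV exceeding
#' `threshold_fwd` until none qualifies. Ties are broken
#' lexicographically by candidate label, so the search is deterministic
#' given the dataset. Candidates whose fit fails are skipped with a
#' logged reason.
#'
#' @param data A [pk_dataset()].
#' @param base A base [pkfit()] or a [pk_model_spec()] to fit first
#'   (default: covariate-free base model).
#' @param candidates Named list of candidate terms, e.g. from
#'   [covariate_candidates()].
#' @param threshold_fwd Forward inclusion threshold on delta OFV
#'   (default 6.63, chi-square 1 df at p = 0.01).
#' @param start,control Passed to the underlying fits.
#' @return A `"pk_covsearch"` object (see [stepwise_covariates()]).
#' @export
forward_search <- function(data, base = pk_model_spec(list()),
                           candidates = covariate_candidates(),
                           threshold_fwd = 6.63,
                           start = pk_params(), control = pkfit_control()) {
  fit <- if (inherits(base, "pkfit")) base else {
    ctl <- control; ctl$se <- FALSE
    pkfit(data, model = base, start = start, control = ctl)
  }
  log <- new_search_log()
  pool <- if (length(candidates)) candidates[order(names(candidates))]
          else candidates
  step <- 0L
  repeat {
    pool <- pool[!(names(pool) %in% spec_labels(fit$model))]
    # an infinite threshold can never be exceeded: return the base as-is
    if (length(pool) == 0 || is.infinite(threshold_fwd)) break
    step <- step + 1L
    dofv <- rep(NA_real_, length(pool))
    fits <- vector("list", length(pool))
    for (k in seq_along(pool)) {
      ev <- evaluate_candidate(fit, pool[[k]], data = data,
                               control = control)
      dofv[k] <- as.numeric(ev)
      fits[[k]] <- attr(ev, "fit")
      if (is.na(dofv[k]))
        log <- rbind(log, log_row(step, "forward", names(pool)[k],
                                  NA, term_df(pool[[k]]),
                                  paste0("skipped: ",
                                         attr(ev, "reason"))))
    }
    qual <- which(!is.na(dofv) & dofv > threshold_fwd)
    if (length(qual) == 0) {
      for (k in which(!is.na(dofv)))
        log <- rbind(log, log_row(step, "forward", names(pool)[k],
                                  dofv[k], term_df(pool[[k]]),
                                  "not included"))
      break
    }
    best <- qual[which.max(dofv[qual])]  # names already sorted: ties -> first
    for (k in which(!is.na(dofv)))
      log <- rbind(log, log_row(step, "forward", names(pool)[k],
                                dofv[k], term_df(pool[[k]]),
                                if (k == best) "included"
                                else "not selected"))
    fit <- fits[[best]]
    pool <- pool[-best]
  }
  new_covsearch(log, fit, threshold_fwd = threshold_fwd,
                threshold_bwd = NA_real_)
}

#' Backward covariate elimination
#'
#' Starting from a full model fit, repeatedly removes the covariate
#' whose removal raises the OFV the least, as long as that rise is below
#' `threshold_bwd`; every retained covariate therefore raises the OFV by
#' at least the threshold when removed.
#'
#' @param data A [pk_dataset()].
#' @param full_fit A converged [pkfit()] of the full model.
#' @param threshold_bwd Backward retention threshold on the OFV rise
#'   (default 10.83, chi-square 1 df at p = 0.001).
#' @param control Control for the reduced fits.
#' @return A `"pk_covsearch"` object.
#' @export
backward_elimination <- function(data, full_fit, threshold_bwd = 10.83,
                                 control = NULL) {
  stopifnot(inherits(full_fit, "pkfit"))
  if (!full_fit$converged) stop("full fit has not converged")
  if (is.null(control)) {
    control <- full_fit$control
    control$se <- FALSE
  }
  fit <- full_fit
  log <- new_search_log()
  step <- 0L
  repeat {
    labs <- sort(spec_labels(fit$model))
    if (length(labs) == 0) break
    step <- step + 1L
    rises <- rep(NA_real_, length(labs))
    fits <- vector("list", length(labs))
    for (k in seq_along(labs)) {
      spec <- spec_drop_term(fit$model, labs[k])
      rf <- tryCatch(refit_with_spec(data, spec, fit, control),
                     error = function(e) NULL)
      if (is.null(rf) || !rf$converged) {
        log <- rbind(log, log_row(step, "backward", labs[k], NA,
                                  term_df_by_label(fit$model, labs[k]),
                                  "skipped: reduced fit failed"))
        next
      }
      rises[k] <- rf$ofv - fit$ofv
      fits[[k]] <- rf
    }
    cand <- which(!is.na(rises) & rises < threshold_bwd)
    if (length(cand) == 0) {
      for (k in which(!is.na(rises)))
        log <- rbind(log, log_row(step, "backward", labs[k], rises[k],
                                  term_df_by_label(fit$model, labs[k]),
                                  "retained"))
      break
    }
    drop <- cand[which.min(rises[cand])]
    for (k in which(!is.na(rises)))
      log <- rbind(log, log_row(step, "backward", labs[k], rises[k],
                                term_df_by_label(fit$model, labs[k]),
                                if (k == drop) "removed" else "kept"))
    fit <- fits[[drop]]
  }
  new_covsearch(log, fit, threshold_fwd = NA_real_,
                threshold_bwd = threshold_bwd)
}

term_df_by_label <- function(spec, label) {
  for (tm in spec$terms) if (term_label(tm) == label) return(term_df(tm))
  NA_integer_
}

#' Stepwise forward-inclusion / backward-elimination search
#'
#' Runs [forward_search()] followed by [backward_elimination()] with the
#' standard thresholds (forward 6.63, backward 10.83).
#'
#' @inheritParams forward_search
#' @inheritParams backward_elimination
#' @return An object of class `"pk_covsearch"`: list with `log` (the
#'   auditable step log), `final_fit`, `included` (labels of retained
#'   covariates), and the thresholds used.
#' @export
stepwise_covariates <- function(data, base = pk_model_spec(list()),
                                candidates = covariate_candidates(),
                                threshold_fwd = 6.63,
                                threshold_bwd = 10.83,
                                start = pk_params(),
                                control = pkfit_control()) {
  fwd <- forward_search(data, base = base, candidates = candidates,
                        threshold_fwd = threshold_fwd, start = start,
                        control = control)
  bwd <- backward_elimination(data, fwd$final_fit,
                              threshold_bwd = threshold_bwd,
                              control = within_control_nose(control))
  new_covsearch(rbind(fwd$log, bwd$log), bwd$final_fit,
                threshold_fwd = threshold_fwd,
                threshold_bwd = threshold_bwd)
}

within_control_nose <- function(control) {
  control$se <- FALSE
  control
}

new_covsearch <- function(log, final_fit, threshold_fwd, threshold_bwd) {
  structure(list(log = log, final_fit = final_fit,
                 included = sort(spec_labels(final_fit$model)),
                 threshold_fwd = threshold_fwd,
                 threshold_bwd = threshold_bwd),
            class = "pk_covsearch")
}

#' @export
print.pk_covsearch <- function(x, ...) {
  cat("Stepwise covariate search")
  if (is.finite(x$threshold_fwd))
    cat(sprintf(" (forward > %.3g", x$threshold_fwd))
  if (is.finite(x$threshold_bwd))
    cat(sprintf("%s backward < %.3g)",
                if (is.finite(x$threshold_fwd)) ";" else " (",
                x$threshold_bwd))
  else if (is.finite(x$threshold_fwd)) cat(")")
  cat("\n")
  if (nrow(x$log)) print(x$log) else cat("  (no steps)\n")
  cat("Included covariates:",
      if (length(x$included)) paste(x$included, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Write the covariate search log
#'
#' Tab-separated step log of a [stepwise_covariates()] /
#' [forward_search()] / [backward_elimination()] result; replaying the
#' logged delta OFV values against the thresholds reproduces the final
#' selection.
#'
#' @param x A `"pk_covsearch"` object.
#' @param path Output file path.
#' @export
write_search_log <- function(x, path) {
  stopifnot(inherits(x, "pk_covsearch"))
  write.table(x$log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
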