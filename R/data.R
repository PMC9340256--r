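# Event-record datasets (NONMEM-style): construction, validation, I/O.

#' Longitudinal PK dataset
#'
#' Builds a validated dataset from an event-record table with columns
#' `ID`, `TIME` (h since each subject's first dose), `AMT` (mg; `NA` on
#' observation rows), `DV` (ng/ml; `NA` on dose rows), `EVID` (1 = dose,
#' 0 = observation), plus per-subject covariate columns (`AGE`, `SEX`,
#' `WT`, `HT`, `CYP2C19` and/or `PHENOTYPE`, laboratory values,
#' co-medication flags). Observations below the assay lower limit of
#' quantification are flagged BLQ and excluded from fitting (with a
#' message); missing `WT`/`HT` are imputed to the column median.
#'
#' @param events A data frame in event-record form.
#' @param lloq Lower limit of quantification (ng/ml); default 3, the
#'   lower end of the assay's linear range.
#' @param quiet Suppress the BLQ/imputation messages.
#' @return An object of class `"pk_dataset"`: a list with elements
#'   `subjects` (one row per subject), `doses`, `obs` (with logical
#'   `BLQ`), `lloq`, `n_blq`, `n_imputed`.
#' @seealso [read_pkdata()], [write_pkdata()]
#' @export
pk_dataset <- function(events, lloq = 3, quiet = FALSE) {
  events <- as.data.frame(events)
  names(events) <- toupper(names(events))
  req <- c("ID", "TIME", "AMT", "DV", "EVID")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (cc in c("TIME", "AMT", "DV", "EVID")) {
    if (!is.numeric(events[[cc]]) && !all(is.na(events[[cc]])))
      stop("column ", cc, " must be numeric")
    events[[cc]] <- as.numeric(events[[cc]])
  }
  if (!all(events$EVID %in% c(0, 1)))
    stop("EVID must be 0 (observation) or 1 (dose); offending row(s): ",
         paste(head(which(!events$EVID %in% c(0, 1))), collapse = ", "))
  if (any(!is.finite(events$TIME)))
    stop("non-numeric TIME in row(s): ",
         paste(head(which(!is.finite(events$TIME))), collapse = ", "))

  is_dose <- events$EVID == 1
  if (any(is_dose & (is.na(events$AMT) | events$AMT <= 0)))
    stop("dose rows must have AMT > 0; offending row(s): ",
         paste(head(which(is_dose & (is.na(events$AMT) | events$AMT <= 0))),
               collapse = ", "))
  if (any(!is_dose & is.na(events$DV)))
    stop("observation rows must have DV; offending row(s): ",
         paste(head(which(!is_dose & is.na(events$DV))), collapse = ", "))

  ids <- unique(events$ID)
  for (id in ids) {
    rows <- which(events$ID == id)
    tt <- events$TIME[rows]
    if (is.unsorted(tt))
      stop("TIME must be non-decreasing within subject ", id,
           " (rows ", paste(head(rows[which(diff(tt) < 0) + 1]),
                            collapse = ", "), ")")
    dose_rows <- rows[events$EVID[rows] == 1]
    obs_rows <- rows[events$EVID[rows] == 0]
    if (length(dose_rows) == 0)
      stop("subject ", id, " has no dose record")
    if (length(obs_rows) == 0)
      stop("subject ", id, " has no observation record")
    first_dose <- min(events$TIME[dose_rows])
    early <- obs_rows[events$TIME[obs_rows] < first_dose]
    if (length(early))
      stop("observation before first dose for subject ", id,
           " (rows ", paste(head(early), collapse = ", "), ")")
  }

  cov_cols <- setdiff(names(events), c(req, "MDV", "BLQ"))
  subjects <- events[match(ids, events$ID), c("ID", cov_cols), drop = FALSE]
  rownames(subjects) <- NULL
  if ("CYP2C19" %in% names(subjects) && !("PHENOTYPE" %in% names(subjects)))
    subjects$PHENOTYPE <- cyp2c19_phenotype(subjects$CYP2C19)
  n_imputed <- 0L
  for (cc in intersect(c("WT", "HT"), names(subjects))) {
    na <- is.na(subjects[[cc]])
    if (any(na)) {
      subjects[[cc]][na] <- median(subjects[[cc]], na.rm = TRUE)
      n_imputed <- n_imputed + sum(na)
    }
  }
  if (n_imputed > 0 && !quiet)
    message(n_imputed, " missing WT/HT value(s) imputed to the column median")

  doses <- data.frame(ID = events$ID[is_dose],
                      TIME = events$TIME[is_dose],
                      AMT = events$AMT[is_dose])
  obs <- data.frame(ID = events$ID[!is_dose],
                    TIME = events$TIME[!is_dose],
                    DV = events$DV[!is_dose])
  obs$BLQ <- !is.na(obs$DV) & obs$DV < lloq
  n_blq <- sum(obs$BLQ)
  if (n_blq > 0 && !quiet)
    message(n_blq, " observation(s) below LLOQ ", lloq,
            " ng/ml flagged BLQ and excluded from fitting")
  if (any(!obs$BLQ & obs$DV <= 0))
    stop("non-BLQ observations must be positive")

  structure(list(subjects = subjects, doses = doses, obs = obs,
                 lloq = lloq, n_blq = n_blq, n_imputed = n_imputed),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("PK dataset: %d subjects, %d observations (%d BLQ excluded), %d dose records\n",
              nrow(x$subjects), nrow(x$obs), x$n_blq, nrow(x$doses)))
  if ("PHENOTYPE" %in% names(x$subjects)) {
    tb <- table(x$subjects$PHENOTYPE)
    cat("  CYP2C19 phenotypes:",
        paste(sprintf("%s %d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.pk_dataset <- function(x, ...) {
  cov_cols <- setdiff(names(x$subjects), "ID")
  d <- data.frame(ID = x$doses$ID, TIME = x$doses$TIME, AMT = x$doses$AMT,
                  DV = NA_real_, EVID = 1, MDV = 1)
  o <- data.frame(ID = x$obs$ID, TIME = x$obs$TIME, AMT = NA_real_,
                  DV = x$obs$DV, EVID = 0, MDV = 0)
  ev <- rbind(d, o)
  ev <- ev[order(ev$ID, ev$TIME, -ev$EVID), , drop = FALSE]
  idx <- match(ev$ID, x$subjects$ID)
  for (cc in cov_cols) ev[[cc]] <- x$subjects[[cc]][idx]
  rownames(ev) <- NULL
  ev
}

#' Read / write event-record CSV files
#'
#' `read_pkdata()` reads a NONMEM-style event-record CSV (UTF-8, header
#' required) and validates it via [pk_dataset()]; `write_pkdata()` writes
#' a dataset back to that format. The two are inverse on validated
#' tables.
#'
#' @param path CSV file path.
#' @param lloq Lower limit of quantification (ng/ml) used to flag BLQ.
#' @param quiet Suppress validation messages.
#' @return `read_pkdata()` returns a `"pk_dataset"`; `write_pkdata()`
#'   returns `path` invisibly.
#' @export
read_pkdata <- function(path, lloq = 3, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  events <- read.csv(path, stringsAsFactors = FALSE)
  pk_dataset(events, lloq = lloq, quiet = quiet)
}

#' @rdname read_pkdata
#' @param data A `"pk_dataset"` object.
#' @export
write_pkdata <- function(data, path) {
  stopifnot(inherits(data, "pk_dataset"))
  write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

# number of usable (non-BLQ) observations
n_obs_used <- function(data) sum(!data$obs$BLQ)

# --- internal fitting design ------------------------------------------------

# Flatten a dataset into the structure used by the likelihood code.
# Observations whose dose history is uniform (equal amounts, equal
# spacing) are evaluated with the closed-form multiple-dose kernel; the
# rest fall back to explicit (observation x dose) superposition pairs.
# Only non-BLQ observations unless include_blq.
build_design <- function(data, include_blq = FALSE) {
  obs <- if (include_blq) data$obs else data$obs[!data$obs$BLQ, , drop = FALSE]
  subjects <- data$subjects
  sub_idx <- match(obs$ID, subjects$ID)
  n_obs <- nrow(obs)
  po <- vector("list", n_obs)
  uni <- logical(n_obs)
  uk <- numeric(n_obs)      # number of doses received
  us <- numeric(n_obs)      # time since last dose
  utau <- numeric(n_obs)    # dosing interval
  uamt <- numeric(n_obs)
  doses_by_id <- split(data$doses, data$doses$ID)
  for (j in seq_len(n_obs)) {
    dd <- doses_by_id[[as.character(obs$ID[j])]]
    dt <- obs$TIME[j] - dd$TIME
    keep <- dt >= 0
    dtk <- dt[keep]
    amtk <- dd$AMT[keep]
    k <- length(dtk)
    if (k == 0) stop("internal error: observation without a preceding dose")
    sp <- if (k > 1) diff(sort(dtk)) else 1
    if (all(abs(amtk - amtk[1]) < 1e-12) &&
        (k == 1 || max(abs(sp - sp[1])) < 1e-9)) {
      uni[j] <- TRUE
      uk[j] <- k
      us[j] <- min(dtk)
      utau[j] <- if (k > 1) sp[1] else 24
      uamt[j] <- amtk[1]
    } else {
      po[[j]] <- list(dt = dtk, amt = amtk)
    }
  }
  gen <- which(!uni)
  npairs <- vapply(po[gen], function(p) length(p$dt), integer(1))
  pair_obs <- rep.int(gen, npairs)
  list(n_sub = nrow(subjects),
       n_obs = n_obs,
       obs_sub = sub_idx,
       y = obs$DV,
       times = obs$TIME,
       obs_id = obs$ID,
       uni_idx = which(uni),
       uni_sub = as.integer(sub_idx[uni]),
       uni_k = uk[uni], uni_s = us[uni], uni_tau = utau[uni],
       uni_amt = uamt[uni],
       pair_obs = as.integer(pair_obs),
       pair_sub = as.integer(sub_idx[pair_obs]),
       pair_dt = as.numeric(unlist(lapply(po[gen], `[[`, "dt")) %||%
                              numeric(0)),
       pair_amt = as.numeric(unlist(lapply(po[gen], `[[`, "amt")) %||%
                               numeric(0)))
}
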