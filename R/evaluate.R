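# Model validation battery: CWRES, goodness-of-fit table, NPDE,
# nonparametric bootstrap.

#' Conditional weighted residuals
#'
#' First-order expansion of the model about the empirical-Bayes modes:
#' per subject, with `G = df/deta` at `eta_hat`,
#' `E = f(eta_hat) - G %*% eta_hat`,
#' `COV = G %*% Omega %*% t(G) + diag(sigma2_prop * f(eta_hat)^2 +
#' sigma2_add)`, and `CWRES = solve(L, y - E)` with `L` the lower
#' Cholesky factor of `COV`. Under a correct model CWRES are
#' approximately standard normal.
#'
#' @param fit A converged [pkfit()] with empirical-Bayes modes.
#' @return Numeric vector of CWRES, one per quantifiable observation.
#' @export
cwres <- function(fit) {
  stopifnot(inherits(fit, "pkfit"))
  cf <- fit$coefficients
  Omega <- diag(c(cf[["omega2_cl"]], cf[["omega2_v"]]))
  inner <- fit$inner
  design <- fit$design
  eta <- as.matrix(fit$eta[, c("eta_cl", "eta_v")])
  out <- numeric(design$n_obs)
  for (i in seq_len(design$n_sub)) {
    idx <- which(design$obs_sub == i)
    G <- inner$J[idx, , drop = FALSE]
    f <- inner$f[idx]
    E <- f - as.vector(G %*% eta[i, ])
    C <- G %*% Omega %*% t(G) +
      diag(cf[["sigma2_prop"]] * f^2 + cf[["sigma2_add"]],
           nrow = length(idx))
    L <- tryCatch(t(chol(C)), error = function(e) NULL)
    if (is.null(L)) {
      jit <- 1e-8 * mean(diag(C))
      message("singular CWRES covariance for subject ",
              fit$data$subjects$ID[i], "; regularized with jitter ",
              signif(jit, 3))
      L <- t(chol(C + diag(jit, nrow(C))))
    }
    out[idx] <- forwardsolve(L, design$y[idx] - E)
  }
  out
}

#' Goodness-of-fit table
#'
#' One row per quantifiable observation with the population prediction
#' (`PRED`, random effects at zero), individual prediction (`IPRED`, at
#' the empirical-Bayes modes), conditional weighted residual (`CWRES`)
#' and time after the last dose (`TAD`, h).
#'
#' @param fit A fitted [pkfit()] model.
#' @return A data frame with columns `ID`, `TIME`, `TAD`, `DV`, `PRED`,
#'   `IPRED`, `CWRES`.
#' @export
gof_table <- function(fit) {
  stopifnot(inherits(fit, "pkfit"))
  design <- fit$design
  last_dose <- vapply(seq_len(design$n_obs), function(j) {
    dd <- fit$data$doses
    dt <- design$times[j] - dd$TIME[dd$ID == design$obs_id[j]]
    design$times[j] - min(dt[dt >= 0])
  }, numeric(1))
  data.frame(ID = design$obs_id,
             TIME = design$times,
             TAD = design$times - last_dose,
             DV = design$y,
             PRED = predict(fit, type = "pred"),
             IPRED = fit$inner$f,
             CWRES = cwres(fit))
}

#' Normalized prediction distribution errors
#'
#' Simulates `nsim` replicate datasets from the fitted model under every
#' subject's own design, decorrelates observed and simulated vectors per
#' subject with the empirical mean and lower Cholesky factor of the
#' simulated covariance, rank-transforms the observation within its
#' simulated distribution (clipping ranks of exactly 0 or 1 to
#' `1/(2*nsim)` bounds), and maps through the standard normal quantile
#' function. Under the true model the NPDE are standard normal; this is
#' checked with a t test (mean 0), a Fisher-type chi-square test
#' (variance 1) and a Shapiro-Wilk normality test, combined into a
#' Bonferroni-adjusted global p-value (3 times the minimum).
#'
#' @param fit A fitted [pkfit()] model.
#' @param nsim Number of simulated replicates (>= 100; the reference
#'   analysis used 1000).
#' @param seed Optional RNG seed.
#' @param y Optional replacement observation vector (same length/order
#'   as the fitting observations); used for self-consistency checks.
#' @return An object of class `"pk_npde"`: list with `npde`
#'   (per-observation values), `mean`, `variance`, `skewness`,
#'   `kurtosis`, `p_t`, `p_fisher`, `p_sw`, `p_global`, `nsim`.
#' @export
npde <- function(fit, nsim = 1000, seed = NULL, y = NULL) {
  stopifnot(inherits(fit, "pkfit"))
  if (nsim < 100) stop("nsim must be >= 100")
  design <- fit$design
  yobs <- y %||% design$y
  if (length(yobs) != design$n_obs)
    stop("y must have one value per quantifiable observation")
  sims <- simulate(fit, nsim = nsim, seed = seed)
  val <- numeric(design$n_obs)
  for (i in seq_len(design$n_sub)) {
    idx <- which(design$obs_sub == i)
    S <- sims[idx, , drop = FALSE]           # k x nsim
    m <- rowMeans(S)
    V <- tcrossprod(S - m) / (nsim - 1)
    L <- tryCatch(t(chol(V)), error = function(e)
      t(chol(V + diag(1e-8 * mean(diag(V)), nrow(V)))))
    ystar <- forwardsolve(L, yobs[idx] - m)
    sstar <- forwardsolve(L, S - m)
    pde <- rowSums(sstar < ystar) / nsim
    pde <- pmin(pmax(pde, 1 / (2 * nsim)), 1 - 1 / (2 * nsim))
    val[idx] <- qnorm(pde)
  }
  mo <- sample_moments(val)
  n <- length(val)
  p_t <- t.test(val, mu = 0)$p.value
  stat <- (n - 1) * mo$variance
  p_fisher <- 2 * min(pchisq(stat, n - 1), pchisq(stat, n - 1,
                                                  lower.tail = FALSE))
  p_sw <- shapiro.test(val)$p.value
  structure(list(npde = val, mean = mo$mean, variance = mo$variance,
                 skewness = mo$skewness, kurtosis = mo$kurtosis,
                 p_t = p_t, p_fisher = min(p_fisher, 1), p_sw = p_sw,
                 p_global = min(1, 3 * min(p_t, p_fisher, p_sw)),
                 nsim = nsim),
            class = "pk_npde")
}

#' @export
print.pk_npde <- function(x, ...) {
  cat(sprintf("NPDE over %d observations (%d simulations)\n",
              length(x$npde), x$nsim))
  cat(sprintf("  mean %.4f, variance %.4f, skewness %.4f, kurtosis %.4f\n",
              x$mean, x$variance, x$skewness, x$kurtosis))
  cat(sprintf("  t-test p %.3f, variance-test p %.3f, Shapiro-Wilk p %.3f\n",
              x$p_t, x$p_fisher, x$p_sw))
  cat(sprintf("  global adjusted p %.3f\n", x$p_global))
  invisible(x)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement to the original subject count,
#' refits each replicate (starting from the original estimates), and
#' summarizes each parameter by the median and percentile 2.5%/97.5%
#' bounds over converged replicates. Failed replicate fits are counted,
#' not fatal.
#'
#' @param fit A fitted [pkfit()] model.
#' @param n Number of bootstrap replicates (the reference analysis used
#'   1000).
#' @param seed Optional RNG seed.
#' @param control Control for the replicate fits; defaults to the
#'   original control without the covariance step.
#' @return An object of class `"pk_bootstrap"`: list with `replicates`
#'   (matrix of estimates), `summary` (median and CI per parameter),
#'   `n`, `n_failed`.
#' @export
bootstrap_pkfit <- function(fit, n = 1000, seed = NULL, control = NULL) {
  stopifnot(inherits(fit, "pkfit"))
  if (nrow(fit$data$subjects) < 2) stop("bootstrap needs >= 2 subjects")
  if (is.null(control)) {
    control <- fit$control
    control$se <- FALSE
  }
  start <- fit_params_as_start(fit)
  ids <- fit$data$subjects$ID
  free <- fit$free
  with_seed(seed, {
    reps <- matrix(NA_real_, n, length(free),
                   dimnames = list(NULL, free))
    n_failed <- 0L
    for (b in seq_len(n)) {
      take <- sample(ids, length(ids), replace = TRUE)
      ds <- resample_dataset(fit$data, take)
      rf <- tryCatch(
        pkfit(ds, model = fit$model, start = start,
              fix = setdiff(fit$fix, c("ka", "sigma2_add")),
              init = fit$coefficients[free], control = control),
        error = function(e) NULL)
      if (is.null(rf) || !rf$converged) {
        n_failed <- n_failed + 1L
        if (!is.null(rf)) reps[b, ] <- NA_real_
      } else {
        reps[b, ] <- rf$coefficients[free]
      }
    }
    ok <- stats::complete.cases(reps)
    if (!any(ok)) stop("all bootstrap replicate fits failed")
    qs <- apply(reps[ok, , drop = FALSE], 2, quantile,
                probs = c(0.5, 0.025, 0.975))
    structure(list(replicates = reps,
                   summary = data.frame(parameter = free,
                                        estimate = fit$coefficients[free],
                                        median = qs[1, ],
                                        lower = qs[2, ],
                                        upper = qs[3, ],
                                        row.names = NULL),
                   n = n, n_failed = n_failed),
              class = "pk_bootstrap")
  })
}

#' @export
print.pk_bootstrap <- function(x, digits = 4, ...) {
  cat(sprintf("Bootstrap: %d replicates (%d failed)\n", x$n, x$n_failed))
  tb <- x$summary
  for (cc in c("estimate", "median", "lower", "upper"))
    tb[[cc]] <- signif(tb[[cc]], digits)
  print(tb)
  invisible(x)
}

# Rebuild a dataset from a with-replacement draw of subject IDs,
# renumbering duplicates.
resample_dataset <- function(data, take) {
  subjects <- data$subjects[match(take, data$subjects$ID), , drop = FALSE]
  new_id <- seq_along(take)
  pieces_d <- vector("list", length(take))
  pieces_o <- vector("list", length(take))
  for (i in seq_along(take)) {
    d <- data$doses[data$doses$ID == take[i], , drop = FALSE]
    o <- data$obs[data$obs$ID == take[i], , drop = FALSE]
    d$ID <- new_id[i]
    o$ID <- new_id[i]
    pieces_d[[i]] <- d
    pieces_o[[i]] <- o
  }
  subjects$ID <- new_id
  rownames(subjects) <- NULL
  out <- list(subjects = subjects,
              doses = do.call(rbind, pieces_d),
              obs = do.call(rbind, pieces_o),
              lloq = data$lloq, n_blq = sum(do.call(rbind, pieces_o)$BLQ),
              n_imputed = data$n_imputed)
  class(out) <- "pk_dataset"
  out
}

# Translate fitted coefficients into a pk_params start object (canonical
# terms mapped back; generic covariate thetas are not representable and
# simply seed the same value via par_table's AGE/phenotype conventions).
fit_params_as_start <- function(fit) {
  cf <- fit$coefficients
  s <- fit$start
  age_theta <- if ("theta_cl_age" %in% names(cf)) cf[["theta_cl_age"]]
               else s$theta_age
  pk_params(tvcl = cf[["tvcl"]], tvv = cf[["tvv"]], ka = s$ka,
            theta_age = age_theta,
            theta_im = if ("theta_im" %in% names(cf)) cf[["theta_im"]]
                       else s$theta_im,
            theta_pm = if ("theta_pm" %in% names(cf)) cf[["theta_pm"]]
                       else s$theta_pm,
            omega2_cl = cf[["omega2_cl"]], omega2_v = cf[["omega2_v"]],
            sigma2_prop = cf[["sigma2_prop"]], sigma2_add = s$sigma2_add,
            age_center = s$age_center, age_decreasing = s$age_decreasing,
            cov_floor = s$cov_floor)
}
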