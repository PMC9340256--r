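# Shared fixtures. Expensive objects (study-scale dataset and fit) are
# memoised so several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small synthetic study
make_study <- function(n_subjects, seed, truth = pk_params(),
                       config = NULL) {
  config <- config %||% cohort_config(n_subjects = n_subjects)
  coh <- generate_cohort(config, seed = seed)
  simulate_pkdata(coh, truth = truth, config = config, seed = seed + 1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the reference study-scale experiment: 106 subjects simulated at the
# published final-model estimates, fitted with the FOCE-I engine
study_dataset <- function() {
  memo("study_dataset", make_study(106, seed = 421))
}

study_fit <- function() {
  memo("study_fit",
       pkfit(study_dataset(), control = pkfit_control(se = FALSE)))
}

# deterministic 2-subject event table exercising both qd and bid dosing
tiny_events <- function() {
  rbind(
    data.frame(ID = 1, TIME = (0:9) * 24, AMT = 10, DV = NA, EVID = 1),
    data.frame(ID = 1, TIME = c(190, 215.5), AMT = NA,
               DV = c(22.1, 25.3), EVID = 0),
    data.frame(ID = 2, TIME = (0:19) * 12, AMT = 5, DV = NA, EVID = 1),
    data.frame(ID = 2, TIME = c(180, 227), AMT = NA,
               DV = c(31.0, 28.4), EVID = 0)
  )[order(c(rep(1, 10), 1, 1, rep(2, 20), 2, 2),
          c((0:9) * 24, 190, 215.5, (0:19) * 12, 180, 227)), ]
}

# fixed 2-subject nonlinear toy for the quadrature oracle: 6
# observations per subject spread across the dosing week and moderate
# variances, so the Laplace-type approximation is accurate while the
# model stays genuinely nonlinear in eta
quad_events <- function() {
  rbind(
    data.frame(ID = 1, TIME = (0:11) * 24, AMT = 10, DV = NA, EVID = 1),
    data.frame(ID = 1,
               TIME = c(162.6, 174, 184.1, 232.2, 234.1, 260),
               AMT = NA,
               DV = c(22.16, 30.55, 27.35, 22.56, 20.97, 22.22),
               EVID = 0),
    data.frame(ID = 2, TIME = (0:11) * 24, AMT = 20, DV = NA, EVID = 1),
    data.frame(ID = 2,
               TIME = c(163.3, 182.8, 208.9, 213.4, 247, 264.8),
               AMT = NA,
               DV = c(63.89, 58.21, 76.14, 68.4, 94.36, 86.41),
               EVID = 0))
}

quad_dataset <- function() {
  ev <- quad_events()
  ev <- ev[order(ev$ID, ev$TIME, -ev$EVID), ]
  ev$AGE <- c(35, 55)[ev$ID]
  ev$PHENOTYPE <- c("EM", "IM")[ev$ID]
  pk_dataset(ev, quiet = TRUE)
}

quad_params <- function() {
  pk_params(omega2_cl = 0.05, omega2_v = 0.05, sigma2_prop = 0.01)
}

tiny_dataset <- function(age = c(40, 60), phenotype = c("EM", "PM")) {
  ev <- tiny_events()
  ev$AGE <- age[match(ev$ID, c(1, 2))]
  ev$PHENOTYPE <- phenotype[match(ev$ID, c(1, 2))]
  pk_dataset(ev, quiet = TRUE)
}

# Gauss-Hermite nodes/weights (Golub-Welsch), for the quadrature oracle
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values),
       weights = rev(sqrt(pi) * e$vectors[1, ]^2))
}

# exact -2 log marginal likelihood by adaptive Gauss-Hermite quadrature
# for one subject of a pk_dataset under proportional error
agh_minus2ll_subject <- function(data, params, sub_idx, n_nodes = 16) {
  design <- escipk:::build_design(data)
  base <- escipk:::params_baseline(params, data$subjects)
  Omega <- diag(c(params$omega2_cl, params$omega2_v))
  inner <- escipk:::pk_inner(design, base$cl_base, base$v_base,
                             params$ka, Omega, params$sigma2_prop,
                             params$sigma2_add)
  idx <- which(design$obs_sub == sub_idx)
  y <- design$y[idx]
  mu <- inner$eta[sub_idx, ]
  Oinv <- solve(Omega)
  H <- 0.5 * (2 * (Oinv + matrix(c(inner$A[sub_idx, 1], inner$A[sub_idx, 2],
                                   inner$A[sub_idx, 2], inner$A[sub_idx, 3]),
                                 2, 2)))
  L <- t(chol(solve(H)))
  gh <- gauss_hermite(n_nodes)
  id <- data$subjects$ID[sub_idx]
  dd <- data$doses[data$doses$ID == id, ]
  tt <- design$times[idx]
  log_joint <- function(eta) {
    f <- concentration_profile(dd$TIME, dd$AMT, tt,
                               base$cl_base[sub_idx] * exp(eta[1]),
                               base$v_base[sub_idx] * exp(eta[2]),
                               params$ka)
    v <- params$sigma2_prop * f^2 + params$sigma2_add
    sum(dnorm(y, f, sqrt(v), log = TRUE)) +
      sum(dnorm(eta, 0, sqrt(diag(Omega)), log = TRUE))
  }
  tot <- 0
  for (a in seq_len(n_nodes)) {
    for (b in seq_len(n_nodes)) {
      z <- c(gh$nodes[a], gh$nodes[b])
      eta <- mu + sqrt(2) * as.vector(L %*% z)
      tot <- tot + gh$weights[a] * gh$weights[b] *
        exp(log_joint(eta) + sum(z^2))
    }
  }
  -2 * (log(tot) + log(2) * 1 + log(det(L)))  # sqrt(2)^2 |L|
}
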