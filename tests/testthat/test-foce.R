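# FOCE-I engine: conditional modes, Laplace objective, and the outer
# fit. The generic R engine doubles as a reference for the compiled
# path.

test_that("compiled and reference engines agree on the PK model", {
  ds <- tiny_dataset()
  p <- pk_params()
  d <- escipk:::build_design(ds)
  base <- escipk:::params_baseline(p, ds$subjects)
  O <- diag(c(p$omega2_cl, p$omega2_v))
  rc <- escipk:::pk_marginal_ofv(d, base$cl_base, base$v_base, p$ka, O,
                                 p$sigma2_prop, 0, use_cpp = TRUE)
  rr <- escipk:::pk_marginal_ofv(d, base$cl_base, base$v_base, p$ka, O,
                                 p$sigma2_prop, 0, use_cpp = FALSE)
  expect_equal(rc$ofv, rr$ofv, tolerance = 1e-9)
  expect_equal(rc$inner$eta, rr$inner$eta, tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("conditional modes are zero for data equal to typical predictions", {
  mk_exact <- function(p) {
    ev <- tiny_events()
    ev$AGE <- 45
    ev$PHENOTYPE <- "EM"
    obs_rows <- ev$EVID == 0
    for (id in unique(ev$ID)) {
      sel <- obs_rows & ev$ID == id
      dd <- ev[ev$EVID == 1 & ev$ID == id, ]
      ev$DV[sel] <- concentration_profile(dd$TIME, dd$AMT, ev$TIME[sel],
                                          p$tvcl, p$tvv, p$ka)
    }
    pk_dataset(ev, quiet = TRUE)
  }
  # additive-only error: the penalty is minimized exactly at zero
  p_add <- pk_params(theta_age = 0, theta_im = 1, theta_pm = 1,
                     sigma2_prop = 0, sigma2_add = 4)
  ce <- conditional_eta(mk_exact(p_add), p_add)
  expect_lt(max(abs(c(ce$eta_cl, ce$eta_v))), 1e-6)
  expect_true(all(ce$converged))
  # proportional error without the interaction term: likewise exact
  p_pr <- pk_params(theta_age = 0, theta_im = 1, theta_pm = 1)
  ce2 <- conditional_eta(mk_exact(p_pr), p_pr, interaction = FALSE)
  expect_lt(max(abs(c(ce2$eta_cl, ce2$eta_v))), 1e-6)
  # under FOCE-I the log-variance term shifts the modes only slightly
  ce3 <- conditional_eta(mk_exact(p_pr), p_pr)
  expect_lt(max(abs(c(ce3$eta_cl, ce3$eta_v))), 0.05)
  # shrinkage: omega2 -> 0 forces the modes to zero for any data
  ce0 <- conditional_eta(tiny_dataset(),
                         pk_params(omega2_cl = 1e-8, omega2_v = 1e-8))
  expect_lt(max(abs(c(ce0$eta_cl, ce0$eta_v))), 1e-3)
})

test_that("conditional modes match a dense grid search", {
  ds <- tiny_dataset()
  p <- pk_params()
  ce <- conditional_eta(ds, p)
  d <- escipk:::build_design(ds)
  base <- escipk:::params_baseline(p, ds$subjects)
  Oinv <- solve(diag(c(p$omega2_cl, p$omega2_v)))
  for (i in 1:2) {
    id <- ds$subjects$ID[i]
    obs <- ds$obs[ds$obs$ID == id, ]
    dd <- ds$doses[ds$doses$ID == id, ]
    pen_dev <- function(e1, e2) {
      f <- concentration_profile(dd$TIME, dd$AMT, obs$TIME,
                                 base$cl_base[i] * exp(e1),
                                 base$v_base[i] * exp(e2), p$ka)
      v <- p$sigma2_prop * f^2
      sum((obs$DV - f)^2 / v + log(v)) +
        as.numeric(c(e1, e2) %*% Oinv %*% c(e1, e2))
    }
    # coarse-to-fine grid, final spacing 2.5e-5
    ctr <- c(0, 0)
    for (half in c(0.8, 0.05, 0.002)) {
      g1 <- seq(ctr[1] - half, ctr[1] + half, length.out = 41)
      g2 <- seq(ctr[2] - half, ctr[2] + half, length.out = 41)
      val <- outer(g1, g2, Vectorize(pen_dev))
      ix <- which(val == min(val), arr.ind = TRUE)[1, ]
      ctr <- c(g1[ix[1]], g2[ix[2]])
    }
    expect_lt(abs(ce$eta_cl[i] - ctr[1]), 1e-4)
    expect_lt(abs(ce$eta_v[i] - ctr[2]), 1e-4)
  }
})

test_that("the Laplace OFV is exact for linear-Gaussian toy models", {
  # f(eta) = a + X eta with additive error: the marginal is Gaussian and
  # the FOCE objective must equal the closed-form -2 log likelihood
  set.seed(14)
  n_sub <- 3; k <- 4
  X <- lapply(1:n_sub, function(i) matrix(rnorm(k * 2), k, 2))
  a <- lapply(1:n_sub, function(i) 5 + rnorm(k))
  Omega <- diag(c(0.5, 0.3))
  sigma2 <- 0.4
  eta_true <- matrix(rnorm(n_sub * 2, 0, 0.5), n_sub, 2)
  y <- unlist(lapply(1:n_sub, function(i)
    a[[i]] + X[[i]] %*% eta_true[i, ] + rnorm(k, 0, sqrt(sigma2))))
  obs_sub <- rep(1:n_sub, each = k)
  model <- function(eta, deriv = TRUE) {
    f <- unlist(lapply(1:n_sub, function(i)
      a[[i]] + X[[i]] %*% eta[i, ]))
    if (!deriv) return(list(f = f))
    list(f = f, J = do.call(rbind, X))
  }
  res <- escipk:::foce_marginal_ofv(model, y, obs_sub, n_sub, Omega,
                                    s2p = 0, s2a = sigma2)
  exact <- sum(vapply(1:n_sub, function(i) {
    S <- X[[i]] %*% Omega %*% t(X[[i]]) + diag(sigma2, k)
    r <- y[obs_sub == i] - a[[i]]
    k * log(2 * pi) + determinant(S)$modulus +
      as.numeric(r %*% solve(S, r))
  }, numeric(1)))
  expect_equal(res$ofv, exact, tolerance = 1e-8)
})

test_that("the FOCE OFV matches adaptive Gauss-Hermite quadrature", {
  ds <- quad_dataset()
  p <- quad_params()
  ofv <- as.numeric(foce_ofv(ds, p))
  quad <- agh_minus2ll_subject(ds, p, 1) + agh_minus2ll_subject(ds, p, 2)
  expect_lt(abs(ofv - quad), 0.1)
})

test_that("the OFV is additive over subjects and invariant to relabeling", {
  ds <- tiny_dataset()
  p <- pk_params()
  per_sub <- attr(foce_ofv(ds, p), "per_subject")
  # duplicate subject 1 under a new ID
  ev <- as.data.frame(ds)
  dup <- ev[ev$ID == 1, ]
  dup$ID <- 3
  ds3 <- pk_dataset(rbind(ev, dup), quiet = TRUE)
  ofv3 <- as.numeric(foce_ofv(ds3, p))
  expect_equal(ofv3, sum(per_sub) + per_sub[1], tolerance = 1e-8)
  # permuting subject order leaves the total unchanged
  perm <- rbind(ev[ev$ID == 2, ], ev[ev$ID == 1, ])
  expect_equal(as.numeric(foce_ofv(pk_dataset(perm, quiet = TRUE), p)),
               as.numeric(foce_ofv(ds, p)), tolerance = 1e-8)
})

test_that("near-noiseless data identify the typical values", {
  truth <- pk_params(omega2_cl = 0, omega2_v = 0, sigma2_prop = 1e-6)
  cfg <- cohort_config(n_subjects = 20, trough_fraction = 0.5)
  coh <- generate_cohort(cfg, seed = 51)
  ds <- simulate_pkdata(coh, truth = truth, config = cfg, seed = 52)
  fit <- pkfit(ds, control = pkfit_control(se = FALSE))
  expect_lt(abs(coef(fit)[["tvcl"]] / 16.3 - 1), 0.01)
  expect_lt(abs(coef(fit)[["tvv"]] / 815 - 1), 0.01)
})

test_that("empirical-Bayes modes shrink toward zero as residual noise grows", {
  ds <- study_dataset()
  p <- pk_params()
  e1 <- conditional_eta(ds, p)
  p2 <- pk_params(sigma2_prop = 16 * p$sigma2_prop)
  e2 <- conditional_eta(ds, p2)
  expect_lt(mean(abs(e2$eta_cl)), mean(abs(e1$eta_cl)))
  expect_lt(mean(abs(e2$eta_v)), mean(abs(e1$eta_v)))
})

test_that("refits from different starting values agree", {
  ds <- study_dataset()
  f1 <- study_fit()
  f2 <- pkfit(ds, control = pkfit_control(se = FALSE),
              start = pk_params(tvcl = 10, tvv = 500, theta_age = 0.002,
                                theta_im = 1, theta_pm = 1,
                                omega2_cl = 0.2, omega2_v = 0.1,
                                sigma2_prop = 0.06))
  expect_lt(abs(f1$ofv - f2$ofv), 0.1)
  expect_lt(max(abs(coef(f1)[f1$free] / coef(f2)[f2$free] - 1)), 0.01)
})

test_that("median parameter recovery stays inside the reference intervals", {
  # repeated study-scale simulation/refit: medians of the recovered
  # well-identified parameters fall in the published bootstrap 95% CIs
  est <- sapply(1:5, function(r) {
    ds <- make_study(106, seed = 700 + r)
    coef(pkfit(ds, control = pkfit_control(se = FALSE,
                                           rel_tol = 1e-6)))
  })
  med <- apply(est, 1, median)
  expect_gt(med[["tvcl"]], 14.7);  expect_lt(med[["tvcl"]], 18.2)
  expect_gt(med[["tvv"]], 581.9);  expect_lt(med[["tvv"]], 1070.8)
  expect_gt(med[["theta_pm"]], 0.38); expect_lt(med[["theta_pm"]], 0.59)
  expect_gt(med[["sigma2_prop"]], 0.0226)
  expect_lt(med[["sigma2_prop"]], 0.0359)
})

test_that("plain FOCE and FOCE-I differ through the interaction term", {
  ds <- tiny_dataset()
  p <- pk_params()
  ofv_i <- as.numeric(foce_ofv(ds, p, interaction = TRUE))
  ofv_p <- as.numeric(foce_ofv(ds, p, interaction = FALSE))
  expect_false(isTRUE(all.equal(ofv_i, ofv_p)))
  expect_lt(abs(ofv_i - ofv_p), 5)  # same data, same scale
})
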