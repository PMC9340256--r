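# Validation battery: CWRES, GOF table, NPDE, bootstrap.

test_that("CWRES reduces to simple weighted residuals without random effects", {
  # negligible IIV and an additive-only error: CWRES = (y - f)/sigma
  sigma <- 1.5
  truth <- pk_params(omega2_cl = 1e-8, omega2_v = 1e-8,
                     sigma2_prop = 1e-10, sigma2_add = sigma^2)
  cfg <- cohort_config(n_subjects = 8)
  ds <- simulate_pkdata(generate_cohort(cfg, seed = 71), truth = truth,
                        config = cfg, seed = 72)
  fit <- pkfit(ds, start = truth,
               fix = c("tvv", "theta_im", "theta_pm",
                       "theta_cl_age", "omega2_cl", "omega2_v",
                       "sigma2_prop"),
               control = pkfit_control(se = FALSE))
  w <- cwres(fit)
  ip <- fit$inner$f
  expect_equal(w, (fit$design$y - ip) / sigma, tolerance = 1e-3)
})

test_that("CWRES on data from the generating model look standard normal", {
  fit <- study_fit()
  w <- cwres(fit)
  expect_equal(length(w), fit$n_obs)
  expect_lt(abs(mean(w)), 0.15)
  expect_gt(var(w), 0.75)
  expect_lt(var(w), 1.3)
  # residuals() dispatch agrees
  expect_identical(residuals(fit), w)
})

test_that("duplicated subjects get identical CWRES segments", {
  ds <- tiny_dataset()
  ev <- as.data.frame(ds)
  dup <- ev[ev$ID == 1, ]
  dup$ID <- 3
  ds3 <- pk_dataset(rbind(ev, dup), quiet = TRUE)
  p <- pk_params()
  fit <- pkfit(ds3, start = p,
               fix = c("tvcl", "tvv", "theta_im", "theta_pm",
                       "theta_cl_age", "omega2_v", "sigma2_prop"),
               control = pkfit_control(se = FALSE))
  w <- cwres(fit)
  seg1 <- w[fit$design$obs_id == 1]
  seg3 <- w[fit$design$obs_id == 3]
  expect_equal(seg1, seg3, tolerance = 1e-8)
})

test_that("the GOF table carries one row per usable observation", {
  fit <- study_fit()
  g <- gof_table(fit)
  expect_equal(nrow(g), fit$n_obs)
  expect_true(all(g$TAD >= 0))
  expect_true(all(g$TAD <= g$TIME))
  expect_equal(g$IPRED, fitted(fit))
  expect_equal(g$PRED, predict(fit, type = "pred"))
  # trough-dominated design: most TAD near the dosing interval
  expect_gt(mean(g$TAD > 9), 0.8)
})

test_that("NPDE of a replicate from the fitted model is standard normal", {
  fit <- study_fit()
  yrep <- as.vector(simulate(fit, 1, seed = 88))
  nd <- npde(fit, nsim = 300, seed = 89, y = yrep)
  expect_lt(abs(nd$mean), 0.1)
  expect_gt(nd$variance, 0.85)
  expect_lt(nd$variance, 1.15)
  expect_true(all(is.finite(nd$npde)))
  expect_true(all(c(nd$p_t, nd$p_fisher, nd$p_sw, nd$p_global) >= 0))
  expect_true(all(c(nd$p_t, nd$p_fisher, nd$p_sw, nd$p_global) <= 1))
  # reproducible given the seed
  nd2 <- npde(fit, nsim = 300, seed = 89, y = yrep)
  expect_identical(nd$npde, nd2$npde)
})

test_that("NPDE detects a grossly misspecified model", {
  fit <- study_fit()
  biased <- fit
  biased$coefficients[["tvcl"]] <- 2 * biased$coefficients[["tvcl"]]
  # simulations now come from a model with doubled clearance: the
  # observed data are far outside the simulated distribution
  nd <- npde(biased, nsim = 200, seed = 90)
  expect_lt(nd$p_global, 0.01)
})

test_that("an identity bootstrap resample reproduces the original fit", {
  ds <- tiny_dataset()
  p <- pk_params()
  fit <- pkfit(ds, start = p,
               fix = c("theta_im", "theta_pm", "theta_cl_age",
                       "omega2_cl", "omega2_v"),
               control = pkfit_control(se = FALSE))
  # find a seed whose 2-subject resample is the identity
  seed_id <- NULL
  for (s in 1:200) {
    ok <- withr::with_seed(s, all(sample(ds$subjects$ID, 2,
                                         replace = TRUE) ==
                                    ds$subjects$ID))
    if (ok) { seed_id <- s; break }
  }
  expect_false(is.null(seed_id))
  bs <- bootstrap_pkfit(fit, n = 1, seed = seed_id)
  expect_equal(bs$n_failed, 0L)
  expect_equal(as.vector(bs$replicates[1, ]),
               as.vector(fit$coefficients[fit$free]), tolerance = 1e-3)
})

test_that("bootstrap summarises replicate spread around the estimates", {
  ds <- memo("boot_study", make_study(24, seed = 311))
  fit <- memo("boot_fit", pkfit(ds, control = pkfit_control(se = FALSE,
                                                            rel_tol = 1e-6)))
  bs <- bootstrap_pkfit(fit, n = 8, seed = 7)
  expect_equal(nrow(bs$replicates), 8)
  expect_lte(bs$n_failed, 2)
  sm <- bs$summary
  expect_true(all(sm$lower <= sm$median & sm$median <= sm$upper))
  # medians of the well-identified parameters sit near the estimates
  for (pn in c("tvcl", "sigma2_prop")) {
    row <- sm[sm$parameter == pn, ]
    expect_lt(abs(row$median / row$estimate - 1), 0.3)
  }
})
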