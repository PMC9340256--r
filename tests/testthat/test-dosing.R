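# Therapeutic-window classification and steady-state dosing simulation.

test_that("concentrations classify into the reference-range bands", {
  cls <- classify_concentration(c(0, 14.999, 15, 50, 80, 80.000001,
                                  159.9, 160, 500))
  expect_equal(as.character(cls),
               c("<15", "<15", "15-80", "15-80", "15-80", "80-160",
                 "80-160", ">=160", ">=160"))
  expect_error(classify_concentration(-1), ">= 0")
})

test_that("window reports count and percentage per band", {
  conc <- c(rep(5, 3), rep(40, 5), rep(100, 2))
  wr <- window_report(conc)
  expect_equal(wr$count, c(3, 5, 2, 0))
  expect_equal(wr$percent, c(30, 50, 20, 0))
  expect_equal(sum(wr$percent), 100)
  # one band only
  wr1 <- window_report(rep(42, 7))
  expect_equal(wr1$count, c(0, 7, 0, 0))
  expect_equal(wr1$percent[2], 100)
  # concatenation adds counts
  wr2 <- window_report(c(conc, rep(42, 7)))
  expect_equal(wr2$count, wr$count + wr1$count)
  expect_error(window_report(numeric(0)), "empty")
})

test_that("typical troughs order EM < IM < PM at any dose and age", {
  p <- pk_params()
  for (dose in c(5, 10, 15, 20)) {
    for (age in c(16, 45, 65)) {
      tr <- vapply(c("EM", "IM", "PM"), function(ph)
        simulate_typical_trough(p, age, ph, regimen(dose)), numeric(1))
      expect_true(all(diff(tr) > 0))
    }
  }
  # identity settings flatten all differences
  p0 <- pk_params(theta_age = 0, theta_im = 1, theta_pm = 1)
  tr0 <- c(simulate_typical_trough(p0, 16, "EM", regimen(10)),
           simulate_typical_trough(p0, 45, "IM", regimen(10)),
           simulate_typical_trough(p0, 80, "PM", regimen(10)))
  expect_equal(tr0[1], tr0[2])
  expect_equal(tr0[1], tr0[3])
})

test_that("population troughs collapse to the typical value without IIV", {
  p0 <- pk_params(omega2_cl = 0, omega2_v = 0)
  sim <- simulate_population_troughs(p0, 45, "EM", regimen(10),
                                     n_subjects = 50, seed = 1)
  expect_true(all(abs(sim$troughs - sim$typical) < 1e-10))
  # and the median converges to the typical trough as IIV shrinks
  p_small <- pk_params(omega2_cl = 1e-4, omega2_v = 1e-4)
  sim2 <- simulate_population_troughs(p_small, 45, "EM", regimen(10),
                                      n_subjects = 2000, seed = 2)
  expect_lt(abs(sim2$quantiles[["50%"]] / sim2$typical - 1), 0.02)
})

test_that("elderly PM exposure doubles that of elderly EM", {
  p <- pk_params()
  em <- simulate_population_troughs(p, 65, "EM", regimen(10),
                                    n_subjects = 2000, seed = 5)
  pm <- simulate_population_troughs(p, 65, "PM", regimen(10),
                                    n_subjects = 2000, seed = 6)
  expect_gte(pm$quantiles[["50%"]], 2 * em$quantiles[["50%"]])
})

test_that("population simulation is seed-stable and fully classified", {
  p <- pk_params()
  s1 <- simulate_population_troughs(p, 45, "IM", regimen(15),
                                    n_subjects = 500, seed = 9)
  s2 <- simulate_population_troughs(p, 45, "IM", regimen(15),
                                    n_subjects = 500, seed = 9)
  expect_identical(s1$troughs, s2$troughs)
  expect_equal(sum(s1$window_fraction), 1)
  # fraction-in-window stable across seeds at large n
  f1 <- simulate_population_troughs(p, 45, "IM", regimen(15),
                                    n_subjects = 10000,
                                    seed = 10)$window_fraction[2]
  f2 <- simulate_population_troughs(p, 45, "IM", regimen(15),
                                    n_subjects = 10000,
                                    seed = 11)$window_fraction[2]
  expect_lt(abs(f1 - f2), 0.02)
})

test_that("the trough table spans the regimen/age/phenotype grid", {
  tb <- trough_table(n_subjects = 300, seed = 3)
  expect_equal(nrow(tb), 4 * 3 * 3)
  expect_true(all(c("typical_trough", "p5", "p95",
                    "frac_window") %in% names(tb)))
  expect_true(all(tb$p5 <= tb$p95))
  expect_true(all(abs(tb$frac_below + tb$frac_window + tb$frac_high +
                        tb$frac_alert - 1) < 1e-9))
  # within each age/phenotype, troughs rise with dose
  for (age in unique(tb$age)) {
    for (ph in unique(tb$phenotype)) {
      sub <- tb[tb$age == age & tb$phenotype == ph, ]
      expect_true(all(diff(sub$typical_trough[order(sub$daily_dose)]) > 0))
    }
  }
})
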