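# Closed-form one-compartment kinetics: single dose, superposition,
# steady state.

test_that("single-dose concentration matches a numerical ODE solution", {
  skip_if_not_installed("deSolve")
  cl <- 16.3; v <- 815; ka <- 0.6; dose <- 10
  rhs <- function(t, A, p) {
    list(c(-ka * A[1], ka * A[1] - (cl / v) * A[2]))
  }
  tt <- c(1, 4, 12, 24, 48)
  out <- deSolve::lsoda(c(gut = dose, central = 0), c(0, tt), rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  ode_conc <- 1000 * out[-1, "central"] / v
  expect_equal(single_dose_concentration(tt, dose, cl, v, ka), ode_conc,
               tolerance = 1e-6)
})

test_that("single-dose concentration basics: zero at t = 0, linear in dose, decays", {
  expect_identical(single_dose_concentration(0, 10, 16.3, 815, 0.6), 0)
  tt <- seq(0.5, 96, by = 0.5)
  c1 <- single_dose_concentration(tt, 7, 16.3, 815, 0.6)
  expect_equal(single_dose_concentration(tt, 14, 16.3, 815, 0.6),
               2 * c1, tolerance = 1e-12)
  expect_true(all(c1 >= 0))
  expect_lt(single_dose_concentration(5000, 10, 16.3, 815, 0.6), 1e-6)
  expect_error(single_dose_concentration(-1, 10, 16.3, 815, 0.6),
               ">= 0")
})

test_that("equal absorption/elimination rates use the analytic limit", {
  # ka == ke exactly, and continuity against a nearby regular case
  v <- 100; ka <- 0.2; cl <- ka * v
  c_deg <- single_dose_concentration(6, 10, cl, v, ka)
  expect_equal(c_deg, 1000 * 10 / v * ka * 6 * exp(-ka * 6),
               tolerance = 1e-12)
  c_near <- single_dose_concentration(6, 10, cl * (1 + 1e-7), v, ka)
  expect_equal(c_deg, c_near, tolerance = 1e-5)
  # steady-state trough limit is continuous too
  s_deg <- steady_state_trough(10, 24, cl, v, ka)
  s_near <- steady_state_trough(10, 24, cl * (1 + 1e-7), v, ka)
  expect_equal(s_deg, s_near, tolerance = 1e-5)
})

test_that("profiles superpose linearly over the dosing history", {
  expect_equal(concentration_profile(numeric(0), numeric(0),
                                     c(1, 10, 20), 16.3, 815, 0.6),
               c(0, 0, 0))
  # two identical doses 24 h apart evaluated at 36 h
  both <- concentration_profile(c(0, 24), c(10, 10), 36, 16.3, 815, 0.6)
  expect_equal(both,
               single_dose_concentration(36, 10, 16.3, 815, 0.6) +
                 single_dose_concentration(12, 10, 16.3, 815, 0.6),
               tolerance = 1e-12)
  # scaling all doses scales the profile
  tt <- c(30, 50, 70)
  p1 <- concentration_profile(c(0, 24, 48), rep(5, 3), tt, 16.3, 815, 0.6)
  p3 <- concentration_profile(c(0, 24, 48), rep(15, 3), tt, 16.3, 815, 0.6)
  expect_equal(p3, 3 * p1, tolerance = 1e-12)
  expect_error(concentration_profile(0, 10, c(10, 5), 16.3, 815, 0.6),
               "sorted")
})

test_that("closed-form steady-state trough matches long superposition", {
  # >= 20 half-lives of repeated dosing across a parameter grid
  for (cl in c(7.808, 16.3, 25)) {
    for (v in c(600, 815, 1000)) {
      for (tau in c(12, 24)) {
        t_half <- log(2) / (cl / v)
        n_dose <- ceiling(25 * t_half / tau)
        sup <- concentration_profile((seq_len(n_dose) - 1) * tau,
                                     rep(10, n_dose), n_dose * tau,
                                     cl, v, 0.6)
        ss <- steady_state_trough(10, tau, cl, v, 0.6)
        expect_lt(abs(sup - ss) / ss, 0.001)
      }
    }
  }
})

test_that("steady-state trough is monotone in dose and clearance", {
  expect_equal(steady_state_trough(0, 24, 16.3, 815, 0.6), 0)
  doses <- c(5, 10, 15, 20)
  tr <- steady_state_trough(doses, 24, 16.3, 815, 0.6)
  expect_true(all(diff(tr) > 0))
  cls <- seq(5, 30, by = 5)
  trc <- vapply(cls, function(cl) steady_state_trough(10, 24, cl, 815, 0.6),
                numeric(1))
  expect_true(all(diff(trc) < 0))
  expect_error(steady_state_trough(10, 0, 16.3, 815, 0.6), "tau")
})

test_that("average steady-state concentration obeys the dose-rate identity", {
  # trapezoidal average over one steady-state interval equals
  # daily-dose-rate / CL for both qd and q12h at the same daily dose
  cl <- 16.3; v <- 815; ka <- 0.6
  avg_conc <- function(dose, tau) {
    t_half <- log(2) / (cl / v)
    n_dose <- ceiling(30 * t_half / tau)
    t0 <- (n_dose - 1) * tau
    tt <- seq(t0, t0 + tau, length.out = 201)
    prof <- concentration_profile((seq_len(n_dose) - 1) * tau,
                                  rep(dose, n_dose), tt, cl, v, ka)
    mean(prof[-1] + prof[-length(prof)]) / 2
  }
  expected <- 1000 * 20 / 24 / cl   # ng/ml
  expect_equal(avg_conc(20, 24), expected, tolerance = 0.005)
  expect_equal(avg_conc(10, 12), expected, tolerance = 0.005)
  # both troughs positive, bid trough above qd trough at equal daily dose
  expect_gt(steady_state_trough(10, 12, cl, v, ka),
            steady_state_trough(20, 24, cl, v, ka) * 0)
})
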