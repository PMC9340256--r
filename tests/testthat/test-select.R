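# Stepwise covariate search: threshold semantics, null behaviour, log
# audit. Study-scale selection power is exercised in the acceptance
# suite; here small cohorts keep the refits cheap.

sel_ctl <- function() pkfit_control(se = FALSE, rel_tol = 1e-6)

small_selection_study <- function() {
  memo("small_selection_study", make_study(40, seed = 301))
}

small_base_fit <- function() {
  memo("small_base_fit",
       pkfit(small_selection_study(), model = pk_model_spec(list()),
             control = sel_ctl()))
}

test_that("re-adding an included covariate contributes nothing", {
  fit <- memo("small_final_fit",
              pkfit(small_selection_study(), control = sel_ctl()))
  ev <- evaluate_candidate(fit, cov_phenotype())
  expect_equal(as.numeric(ev), 0)
  expect_equal(attr(ev, "reason"), "already included")
  ev2 <- evaluate_candidate(fit, cov_continuous("AGE", center = 45,
                                                decreasing = TRUE))
  expect_equal(as.numeric(ev2), 0)
})

test_that("adding the generating covariate lowers the objective", {
  base <- small_base_fit()
  ev <- evaluate_candidate(base, cov_phenotype(), control = sel_ctl())
  expect_gt(as.numeric(ev), 0)
  expect_equal(attr(ev, "df"), 2L)
})

test_that("degenerate thresholds reduce to the expected models", {
  ds <- small_selection_study()
  # no candidates: base returned unchanged
  sr0 <- forward_search(ds, base = small_base_fit(),
                        candidates = list(), control = sel_ctl())
  expect_length(sr0$included, 0)
  expect_equal(nrow(sr0$log), 0)
  # infinite forward threshold: base returned without candidate refits
  srInf <- forward_search(ds, base = small_base_fit(),
                          candidates = covariate_candidates(),
                          threshold_fwd = Inf, control = sel_ctl())
  expect_length(srInf$included, 0)
  expect_equal(nrow(srInf$log), 0)
  # infinite backward threshold: everything is eliminated down to base
  full <- memo("small_final_fit",
               pkfit(ds, control = sel_ctl()))
  be <- backward_elimination(ds, full, threshold_bwd = Inf,
                             control = sel_ctl())
  expect_length(be$included, 0)
})

test_that("a spurious covariate is removed by backward elimination", {
  ds <- small_selection_study()
  full <- pkfit(ds, model = pk_model_spec(list(
    cov_phenotype(), cov_categorical("SEX"))), control = sel_ctl())
  be <- backward_elimination(ds, full, control = sel_ctl())
  expect_false("cl:SEX" %in% be$included)
})

test_that("null-effect candidates behave like the chi-square reference", {
  # data generated without any SEX effect: delta OFV for the SEX
  # candidate is approximately chi-square(1)
  n_rep <- 20
  dofv <- numeric(n_rep)
  cfg <- cohort_config(n_subjects = 20)
  for (r in seq_len(n_rep)) {
    coh <- generate_cohort(cfg, seed = 500 + r)
    ds <- simulate_pkdata(coh, truth = pk_params(), config = cfg,
                          seed = 600 + r)
    base <- pkfit(ds, control = sel_ctl())
    ev <- evaluate_candidate(base, cov_categorical("SEX"),
                             control = sel_ctl())
    dofv[r] <- as.numeric(ev)
  }
  dofv <- dofv[!is.na(dofv)]
  expect_gt(length(dofv), n_rep * 0.7)
  expect_lte(mean(dofv > 6.63), 0.15)   # nominal 1%, Monte-Carlo slack
  expect_lt(median(dofv), 2.5)          # chi-square(1) median 0.455
  expect_gt(min(dofv), -0.5)            # nested fits: never truly negative
})

test_that("the search log replays to the final selection", {
  ds <- small_selection_study()
  cand <- covariate_candidates(continuous = "AGE", categorical = "SEX",
                               phenotype = TRUE)
  sr <- stepwise_covariates(ds, candidates = cand,
                            control = sel_ctl())
  # replay: apply the logged decisions mechanically
  fwd <- sr$log[sr$log$phase == "forward", ]
  included <- character()
  for (s in unique(fwd$step)) {
    rows <- fwd[fwd$step == s & !is.na(fwd$dofv), ]
    qual <- rows[rows$dofv > sr$threshold_fwd, ]
    if (nrow(qual)) included <- c(included,
                                  qual$candidate[which.max(qual$dofv)])
  }
  bwd <- sr$log[sr$log$phase == "backward", ]
  for (s in unique(bwd$step)) {
    rows <- bwd[bwd$step == s & !is.na(bwd$dofv), ]
    drop <- rows[rows$dofv < sr$threshold_bwd, ]
    if (nrow(drop)) included <- setdiff(included,
                                        drop$candidate[which.min(drop$dofv)])
  }
  expect_setequal(sr$included, included)
  # the log is written as a readable TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_search_log(sr, path)
  replay <- read.delim(path)
  expect_equal(nrow(replay), nrow(sr$log))
  expect_equal(replay$dofv, sr$log$dofv, tolerance = 1e-9)
})
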