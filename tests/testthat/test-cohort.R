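# Synthetic-cohort generator: genotype sampling, allele bookkeeping,
# cohort structure, and the generating model of the observations.

test_that("genotype sampling follows the requested frequencies", {
  degenerate <- c("*1/*1" = 1, "*1/*2" = 0, "*1/*3" = 0,
                  "*2/*2" = 0, "*2/*3" = 0)
  g <- sample_genotypes(50, degenerate, seed = 1)
  expect_true(all(g == "*1/*1"))
  expect_true(all(cyp2c19_phenotype(g) == "EM"))
  # large draw recovers the PM fraction implied by the defaults
  g2 <- sample_genotypes(1e5, seed = 7)
  pm_frac <- mean(cyp2c19_phenotype(g2) == "PM")
  expect_lt(abs(pm_frac - 0.0944), 0.003)
  # reproducibility
  expect_identical(sample_genotypes(100, seed = 3),
                   sample_genotypes(100, seed = 3))
  expect_error(sample_genotypes(10, c("*1/*1" = 0.5)), "named")
})

test_that("allele frequencies aggregate diplotype counts correctly", {
  counts <- c("*1/*1" = 47, "*1/*2" = 48, "*1/*3" = 1,
              "*2/*2" = 7, "*2/*3" = 3)
  af <- allele_frequencies(counts)
  expect_equal(af$count, c(143, 65, 4))
  expect_equal(af$percent, 100 * c(143, 65, 4) / 212, tolerance = 1e-12)
  one <- allele_frequencies(c("*1/*2" = 1))
  expect_equal(one$percent, c(50, 50, 0))
  expect_error(allele_frequencies(c("*4/*4" = 2)), "diplotypes")
  expect_error(allele_frequencies(c("*1/*1" = 0)), "all-zero")
})

test_that("generated cohorts honour the configured design", {
  coh <- generate_cohort(seed = 5)
  expect_equal(nrow(coh), 106)
  expect_true(all(coh$AGE >= 12 & coh$AGE <= 83))
  expect_true(all(coh$PHENOTYPE %in% c("EM", "IM", "PM")))
  expect_true(all(coh$PHENOTYPE == cyp2c19_phenotype(coh$CYP2C19)))
  expect_true(all(coh$DOSE * 24 / coh$TAU <= 30))
  expect_identical(generate_cohort(seed = 5), coh)
  expect_false(identical(generate_cohort(seed = 6), coh))
})

test_that("noise-free simulation reproduces the typical predictions", {
  truth <- pk_params(omega2_cl = 0, omega2_v = 0, sigma2_prop = 0)
  coh <- generate_cohort(cohort_config(n_subjects = 6), seed = 9)
  ds <- simulate_pkdata(coh, truth = truth, seed = 10,
                        config = cohort_config(n_subjects = 6))
  for (i in seq_len(nrow(ds$subjects))) {
    id <- ds$subjects$ID[i]
    obs <- ds$obs[ds$obs$ID == id, ]
    dd <- ds$doses[ds$doses$ID == id, ]
    ind <- individual_parameters(truth,
                                 list(age = ds$subjects$AGE[i],
                                      phenotype = ds$subjects$PHENOTYPE[i]))
    f <- concentration_profile(dd$TIME, dd$AMT, obs$TIME,
                               ind$cl_i, ind$v_i, truth$ka)
    expect_equal(obs$DV, f, tolerance = 0.005)  # DV rounded to 0.01
  }
})

test_that("the default design produces a study-sized dataset", {
  ds <- study_dataset()
  n_obs <- nrow(ds$obs)
  expect_equal(nrow(ds$subjects), 106)
  expect_gt(n_obs, 337 * 0.9)
  expect_lt(n_obs, 337 * 1.1)
  # invariants: ordered times, positive doses, >= 2 usable obs/subject
  expect_true(all(ds$doses$AMT > 0))
  used <- table(ds$obs$ID[!ds$obs$BLQ])
  expect_true(all(used >= 2))
  for (id in ds$subjects$ID[1:10]) {
    expect_false(is.unsorted(ds$obs$TIME[ds$obs$ID == id]))
    expect_gte(min(ds$obs$TIME[ds$obs$ID == id]),
               min(ds$doses$TIME[ds$doses$ID == id]))
  }
  # most observations fall within 2 h of the next scheduled dose
  tau_of <- vapply(split(ds$doses$TIME, ds$doses$ID),
                   function(tt) min(diff(sort(tt))), numeric(1))
  tad_frac <- mean(vapply(seq_len(nrow(ds$obs)), function(j) {
    tau <- tau_of[[as.character(ds$obs$ID[j])]]
    (ceiling(ds$obs$TIME[j] / tau) * tau - ds$obs$TIME[j]) <= 2
  }, logical(1)))
  expect_gt(tad_frac, 0.8)
})

test_that("simulated residual spread matches the proportional error model", {
  # large noise-only cohort: empirical CV of Y around f approximates
  # sqrt(sigma2_prop) ~ 17%
  truth <- pk_params(omega2_cl = 0, omega2_v = 0)
  cfg <- cohort_config(n_subjects = 250)
  coh <- generate_cohort(cfg, seed = 31)
  ds <- simulate_pkdata(coh, truth = truth, config = cfg, seed = 32)
  rel <- unlist(lapply(seq_len(nrow(ds$subjects)), function(i) {
    id <- ds$subjects$ID[i]
    obs <- ds$obs[ds$obs$ID == id, ]
    dd <- ds$doses[ds$doses$ID == id, ]
    ind <- individual_parameters(truth,
                                 list(age = ds$subjects$AGE[i],
                                      phenotype = ds$subjects$PHENOTYPE[i]))
    f <- concentration_profile(dd$TIME, dd$AMT, obs$TIME,
                               ind$cl_i, ind$v_i, truth$ka)
    obs$DV / f - 1
  }))
  expect_lt(abs(sd(rel) - sqrt(0.0287)), 0.015)
  expect_lt(abs(mean(rel)), 0.015)
})
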