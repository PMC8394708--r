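test_that("cohorts are reproducible from the seed and vary across seeds", {
  a <- generate_cohort(cohort_params(n_per_arm = 50, seed = 21))
  b <- generate_cohort(cohort_params(n_per_arm = 50, seed = 21))
  expect_identical(a, b)
  c <- generate_cohort(cohort_params(n_per_arm = 50, seed = 22))
  expect_false(identical(serialize(a, NULL), serialize(c, NULL)))
})

test_that("zero utility noise collapses to the stage means", {
  p <- cohort_params(n_per_arm = 100, utility_sd = 0,
                     allocation = "deterministic", seed = 1)
  cohort <- generate_cohort(p)
  gt2 <- cohort$utility[cohort$arm == "genetic_testing" & cohort$stage == "II"]
  expect_true(all(gt2 == 0.82))
  i4 <- cohort$utility[cohort$arm == "iFOBT" & cohort$stage == "IV"]
  expect_true(all(i4 == 0.11))
})

test_that("generated utilities and VAS respect their ranges", {
  cohort <- generate_cohort(cohort_params(n_per_arm = 500, seed = 8))
  expect_true(all(cohort$utility <= 1))
  expect_true(all(cohort$utility >= -1))
  expect_true(all(cohort$vas >= 0 & cohort$vas <= 100))
  lv <- as.matrix(cohort[, c("mo", "sc", "ua", "pd", "ad")])
  expect_true(all(lv %in% 1:5))
})

test_that("stage frequencies converge to the stage distribution", {
  p <- cohort_params(n_per_arm = 10000, seed = 31)
  cohort <- generate_cohort(p)
  for (arm in names(p$stage_probs)) {
    probs <- p$stage_probs[[arm]]
    counts <- table(factor(cohort$stage[cohort$arm == arm],
                           levels = c("I", "II", "III", "IV")))
    se <- sqrt(probs * (1 - probs) / p$n_per_arm)
    expect_true(all(abs(as.numeric(counts) / p$n_per_arm - probs) <= 3 * se))
  }
})

test_that("stage-mean calibration removes the truncation bias", {
  set.seed(13)
  cohort <- generate_cohort(cohort_params(n_per_arm = 20000, seed = 13))
  for (arm in c("iFOBT", "genetic_testing")) {
    means <- cohort_params()$utility_means[[arm]]
    for (k in seq_along(means)) {
      u <- cohort$utility[cohort$arm == arm &
                            cohort$stage == c("I", "II", "III", "IV")[k]]
      expect_lt(abs(mean(u) - means[k]), 0.02)
    }
  }
})

test_that("deterministic zero-noise cohorts recover the stage-table aggregates exactly", {
  p <- cohort_params(utility_sd = 0, allocation = "deterministic", seed = 2)
  cohort <- generate_cohort(p)
  surv <- with(fx$stage_tables$iFOBT, setNames(survival_mean, stage))
  for (arm in c("iFOBT", "genetic_testing")) {
    tab <- cohort_to_stage_table(cohort[cohort$arm == arm, ], surv)
    res <- stage_qalys(tab)
    ref <- stage_qalys(fx$stage_tables[[arm]])
    expect_equal(res$per_patient_ly, ref$per_patient_ly, tolerance = 1e-12)
    expect_equal(res$per_patient_qaly, ref$per_patient_qaly, tolerance = 1e-12)
  }
})

test_that("large stochastic cohorts recover per-patient QALYs within 2 percent", {
  p <- cohort_params(n_per_arm = 10000, seed = 17)
  cohort <- generate_cohort(p)
  surv <- with(fx$stage_tables$iFOBT, setNames(survival_mean, stage))
  for (arm in c("iFOBT", "genetic_testing")) {
    res <- stage_qalys(cohort_to_stage_table(cohort[cohort$arm == arm, ], surv))
    ref <- stage_qalys(fx$stage_tables[[arm]])
    expect_lt(abs(res$per_patient_qaly - ref$per_patient_qaly) /
                ref$per_patient_qaly, 0.02)
    expect_lt(abs(res$per_patient_ly - ref$per_patient_ly) /
                ref$per_patient_ly, 0.02)
  }
})

test_that("cohort aggregation validates arms and survival coverage", {
  cohort <- generate_cohort(cohort_params(n_per_arm = 10, seed = 4))
  surv <- c(I = 6.71, II = 6.51, III = 5.65, IV = 2.84)
  expect_error(cohort_to_stage_table(cohort, surv), "single arm")
  one <- cohort[cohort$arm == "iFOBT", ]
  expect_error(cohort_to_stage_table(one, surv[c("I", "II")]),
               "survival mean missing")
  # an absent stage carries n = 0 and an unused NA utility
  sub <- one[one$stage != "I", ]
  tab <- cohort_to_stage_table(sub, surv)
  expect_equal(tab$n[tab$stage == "I"], 0)
  expect_true(is.na(tab$utility_mean[tab$stage == "I"]))
})

test_that("synthetic cost ledgers stay non-negative and centre on the component means", {
  comp <- with(fx$cost_components[fx$cost_components$arm == "iFOBT", ],
               cost_components(name, category, method, amount, se))
  led <- generate_cost_ledger(2000, comp, seed = 6)
  expect_true(all(as.matrix(led[, comp$name]) >= 0))
  expect_equal(unname(colMeans(led[, comp$name])), comp$amount,
               tolerance = 0.05)
  expect_equal(led$total, rowSums(led[, comp$name]))
})

test_that("the bundled dataset loads with verified checksums and expected entries", {
  expect_s3_class(fx, "crc_fixture")
  gt <- fx$stage_tables$genetic_testing
  row2 <- gt[gt$stage == "II", ]
  expect_equal(row2$survival_mean, 6.51)
  expect_equal(row2$n, 60)
  expect_equal(row2$utility_mean, 0.82)
  expect_equal(gt$treatment_cost[gt$stage == "IV"], 6612.80)
  expect_equal(round(fx$cost_profiles$iFOBT$total, 2), 372.83)
  # corruption is caught by the manifest
  dir <- system.file("extdata", package = "ceascreen")
  tmp <- file.path(tempdir(), "extdata-corrupt")
  dir.create(tmp, showWarnings = FALSE)
  file.copy(list.files(dir, full.names = TRUE), tmp, overwrite = TRUE)
  cat("tampered\n", file = file.path(tmp, "stage_tables.csv"), append = TRUE)
  expect_error(load_crc_fixture(dir = tmp), "checksum")
})

test_that("invalid generator parameters are rejected", {
  expect_error(cohort_params(stage_probs = list(
    iFOBT = c(0.5, 0.5, 0.1, 0), genetic_testing = c(0.25, 0.25, 0.25, 0.25))),
    "summing to 1")
  expect_error(cohort_params(utility_sd = -1))
  p <- cohort_params(n_per_arm = 10, stage_probs = list(
    iFOBT = c(0.05, 0.05, 0.45, 0.45),
    genetic_testing = c(0.1, 0.6, 0.25, 0.05)),
    allocation = "deterministic")
  expect_error(generate_cohort(p), "integer")
})
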