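test_that("cohort tables honor the row-wise identity and reproduce by seed", {
  spec <- cohort_spec(seed = 5)
  co <- make_cohort_table(spec)
  expect_equal(nrow(co), 132)
  expect_equal(co$dV, co$dV_plus - co$dV_minus)  # exact
  expect_true(all(co$dV_minus >= 0 & co$dV_plus >= 0))
  expect_true(all(co$NRS >= 0 & co$NRS <= 10))
  expect_true(all(co$pain_relief_duration >= 0))
  expect_identical(make_cohort_table(spec), co)
  expect_false(identical(make_cohort_table(cohort_spec(seed = 6)), co))
})

test_that("stratum sizes and the bilateral structure match the design", {
  co <- make_cohort_table(cohort_spec(seed = 2))
  expect_equal(sum(co$erosion == "yes"), 90)
  expect_equal(sum(co$erosion == "no"), 42)
  ep <- co[co$erosion == "yes" & co$pain == "yes", ]
  expect_equal(nrow(ep), 65)
  bil <- table(ep$patient_id)
  expect_equal(sum(bil == 2), 10)   # planted bilateral erosion+pain patients
  expect_equal(sum(bil == 1), 45)
  # patient-level covariates are shared within a patient
  ag <- tapply(co$age, co$patient_id, function(x) diff(range(x)))
  expect_true(all(ag == 0))
})

test_that("configured stratum means are the actual means (law of large numbers)", {
  co <- make_cohort_table(cohort_spec(
    n_bilateral_pain_erosion = 0, n_unilateral_pain_erosion = 10000,
    n_erosion_nopain = 10, n_no_erosion = 10, seed = 31))
  x <- co$dV_minus[co$erosion == "yes" & co$pain == "yes"]
  se <- 135.54 / sqrt(length(x))
  expect_lt(abs(mean(x) - 111.74), 3 * se)
  y <- co$dV_plus[co$erosion == "yes" & co$pain == "yes"]
  expect_lt(abs(mean(y) - 39.02), 3 * 36.85 / sqrt(length(y)))
})

test_that("rank-correlation targets are realized through the copula", {
  tg <- default_correlation_targets()
  co <- make_cohort_table(cohort_spec(
    n_bilateral_pain_erosion = 0, n_unilateral_pain_erosion = 4000,
    n_erosion_nopain = 10, n_no_erosion = 10, seed = 13))
  s <- co[co$erosion == "yes" & co$pain == "yes", ]
  expect_equal(cor(s$pain_relief_duration, s$dV_minus, method = "spearman"),
               tg["relief", "dv_minus"], tolerance = 0.05)
  expect_equal(cor(s$CBCT_interval, s$dV_plus, method = "spearman"),
               tg["interval", "dv_plus"], tolerance = 0.05)
})

test_that("a target on the derived dV is realized within 0.05", {
  tg <- default_correlation_targets()
  tg2 <- rbind(cbind(tg, dv = 0), dv = 0)
  rownames(tg2) <- colnames(tg2) <- c(rownames(tg), "dv")
  tg2["relief", "dv"] <- tg2["dv", "relief"] <- -0.5
  co <- make_cohort_table(cohort_spec(
    n_bilateral_pain_erosion = 0, n_unilateral_pain_erosion = 2000,
    n_erosion_nopain = 10, n_no_erosion = 10,
    correlation_targets = tg2, seed = 11))
  s <- co[co$erosion == "yes" & co$pain == "yes", ]
  expect_equal(cor(s$pain_relief_duration, s$dV, method = "spearman"),
               -0.5, tolerance = 0.05)
})

test_that("invalid cohort specifications raise spec errors", {
  bad <- default_correlation_targets()
  bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(cohort_spec(correlation_targets = bad), "\\[-1, 1\\]")
  asym <- default_correlation_targets()
  asym[1, 2] <- 0.9
  expect_error(cohort_spec(correlation_targets = asym), "symmetric")
  sp <- default_strata_params()
  sp$dv_minus_mean[1] <- -5
  expect_error(cohort_spec(strata_params = sp), "positive")
})

test_that("cohort CSV round-trips", {
  co <- make_cohort_table(cohort_spec(seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  co2 <- read_cohort(f)
  expect_equal(nrow(co2), nrow(co))
  expect_equal(co2$dV, co$dV, tolerance = 1e-9)
})
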