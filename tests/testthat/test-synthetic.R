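test_that("cohorts follow the study design: 4 groups x 10 animals x 8 points", {
  co <- generate_cohort(calibrated_presets("GTT"), seed = 1)
  expect_length(co, 40)
  df <- cohort_to_df(co)
  expect_equal(nrow(df), 320)
  expect_equal(unname(table(df$group)), rep(80L, 4), ignore_attr = TRUE)
  expect_true(all(df$time_min %in% protocol_grid("GTT")))
  expect_true(all(df$glucose_mmol_per_l > 0))
})

test_that("noiseless, unjittered cohorts lie exactly on the truth curve", {
  pres <- calibrated_presets(n_animals = 2, noise_sd = 0)
  pres <- lapply(pres, function(p) { p$biphasic_fraction <- 0; p })
  co <- generate_cohort(pres, seed = 7, jitter = FALSE)
  for (s in co) {
    pre <- Filter(function(p) p$group == s$group && p$test == s$test, pres)[[1]]
    expect_identical(s$glucose, glucose_curve(pre$truth, s$times))
  }
})

test_that("generation is reproducible from the seed", {
  pres <- calibrated_presets("GTT", n_animals = 5)
  a <- generate_cohort(pres, seed = 42)
  b <- generate_cohort(pres, seed = 42)
  c <- generate_cohort(pres, seed = 43)
  expect_identical(cohort_to_df(a), cohort_to_df(b))
  expect_false(identical(cohort_to_df(a)$glucose_mmol_per_l,
                         cohort_to_df(c)$glucose_mmol_per_l))
})

test_that("generated glucose stays positive even under heavy noise", {
  pres <- lapply(calibrated_presets("ITT", n_animals = 20, noise_sd = 1.5),
                 function(p) { p$biphasic_fraction <- 0; p })
  df <- cohort_to_df(generate_cohort(pres, seed = 3))
  expect_true(all(df$glucose_mmol_per_l > 0))
  expect_true(all(is.finite(df$glucose_mmol_per_l)))
})

test_that("preset truths reproduce the group inflection-time anchors", {
  anchors <- c(young_male.GTT = 82.0, adult_male.GTT = 23.1,
               young_female.GTT = 44.3, adult_female.GTT = 19.6,
               young_male.ITT = 122.6, adult_male.ITT = 102.4,
               young_female.ITT = 135.7, adult_female.ITT = 91.5)
  for (pre in calibrated_presets()) {
    f <- extract_features(pre$truth, pre$test)
    expect_equal(f$t_I, unname(anchors[paste(pre$group, pre$test, sep = ".")]),
                 tolerance = 1e-6)
  }
})

test_that("young females dip into life-threatening hypoglycemia in ITT", {
  pre <- Filter(function(p) p$group == "young_female" && p$test == "ITT",
                calibrated_presets("ITT"))[[1]]
  f <- extract_features(pre$truth, "ITT")
  expect_lt(f$g_extremum, 2.2)
  expect_equal(classify_glycemia(f$g_extremum), "severe_hypo")
  # males stay above the severe-hypoglycemia threshold
  for (g in c("young_male", "adult_male")) {
    pre <- Filter(function(p) p$group == g, calibrated_presets("ITT"))[[1]]
    expect_gt(extract_features(pre$truth, "ITT")$g_extremum, 2.2)
  }
})

test_that("fitting noiseless cohorts recovers every preset truth", {
  pres <- lapply(calibrated_presets(n_animals = 1, noise_sd = 0),
                 function(p) { p$biphasic_fraction <- 0; p })
  co <- generate_cohort(pres, seed = 5, jitter = FALSE)
  for (i in seq_along(co)) {
    fit <- fit_glucose(co[[i]])
    truth <- pres[[i]]$truth
    rel <- abs(unlist(fit$params) - unlist(truth)) / abs(unlist(truth))
    expect_lt(max(rel), 1e-3)
  }
})

test_that("biphasic contaminants are two-peaked and mostly rejected by the gate", {
  pre <- group_preset("young_female", "GTT",
                      calibrated_presets("GTT")[[3]]$truth,
                      noise_sd = 0, biphasic_fraction = 1, n_animals = 6)
  co <- generate_cohort(pre, seed = 17)
  grid <- protocol_grid("GTT")
  for (s in co) {
    expect_true(isTRUE(attr(s, "biphasic")))
    y <- s$glucose
    # first peak at 15 min, dip, then a second elevation near 60 min
    expect_gt(y[grid == 15], y[grid == 30])
    expect_gt(y[grid == 60], y[grid == 30])
    expect_gt(y[grid == 15], y[1])
  }
  flagged <- vapply(co, function(s) !fit_glucose(s)$acceptable, logical(1))
  expect_gte(mean(flagged), 0.8)
})
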