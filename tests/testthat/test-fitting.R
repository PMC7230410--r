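test_that("noiseless curves are recovered to numerical precision", {
  truth <- model_params(0.03, 0.0012, 6, 5, 0.9)
  fit <- fit_glucose(make_series(truth))
  rel <- abs(unlist(fit$params) - unlist(truth)) / abs(unlist(truth))
  expect_lt(max(rel), 1e-4)
  expect_lt(fit$rss, 1e-10)
  expect_true(fit$converged)
  expect_true(fit$acceptable)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("constant series is an exact but non-identifiable degenerate fit", {
  g <- protocol_grid("GTT")
  s <- glucose_series("c1", "young_male", "GTT", g, rep(5, 8))
  fit <- fit_glucose(s)
  expect_equal(fit$rss, 0)
  expect_false(fit$acceptable)
  expect_match(fit$gate_notes, "non-identifiable")
  expect_equal(glucose_curve(fit$params, g), rep(5, 8))
  expect_equal(fit$params$mu, 5)
  expect_equal(fit$params$g_stab, 5)
  expect_equal(fit$params$nu, 0)
})

test_that("goodness of fit follows the residual-sum definitions", {
  truth <- model_params(0.03, 0.0012, 6, 5, 0.9)
  s <- make_series(truth)
  perfect <- goodness_of_fit(s, truth)
  expect_equal(perfect$rss, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$est_var, 0)

  set.seed(3)
  wrong <- model_params(0.05, 0.002, 5.5, 5.2, 0.5)
  g <- goodness_of_fit(s, wrong)
  # direct-summation oracle
  rss_hand <- sum((glucose_curve(wrong, s$times) - s$glucose)^2)
  expect_equal(g$rss, rss_hand, tolerance = 1e-10)
  expect_equal(g$r2, 1 - rss_hand / sum((s$glucose - mean(s$glucose))^2))
  expect_equal(g$est_var, g$rss / (length(s$times) - 5))  # m = 8 -> rss/3

  # zero-variance series with nonzero rss: r2 is a -Inf marker
  s0 <- glucose_series("z", "g", "GTT", protocol_grid("GTT"), rep(5, 8))
  expect_equal(goodness_of_fit(s0, wrong)$r2, -Inf)
})

test_that("adding starts never worsens the best residual", {
  set.seed(10)
  truth <- model_params(0.05, 0.004, 5.5, 5.5, 0.6)
  s <- make_series(truth, noise_sd = 0.3)
  few <- fit_glucose(s, fit_config(alpha_starts = c(0.02, 0.1),
                                   omega_ratio_starts = c(0.5, 2),
                                   n_random_starts = 0))
  more <- fit_glucose(s, fit_config(n_random_starts = 8))
  expect_lte(more$rss, few$rss + 1e-12)
})

test_that("fits are deterministic given series and config", {
  set.seed(20)
  s <- make_series(model_params(0.03, 0.0012, 6, 5, 0.9), noise_sd = 0.2)
  f1 <- fit_glucose(s, fit_config(seed = 5))
  f2 <- fit_glucose(s, fit_config(seed = 5))
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$rss, f2$rss)
})

test_that("acceptable noisy fits recover sign of nu and the stabilized level", {
  set.seed(30)
  n_ok <- 0; n_good <- 0
  for (i in 1:40) {
    truth <- random_valid_params(underdamped = i %% 2 == 0)
    s <- make_series(truth, noise_sd = 0.2)
    fit <- fit_glucose(s)
    if (!fit$acceptable) next
    n_ok <- n_ok + 1
    good <- sign(fit$params$nu) == sign(truth$nu) &&
      abs(fit$params$g_stab - truth$g_stab) < 1
    n_good <- n_good + good
  }
  expect_gt(n_ok, 20)
  expect_gte(n_good / n_ok, 0.9)
})

test_that("fitting rejects series that cannot identify five parameters", {
  s <- glucose_series("s", "g", "GTT", c(0, 15, 30, 45, 60),
                      c(5, 8, 9, 8, 6))
  expect_error(fit_glucose(s), "at least 6 points")
})

test_that("group mean curves are averaged on a shared grid", {
  pres <- calibrated_presets("GTT", n_animals = 4)
  pres <- Filter(function(p) p$biphasic_fraction == 0, pres)
  co <- generate_cohort(pres, seed = 9)
  m <- group_mean_series(co, group = "young_male", test = "GTT")
  ym <- Filter(function(s) s$group == "young_male", co)
  expect_equal(m$glucose,
               colMeans(do.call(rbind, lapply(ym, `[[`, "glucose"))))
  expect_error(group_mean_series(co, group = "no_such_group"), "no series")
})

test_that("exact runs-test null distribution sums to one and is symmetric", {
  for (n1 in 2:5) for (n2 in 2:5) {
    pmf <- glucodyn:::runs_null_pmf(n1, n2)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_true(all(pmf >= 0))
  }
  # perfectly alternating residuals reach the maximum runs count
  expect_false(glucodyn:::runs_extreme(c(1, -1, 1, -1), 0.05))
})
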