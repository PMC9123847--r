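# a fit with beta1 = 0 makes the surrogate prediction independent of the
# drawn baseline, so residuals are deterministic and easy to reason about
flat_fit <- fit_quiet(exact_pairs(c(3e-3, 0, -1e-4), n_subjects = 6))

baseline_pool <- data.frame(mouse_id = paste0("P", 1:10), age = 7,
                            delta = seq(2e-3, 4e-3, length.out = 10))

test_that("surrogate residuals honor the sign convention exactly", {
  pred <- predict_delta(flat_fit, 0, age_initial = 7, ivi = 3)
  targets <- data.frame(mouse_id = paste0("T", 1:4), age = 10, delta = pred)
  sr <- surrogate_residuals(targets, baseline_pool, flat_fit, seed = 1)
  expect_equal(sr$residual, rep(0, 4), tolerance = 1e-12)
  expect_equal(sr$ivi, rep(3, 4))
  # observations 0.001 below prediction give +0.001 residuals
  targets$delta <- pred - 1e-3
  sr2 <- surrogate_residuals(targets, baseline_pool, flat_fit, seed = 1)
  expect_equal(sr2$residual, rep(1e-3, 4), tolerance = 1e-12)
})

test_that("self-exclusion draws never pair a mouse with itself", {
  targets <- data.frame(mouse_id = paste0("P", 1:10), age = 10, delta = 3e-3)
  sr <- surrogate_residuals(targets, baseline_pool, flat_fit,
                            exclude_self = TRUE, seed = 2)
  expect_true(all(sr$baseline_mouse != sr$mouse_id))
  solo <- baseline_pool[1, , drop = FALSE]
  expect_error(surrogate_residuals(targets[1, ], solo, flat_fit,
                                   exclude_self = TRUE, seed = 1),
               "exhausted")
})

test_that("control-group residuals are centred near zero (self-consistency)", {
  ch <- small_mouse_cohort(seed = 11)
  fit <- fit_quiet(mouse_control_pairs(ch$visits), units = "weeks")
  pool <- ch$visits[ch$visits$group == "AS_control" & ch$visits$week == 2, ]
  w5 <- ch$visits[ch$visits$group == "AS_control" & ch$visits$week == 5, ]
  sr <- surrogate_residuals(w5, pool, fit, seed = 3)
  expect_lt(abs(median(sr$residual)), 4e-4)
})

test_that("per-week effects recover an injected additive treatment effect", {
  ch <- small_mouse_cohort(treatment_effect = 1e-3, seed = 21)
  fit <- fit_quiet(mouse_control_pairs(ch$visits), units = "weeks")
  eff <- treatment_effect_by_week(ch$visits, fit, n_resamples = 800,
                                  seed = 5)
  expect_equal(eff$week, 3:8)           # week 2 is the initial visit only
  expect_true(all(eff$ci_lo <= eff$ci_hi))
  expect_lt(abs(mean(eff$effect_mean) - 1e-3), 3e-4)
  # a week with no treated observations is skipped with a warning
  vv <- ch$visits[!(ch$visits$group == "AS_ASO" & ch$visits$week == 6), ]
  expect_warning(treatment_effect_by_week(vv, fit, n_resamples = 50,
                                          weeks = c(5, 6), seed = 1),
                 "week 6")
})

test_that("the permutation null is centred and detects a strong effect", {
  ch <- small_mouse_cohort(treatment_effect = 0, seed = 31)
  fit <- fit_quiet(mouse_control_pairs(ch$visits), units = "weeks")
  ob <- treatment_effect_by_week(ch$visits, fit, n_resamples = 400,
                                 weeks = 5, seed = 6)
  pn <- permutation_null(ch$visits, fit, n_resamples = 600, observed = ob,
                         weeks = 5, seed = 7)
  expect_lt(abs(mean(pn$null[, "5"])), 1e-4)   # exchangeability
  expect_gt(pn$p[["5"]], 0.01)

  # 5x residual-SD injected effect: overwhelmingly significant
  ch2 <- small_mouse_cohort(treatment_effect = 5 * 4.5e-4, seed = 32)
  fit2 <- fit_quiet(mouse_control_pairs(ch2$visits), units = "weeks")
  ob2 <- treatment_effect_by_week(ch2$visits, fit2, n_resamples = 400,
                                  weeks = 5, seed = 8)
  pn2 <- permutation_null(ch2$visits, fit2, n_resamples = 600,
                          observed = ob2, weeks = 5, seed = 9)
  expect_lt(pn2$p[["5"]], 0.01)
  # the distribution-vs-distribution t-test variant is available
  pn3 <- permutation_null(ch2$visits, fit2, n_resamples = 200,
                          observed = ob2, weeks = 5, seed = 10,
                          p_method = "t_test")
  expect_lt(pn3$p[["5"]], 1e-6)
})

test_that("results are reproducible and invariant to input row order", {
  ch <- small_mouse_cohort(seed = 41)
  fit <- fit_quiet(mouse_control_pairs(ch$visits), units = "weeks")
  e1 <- treatment_effect_by_week(ch$visits, fit, n_resamples = 200, seed = 4)
  shuffled <- ch$visits[sample(nrow(ch$visits)), ]
  e2 <- treatment_effect_by_week(shuffled, fit, n_resamples = 200, seed = 4)
  expect_equal(as.data.frame(e1), as.data.frame(e2))
  p1 <- permutation_null(ch$visits, fit, n_resamples = 100, weeks = 4,
                         seed = 5)
  p2 <- permutation_null(shuffled, fit, n_resamples = 100, weeks = 4,
                         seed = 5)
  expect_equal(p1$null, p2$null)
})

test_that("the cross-age contrast adjusts for the age/IVI drift", {
  ch <- small_mouse_cohort(treatment_effect = 1e-3, seed = 51)
  fit <- fit_quiet(mouse_control_pairs(ch$visits), units = "weeks")
  cc <- cross_age_contrast(ch$visits, fit, treated_week = 4,
                           control_week = 8, n_resamples = 500, seed = 11)
  # the effect is constant across weeks; the model recovers it despite the
  # age gap between the groups
  expect_lt(abs(cc$effect_mean - 1e-3), 4e-4)
  expect_lt(cc$p, 0.05)
  expect_true(is.finite(cc$p_naive_t))
  # same group, same week, against itself: no effect
  cc0 <- cross_age_contrast(ch$visits, fit, treated_week = 5,
                            control_week = 5,
                            treated_group = "AS_control",
                            control_group = "AS_control",
                            n_resamples = 300, seed = 12)
  expect_lt(abs(cc0$effect_mean), 1e-4)
})
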