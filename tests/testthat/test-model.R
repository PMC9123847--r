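test_that("pair construction follows the chosen policy", {
  v <- data.frame(subject_id = "m1", age = c(7, 8, 9), delta = c(1, 2, 3),
                  week = c(2, 3, 4))
  allp <- build_pairs(v, "all_combinations")
  expect_equal(nrow(allp), 3)
  expect_equal(sort(allp$ivi), c(1, 1, 2))
  expect_equal(allp$week_subsequent, c(3, 4, 4))

  v7 <- data.frame(subject_id = "m2", age = 7:13, delta = rnorm(7))
  expect_equal(nrow(build_pairs(v7, "all_combinations")), 21)
  expect_equal(nrow(build_pairs(v7, "consecutive")), 6)

  # singleton subjects contribute nothing; duplicate times are an error
  v2 <- rbind(v7, data.frame(subject_id = "solo", age = 5, delta = 0.1))
  expect_equal(nrow(build_pairs(v2, "consecutive")), 6)
  vdup <- data.frame(subject_id = "x", age = c(3, 3), delta = c(1, 2))
  expect_error(build_pairs(vdup), "duplicate")
})

test_that("noise-free data are recovered to numerical precision", {
  beta <- c(0.25, 0.43, -0.03)
  fit <- fit_quiet(exact_pairs(beta))
  expect_equal(unname(fit$beta), beta, tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-10)
  expect_equal(fit$sigma_b, 0, tolerance = 1e-6)
  # identity-map limit: beta1 = 1 passes delta through unchanged
  fit_id <- fit_quiet(exact_pairs(c(0, 1, 0)))
  p <- predict_delta(fit_id, 0.37, age_initial = 5, ivi = 2)
  expect_equal(p, 0.37, tolerance = 1e-8)
})

test_that("predictions are arithmetic in the fitted coefficients", {
  fit <- fit_quiet(exact_pairs(c(0.25, 0.43, -0.03)))
  # 0.25 + 0.43*0.5 - 0.03*log10(10)*1 = 0.435
  expect_equal(predict_delta(fit, 0.5, 10, 1), 0.435, tolerance = 1e-8)
  # ivi = 0 removes the age term entirely
  expect_equal(predict_delta(fit, 0.5, 2, 0),
               predict_delta(fit, 0.5, 30, 0), tolerance = 1e-10)
  # affine in delta_initial with slope beta1
  d <- seq(0.1, 0.9, by = 0.2)
  p <- predict_delta(fit, d, 10, 1)
  expect_equal(unname(diff(p) / diff(d)), rep(fit$beta[[2]], 4),
               tolerance = 1e-8)
  expect_error(predict_delta(fit, 0.5, -1, 1))
  expect_error(predict_delta(fit, 0.5, 10, 1, subject = "nope"), "unknown")
})

test_that("residuals use the predicted-minus-observed sign convention", {
  fit <- fit_quiet(exact_pairs(c(0.25, 0.43, -0.03)))
  pr <- data.frame(subject_id = "S1", delta_initial = 0.5,
                   delta_subsequent = 0.335, age_initial = 10, ivi = 1)
  # prediction is 0.435; a treatment-lowered observation gives +0.10
  expect_equal(residual_delta(fit, pr), 0.1, tolerance = 1e-8)
  pr$delta_subsequent <- 0.435
  expect_equal(residual_delta(fit, pr), 0, tolerance = 1e-8)
})

test_that("stochastic recovery is unbiased and the Table-like sign pattern holds", {
  fits <- lapply(1:40, function(s)
    fit_quiet(make_human_cohort(seed = 4000 + s)$pairs))
  B <- vapply(fits, function(f) f$beta, numeric(3))
  m <- rowMeans(B); se3 <- 3 * apply(B, 1, sd) / sqrt(ncol(B))
  truth <- c(0.25, 0.43, -0.03)
  expect_true(all(abs(m - truth) < se3))
  # delta-initial slope positive, age:IVI slope negative, essentially always
  expect_gte(mean(B[2, ] > 0 & B[3, ] < 0), 0.95)
  # variance components are recovered too
  expect_equal(mean(vapply(fits, `[[`, 1, "sigma_e")), 0.09,
               tolerance = 0.02)
})

test_that("a spurious genotype covariate does not improve model fit", {
  # cohorts generated WITHOUT genotype effects: adding a random genotype
  # factor should move AIC by less than 2 in most replicates
  delta_aic <- vapply(1:15, function(s) {
    ch <- make_human_cohort(seed = 6000 + s)
    p <- ch$pairs
    set.seed(s)
    geno <- sample(c("deletion", "other"),
                   length(unique(p$subject_id)), replace = TRUE)
    p$genotype <- geno[match(p$subject_id, unique(p$subject_id))]
    d <- data.frame(y = p$delta_subsequent, di = p$delta_initial,
                    x = log10(p$age_initial) * p$ivi,
                    g = factor(p$genotype), subject = factor(p$subject_id))
    f0 <- lme4::lmer(y ~ di + x + (1 | subject), data = d, REML = FALSE)
    f1 <- lme4::lmer(y ~ di + x + g + (1 | subject), data = d, REML = FALSE)
    abs(AIC(f1) - AIC(f0))
  }, numeric(1))
  expect_gte(mean(delta_aic < 2), 0.6)
})

test_that("cross-validation pools population-level fold residuals", {
  # noise-free: every fold predicts perfectly
  cv0 <- suppressWarnings(cross_validate(exact_pairs(c(0.2, 0.5, -0.02),
                                                     n_subjects = 8)))
  expect_lt(cv0$rmse, 1e-8)

  # sigma_e recovery and the optimism property, on replicate cohorts
  reps <- lapply(1:6, function(s) {
    ch <- make_human_cohort(seed = 7000 + s)
    suppressWarnings(cross_validate(ch$pairs))
  })
  cv_rmse <- vapply(reps, `[[`, 1, "rmse")
  in_rmse <- vapply(reps, `[[`, 1, "in_sample_rmse")
  expect_lt(abs(mean(cv_rmse) - sqrt(0.09^2 + 0.05^2)), 0.01)
  expect_gt(mean(cv_rmse - in_rmse), 0)

  # leave-one-week-out needs the week column; works on mouse pairs
  ch <- small_mouse_cohort(seed = 3)
  mp <- mouse_control_pairs(ch$visits)
  cvw <- cross_validate(mp, scheme = "week")
  expect_equal(sort(cvw$per_fold$fold), as.character(3:8))
  expect_gt(cvw$rmse, 0)
  expect_error(cross_validate(ch$visits, scheme = "week"))
})

test_that("degenerate designs are rejected with diagnostics", {
  p <- exact_pairs(c(0.2, 0.5, -0.02))
  p$delta_initial <- 0.5  # constant regressor, collinear with intercept
  expect_error(fit_natural_history(p), "singular")
  expect_error(fit_natural_history(p[1:2, ]), "subjects|pairs")
})
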