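test_that("all generators are deterministic under a fixed seed", {
  expect_identical(make_synthetic_eeg(0.5, 10, 200, 2, seed = 9)$samples,
                   make_synthetic_eeg(0.5, 10, 200, 2, seed = 9)$samples)
  h1 <- make_human_cohort(seed = 5); h2 <- make_human_cohort(seed = 5)
  expect_identical(h1$pairs, h2$pairs)
  m1 <- make_mouse_cohort(seed = 5); m2 <- make_mouse_cohort(seed = 5)
  expect_identical(m1$visits, m2$visits)
  ids <- unique(m1$visits$mouse_id)[1:6]
  expect_identical(make_expression(m1$visits, ids, seed = 2),
                   make_expression(m1$visits, ids, seed = 2))
})

test_that("synthetic EEG hits its programmed relative delta power", {
  for (r in c(0.2, 0.5, 0.8)) {
    rec <- make_synthetic_eeg(r, seed = round(1000 * r))
    est <- relative_delta_power(rereference_average(rec))
    expect_lt(abs(est$value - r), 3 * est$sem)
  }
  # near-total delta concentration is reachable
  rec1 <- make_synthetic_eeg(0.97, duration_s = 30, seed = 1)
  expect_gt(relative_delta_power(rec1)$value, 0.9)
  expect_error(make_synthetic_eeg(0.004), "infeasible")
  expect_error(make_synthetic_eeg(1.2))
})

test_that("the human cohort reproduces its design and generating equation", {
  ch <- make_human_cohort(seed = 10)
  expect_equal(nrow(ch$visits), 204)
  expect_equal(length(unique(ch$visits$subject_id)), 56)
  expect_equal(nrow(ch$pairs), 204 - 56)
  expect_true(all(ch$visits$delta >= 0 & ch$visits$delta <= 1))
  expect_true(all(table(ch$visits$subject_id) >= 2))
  expect_true(all(table(ch$visits$subject_id) <= 13))
  expect_true(all(ch$pairs$ivi > 0))

  # clipping is rare under the default spec
  clips <- vapply(1:20, function(s)
    make_human_cohort(seed = 200 + s)$truth$n_clipped, numeric(1))
  expect_lt(sum(clips) / (20 * 204), 0.01)

  # noise-free generation satisfies the generating equation exactly
  sp0 <- human_cohort_spec(sigma_b = 0, sigma_e = 0)
  ch0 <- make_human_cohort(sp0, seed = 3)
  p <- ch0$pairs
  lhs <- p$delta_subsequent
  rhs <- 0.25 + 0.43 * p$delta_initial - 0.03 * log10(p$age_initial) * p$ivi
  expect_equal(lhs, pmin(pmax(rhs, 0), 1), tolerance = 1e-12)
})

test_that("doubling the residual SD doubles the cross-validated RMSE", {
  rmse_at <- function(sig) {
    mean(vapply(1:4, function(s) {
      ch <- make_human_cohort(human_cohort_spec(sigma_b = 0, sigma_e = sig),
                              seed = 300 + s)
      suppressWarnings(cross_validate(ch$pairs))$rmse
    }, numeric(1)))
  }
  expect_equal(rmse_at(0.10) / rmse_at(0.05), 2, tolerance = 0.15)
})

test_that("the mouse cohort reproduces the published pairing design", {
  ch <- make_mouse_cohort(seed = 20)
  tab <- table(unique(ch$visits[, c("mouse_id", "group")])$group)
  expect_equal(as.integer(tab[c("WT_control", "AS_control", "AS_ASO")]),
               c(28, 26, 15))
  mp <- mouse_control_pairs(ch$visits)
  expect_equal(nrow(mp), 401)
  per_mouse <- table(mp$subject_id)
  expect_equal(range(per_mouse), c(6, 21))
  expect_true(all(ch$visits$delta > 0))
  expect_true(all(ch$visits$age == ch$visits$week + 5))
  # treated mice sit treatment_effect below the control trajectory
  mu <- ch$truth$mu
  w5 <- ch$visits[ch$visits$week == 5, ]
  gap <- mean(w5$delta[w5$group == "AS_control"]) -
    mean(w5$delta[w5$group == "AS_ASO"])
  expect_lt(abs(gap - ch$truth$treatment_effect), 4e-4)
  # wild-type sits below AS controls
  expect_lt(mean(w5$delta[w5$group == "WT_control"]),
            mean(w5$delta[w5$group == "AS_control"]))
})

test_that("the solved mouse trajectory is self-consistent for the estimand", {
  sp <- mouse_cohort_spec()
  mu <- deltatrack:::solve_mouse_trajectory(sp)
  expect_true(all(mu > 0))
  expect_equal(length(mu), 7)
  # with the noise terms switched off, the plain OLS moments of the solved
  # trajectory match the generating coefficients exactly
  sp0 <- mouse_cohort_spec(sigma_b = 0, sigma_e = 0)
  mu0 <- deltatrack:::solve_mouse_trajectory(sp0)
  idx <- do.call(rbind, lapply(sp0$control_visit_counts, function(nv) {
    cmb <- combn(nv, 2); cbind(cmb[1, ], cmb[2, ])
  }))
  ages <- sp0$weeks + 5
  X <- cbind(1, mu0[idx[, 1]],
             log10(ages[idx[, 1]]) * (ages[idx[, 2]] - ages[idx[, 1]]))
  est <- qr.solve(X, mu0[idx[, 2]])
  expect_equal(unname(est), sp0$beta, tolerance = 1e-6)
})

test_that("expression generation couples to the injected deviation", {
  ch <- make_mouse_cohort(seed = 30)
  w7 <- ch$visits[ch$visits$week == 7, ]
  ids <- c(head(w7$mouse_id[w7$group == "AS_control"], 8),
           head(w7$mouse_id[w7$group == "AS_ASO"], 4))
  ex <- make_expression(ch$visits, ids, treatment_effect = 1e-3,
                        noise_sd = 0, seed = 4)
  expect_equal(ex$mrna_relative[ex$group == "AS_control"], rep(0.22, 8))
  expect_equal(ex$mrna_relative[ex$group == "AS_ASO"],
               rep(0.22 + 280 * 1e-3, 4))
  expect_error(make_expression(ch$visits, "nope", seed = 1), "nope")
})
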