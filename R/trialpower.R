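#' Simulate one two-arm comparison with an injected treatment effect
#'
#' Samples `n_per_group` longitudinal pairs with replacement from the pool
#' for each arm, subtracts `offset` from the treatment arm's
#' delta-at-subsequent-visit (clamping at 0, counted -- relative power cannot
#' be negative), computes population-level residuals (predicted minus
#' observed) under the FIXED pre-fitted natural-history model, and compares
#' arms with a one-sided Welch t-test (H1: treatment residuals exceed
#' control residuals).
#'
#' @param pairs pool of longitudinal pairs.
#' @param fit an `nh_fit` estimated once on the untreated pool (the model is
#'   the instrument and is not refit per simulation).
#' @param n_per_group subjects per arm.
#' @param offset injected reduction in relative delta power (>= 0).
#' @param alpha significance level (default 0.05).
#' @param seed optional integer seed.
#' @return list: `p`, `effect` (difference in mean residuals), `n_clamped`.
#' @export
simulate_two_arm <- function(pairs, fit, n_per_group, offset, alpha = 0.05,
                             seed = NULL) {
  stopifnot(offset >= 0, n_per_group >= 2)
  validate_pairs(pairs)
  if (!is.null(seed)) set.seed(seed)
  res <- residual_delta(fit, pairs, mode = "population")
  obs <- pairs$delta_subsequent
  ic <- sample.int(nrow(pairs), n_per_group, replace = TRUE)
  it <- sample.int(nrow(pairs), n_per_group, replace = TRUE)
  rc <- res[ic]
  clamped <- offset > obs[it]
  rt <- res[it] + ifelse(clamped, obs[it], offset)
  tst <- stats::t.test(rt, rc, alternative = "greater")
  list(p = tst$p.value, effect = mean(rt) - mean(rc),
       n_clamped = sum(clamped), alpha = alpha,
       significant = tst$p.value < alpha)
}

welch_p_greater <- function(mt, vt, mc, vc, n) {
  se2t <- vt / n; se2c <- vc / n
  tstat <- (mt - mc) / sqrt(se2t + se2c)
  df <- (se2t + se2c)^2 / (se2t^2 / (n - 1) + se2c^2 / (n - 1))
  stats::pt(tstat, df, lower.tail = FALSE)
}

#' Power surface over treatment offsets and group sizes
#'
#' For every (offset, group size) cell, repeats [simulate_two_arm()]'s
#' resampling `n_sims` times (vectorized) and reports the fraction of
#' simulations with one-sided p below `alpha`, plus the smallest grid offset
#' reaching 80% power per group size. The default grid spans offsets 0-0.1
#' in steps of 0.002 and group sizes 25/50/100/150.
#'
#' @param pairs pool of longitudinal pairs.
#' @param fit the fixed `nh_fit`.
#' @param offsets grid of injected reductions.
#' @param group_sizes subjects per arm.
#' @param n_sims simulations per cell (default 2000).
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @return a `power_curve`: data frame (`offset`, `n_per_group`, `power`,
#'   `mean_effect`, `n_clamped`) with attributes `alpha`, `n_sims`,
#'   `thresholds_80` (named by group size).
#' @export
power_curve <- function(pairs, fit, offsets = seq(0, 0.1, by = 0.002),
                        group_sizes = c(25, 50, 100, 150), n_sims = 2000,
                        alpha = 0.05, seed = NULL) {
  validate_pairs(pairs)
  stopifnot(all(offsets >= 0), n_sims >= 2)
  if (!is.null(seed)) set.seed(seed)
  res <- residual_delta(fit, pairs, mode = "population")
  obs <- pairs$delta_subsequent
  npool <- nrow(pairs)
  out <- list()
  for (n in group_sizes) {
    IC <- matrix(sample.int(npool, n * n_sims, TRUE), nrow = n)
    IT <- matrix(sample.int(npool, n * n_sims, TRUE), nrow = n)
    RC <- matrix(res[IC], nrow = n)
    RT0 <- matrix(res[IT], nrow = n)
    OT <- matrix(obs[IT], nrow = n)
    mc <- colMeans(RC)
    vc <- colMeans(RC^2) - mc^2
    vc <- vc * n / (n - 1)
    for (off in offsets) {
      add <- pmin(OT, off)
      RT <- RT0 + add
      mt <- colMeans(RT)
      vt <- (colMeans(RT^2) - mt^2) * n / (n - 1)
      p <- welch_p_greater(mt, vt, mc, vc, n)
      out[[length(out) + 1L]] <- data.frame(
        offset = off, n_per_group = n, power = mean(p < alpha),
        mean_effect = mean(mt - mc), n_clamped = sum(add < off))
    }
  }
  df <- do.call(rbind, out)
  thr <- vapply(group_sizes, function(n) {
    sub <- df[df$n_per_group == n, ]
    hit <- sub$offset[sub$power >= 0.8]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  attr(df, "alpha") <- alpha
  attr(df, "n_sims") <- n_sims
  attr(df, "thresholds_80") <- stats::setNames(thr, group_sizes)
  class(df) <- c("power_curve", "data.frame")
  df
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("<power_curve> alpha=%.3g, %d sims/cell\n",
              attr(x, "alpha"), attr(x, "n_sims")))
  thr <- attr(x, "thresholds_80")
  cat("smallest offset with power >= 0.8, per group size:\n")
  for (nm in names(thr))
    cat(sprintf("  n=%s: %s\n", nm,
                ifelse(is.na(thr[nm]), "not reached", format(thr[nm]))))
  invisible(x)
}
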