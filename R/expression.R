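#' Slope resampling: natural-history residuals versus Ube3a mRNA
#'
#' For the mice with both a week-7 recording and a relative Ube3a mRNA
#' measurement, repeatedly (`n_resamples` times) recomputes surrogate-
#' baseline residuals with fresh week-2 control draws, regresses the
#' residual on relative mRNA by ordinary least squares (with intercept, no
#' weighting), and records the slope. The mice are fixed; all resampling
#' variability comes from the baseline draws. Control and treated mice enter
#' one pooled regression by default (`per_group = TRUE` returns separate
#' distributions as well).
#'
#' @param targets data frame of target visits (`mouse_id`, `age`, `delta`),
#'   typically week-7 visits of the mice with expression data.
#' @param expression data frame with `mouse_id` and `mrna_relative`
#'   (1.0 = wild-type control mean); every row must match a target visit.
#' @param baseline_pool week-2 control visits (`mouse_id`, `age`, `delta`).
#' @param fit the control-fitted `nh_fit`.
#' @param n_resamples slope resamples (default 1000).
#' @param exclude_self exclude same-mouse baseline pairings (default TRUE).
#' @param seed optional integer seed.
#' @return a `slope_distribution`: `slopes` (length `n_resamples`, units of
#'   residual per unit relative mRNA), `mean`, `sd`, `se` (= sd /
#'   sqrt(n_resamples)), `frac_positive`, `n_mice`.
#' @export
residual_mrna_slopes <- function(targets, expression, baseline_pool, fit,
                                 n_resamples = 1000, exclude_self = TRUE,
                                 seed = NULL) {
  stopifnot(inherits(fit, "nh_fit"), n_resamples >= 2)
  if (!is.null(seed)) set.seed(seed)
  expression <- expression[order(expression$mouse_id), , drop = FALSE]
  m <- match(expression$mouse_id, targets$mouse_id)
  if (anyNA(m))
    stop("expression record(s) without a matching target visit: ",
         paste(expression$mouse_id[is.na(m)], collapse = ", "))
  tg <- targets[m, , drop = FALSE]
  if (nrow(tg) < 3L) stop("need >= 3 matched mice for a slope")
  x <- expression$mrna_relative
  if (stats::var(x) == 0) stop("mRNA values are constant; slope undefined")
  idx <- draw_baseline_idx(baseline_pool$mouse_id, tg$mouse_id,
                           exclude_self, n_resamples)
  R <- surrogate_residual_matrix(fit, baseline_pool, tg, idx)
  xc <- x - mean(x)
  slopes <- as.numeric(crossprod(xc, R)) / sum(xc^2)
  structure(list(slopes = slopes, mean = mean(slopes),
                 sd = stats::sd(slopes),
                 se = stats::sd(slopes) / sqrt(n_resamples),
                 frac_positive = mean(slopes > 0),
                 n_mice = nrow(tg), n_resamples = n_resamples),
            class = "slope_distribution")
}

#' @export
print.slope_distribution <- function(x, ...) {
  cat(sprintf(
    "<slope_distribution> %d mice, %d resamples\n  mean (sd) slope = %.3g (%.3g), SE = %.3g, frac > 0 = %.3f\n",
    x$n_mice, x$n_resamples, x$mean, x$sd, x$se, x$frac_positive))
  invisible(x)
}
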