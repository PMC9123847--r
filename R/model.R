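#' Build longitudinal pairs from a visit table
#'
#' Turns per-subject visit sequences into longitudinal (initial, subsequent)
#' pairs. `consecutive` pairs each visit with the next; `all_combinations`
#' forms every ordered pair of visits `(i, j)`, `i < j` -- the all-pairs
#' scheme used for weekly mouse cohorts (a mouse with 7 weekly visits yields
#' 21 pairs). The inter-visit interval is the difference of the ages, in
#' whatever unit `age` carries (years for humans, weeks for mice).
#'
#' @param visits data frame with columns `subject_id`, `age`, `delta`, and
#'   optionally `group` and `week`; visits need not be pre-sorted. Subjects
#'   with a single visit contribute nothing.
#' @param policy `"consecutive"` or `"all_combinations"`.
#' @return data frame of pairs: `subject_id`, `delta_initial`,
#'   `delta_subsequent`, `age_initial`, `ivi`, `age_subsequent` (and
#'   `week_initial`/`week_subsequent` when `week` is present).
#' @export
build_pairs <- function(visits, policy = c("consecutive", "all_combinations")) {
  policy <- match.arg(policy)
  need <- c("subject_id", "age", "delta")
  if (!all(need %in% names(visits)))
    stop("visits must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(visits$age > 0), all(is.finite(visits$delta)))
  out <- lapply(split(visits, visits$subject_id), function(v) {
    v <- v[order(v$age), , drop = FALSE]
    if (anyDuplicated(v$age))
      stop("duplicate same-time visits for subject ", v$subject_id[1])
    n <- nrow(v)
    if (n < 2L) return(NULL)
    if (policy == "consecutive") {
      i <- seq_len(n - 1L); j <- i + 1L
    } else {
      cmb <- utils::combn(n, 2L)
      i <- cmb[1L, ]; j <- cmb[2L, ]
    }
    p <- data.frame(subject_id = v$subject_id[i],
                    delta_initial = v$delta[i],
                    delta_subsequent = v$delta[j],
                    age_initial = v$age[i],
                    ivi = v$age[j] - v$age[i],
                    age_subsequent = v$age[j])
    if ("week" %in% names(v)) {
      p$week_initial <- v$week[i]
      p$week_subsequent <- v$week[j]
    }
    p
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

validate_pairs <- function(pairs) {
  need <- c("subject_id", "delta_initial", "delta_subsequent",
            "age_initial", "ivi")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(pairs$ivi > 0), all(pairs$age_initial > 0),
            all(is.finite(pairs$delta_initial)),
            all(is.finite(pairs$delta_subsequent)))
  invisible(pairs)
}

#' Fit the natural-history model of delta power
#'
#' Fits, by maximum likelihood, the random-intercept model
#' \deqn{\delta_{subsequent} = \beta_0 + \beta_1 \delta_{initial} +
#'   \beta_2 \log_{10}(age_{initial}) \cdot IVI + b_{subject} + \epsilon}
#' with \eqn{b \sim N(0, \sigma_b^2)} and \eqn{\epsilon \sim N(0,
#' \sigma_e^2)}. Inference on the fixed effects uses Wald t-tests with
#' residual degrees of freedom (`n_pairs - 4`); Satterthwaite degrees of
#' freedom are available via `df_method = "satterthwaite"` (requires
#' lmerTest). RMSE is computed on population-level residuals (random
#' intercept set to zero).
#'
#' Should the mixed fit fail (e.g. noise-free data with a degenerate residual
#' variance), the model falls back to ordinary least squares with
#' `sigma_b = 0`, which is exact in that limit.
#'
#' @param pairs data frame of longitudinal pairs (see [build_pairs()]).
#' @param method `"ML"` (default, mirroring the original analysis) or
#'   `"REML"`.
#' @param df_method `"residual"` (default) or `"satterthwaite"`.
#' @param units time unit of `age_initial`/`ivi`, echoed in outputs.
#' @return an object of class `nh_fit`: coefficient table (estimate, SE, df,
#'   t, p, 95% CI), `sigma_b`, `sigma_e`, `rmse`, `aic`, `n_pairs`,
#'   `n_subjects`, empirical-Bayes intercepts (`ranef`).
#' @export
fit_natural_history <- function(pairs, method = c("ML", "REML"),
                                df_method = c("residual", "satterthwaite"),
                                units = "years") {
  method <- match.arg(method)
  df_method <- match.arg(df_method)
  validate_pairs(pairs)
  if (length(unique(pairs$subject_id)) < 2L)
    stop("need >= 2 subjects")
  if (nrow(pairs) < 3L) stop("need >= 3 pairs")
  d <- data.frame(y = pairs$delta_subsequent,
                  di = pairs$delta_initial,
                  x = log10(pairs$age_initial) * pairs$ivi,
                  subject = factor(pairs$subject_id))
  if (qr(cbind(1, d$di, d$x))$rank < 3L)
    stop("singular design: delta_initial and log10(age):IVI are collinear ",
         "or constant")
  ctrl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    calc.derivs = FALSE)
  fitter <- if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE))
      stop("df_method = 'satterthwaite' requires the lmerTest package")
    lmerTest::lmer
  } else lme4::lmer
  df_res <- nrow(d) - 4
  extracted <- tryCatch({
    fm <- suppressMessages(
      suppressWarnings(fitter(y ~ di + x + (1 | subject), data = d,
                              REML = (method == "REML"), control = ctrl)))
    se <- sqrt(diag(as.matrix(stats::vcov(fm))))
    if (anyNA(se)) stop("degenerate variance-covariance matrix")
    vc <- as.data.frame(lme4::VarCorr(fm))
    re_df <- lme4::ranef(fm)$subject
    list(beta = lme4::fixef(fm), se = se,
         sigma_b = vc$sdcor[vc$grp == "subject"],
         sigma_e = vc$sdcor[vc$grp == "Residual"],
         re = stats::setNames(re_df[["(Intercept)"]], rownames(re_df)),
         aic = stats::AIC(fm), note = NULL,
         dfs = if (df_method == "satterthwaite")
           stats::coef(summary(fm))[, "df"] else rep(df_res, 3L))
  }, error = function(e) {
    # degenerate (e.g. noise-free) data: OLS limit with sigma_b = 0
    lm0 <- stats::lm(y ~ di + x, data = d)
    list(beta = stats::coef(lm0), se = sqrt(diag(stats::vcov(lm0))),
         sigma_b = 0, sigma_e = stats::sigma(lm0),
         re = stats::setNames(rep(0, nlevels(d$subject)),
                              levels(d$subject)),
         aic = stats::AIC(lm0),
         note = paste("mixed fit unavailable; ordinary least squares",
                      "fallback:", conditionMessage(e)),
         dfs = rep(df_res, 3L))
  })
  beta <- extracted$beta; se <- extracted$se
  sigma_b <- extracted$sigma_b; sigma_e <- extracted$sigma_e
  re <- extracted$re; aic <- extracted$aic; note <- extracted$note
  dfs <- extracted$dfs
  if (!is.null(note) && sigma_e > 1e-8) warning(note)
  tcrit <- stats::qt(0.975, dfs)
  tval <- beta / se
  coef_tab <- data.frame(
    term = c("intercept", "delta_initial", "log10_age_x_ivi"),
    estimate = as.numeric(beta), se = as.numeric(se), df = as.numeric(dfs),
    t = as.numeric(tval),
    p = 2 * stats::pt(-abs(tval), dfs),
    ci_lo = as.numeric(beta - tcrit * se),
    ci_hi = as.numeric(beta + tcrit * se),
    row.names = NULL)
  beta <- stats::setNames(as.numeric(beta),
                          c("intercept", "delta_initial", "log10_age_x_ivi"))
  pred <- beta[1] + beta[2] * d$di + beta[3] * d$x
  fit <- structure(list(
    coefficients = coef_tab, beta = beta,
    sigma_b = sigma_b, sigma_e = sigma_e,
    rmse = sqrt(mean((pred - d$y)^2)),
    aic = aic, method = method, df_method = df_method, units = units,
    n_pairs = nrow(d), n_subjects = nlevels(d$subject),
    ranef = re, note = note), class = "nh_fit")
  fit
}

#' @export
print.nh_fit <- function(x, ...) {
  cat(sprintf("Natural-history model (%s, %d pairs / %d subjects, ages in %s)\n",
              x$method, x$n_pairs, x$n_subjects, x$units))
  ct <- x$coefficients
  ct[-1] <- lapply(ct[-1], signif, digits = 4)
  print(ct, row.names = FALSE)
  cat(sprintf("sigma_b = %.4g, sigma_e = %.4g, RMSE = %.4g, AIC = %.2f\n",
              x$sigma_b, x$sigma_e, x$rmse, x$aic))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Predict delta power at a subsequent visit
#'
#' Population mode sets the random intercept to zero; known-subject mode adds
#' the empirical-Bayes intercept of that subject (error if unknown). All
#' arguments are vectorized.
#'
#' @param fit an [fit_natural_history()] result.
#' @param delta_initial delta power at the initial visit.
#' @param age_initial age at the initial visit (> 0, same unit as the fit).
#' @param ivi elapsed time between visits (>= 0).
#' @param subject optional subject id(s) for subject-specific predictions.
#' @return predicted delta at the subsequent visit.
#' @export
predict_delta <- function(fit, delta_initial, age_initial, ivi,
                          subject = NULL) {
  stopifnot(inherits(fit, "nh_fit"), all(age_initial > 0), all(ivi >= 0))
  b <- 0
  if (!is.null(subject)) {
    subject <- as.character(subject)
    miss <- setdiff(unique(subject), names(fit$ranef))
    if (length(miss) > 0L)
      stop("unknown subject id(s): ", paste(miss, collapse = ", "))
    b <- fit$ranef[subject]
  }
  unname(fit$beta[1] + fit$beta[2] * delta_initial +
           fit$beta[3] * log10(age_initial) * ivi + b)
}

#' Model residuals: predicted minus observed
#'
#' Sign convention: residual = predicted - observed, so a treatment that
#' LOWERS delta power yields POSITIVE residuals. This is deliberate (the
#' treatment-effect machinery tests for residuals larger in the treated
#' group) and opposite to the usual regression convention.
#'
#' @param fit an `nh_fit`.
#' @param pairs data frame of pairs to evaluate.
#' @param mode `"population"` (random intercept zero) or `"subject"`
#'   (empirical-Bayes intercepts, subjects must be known to the fit).
#' @return numeric vector of residuals, aligned with `pairs` rows.
#' @export
residual_delta <- function(fit, pairs, mode = c("population", "subject")) {
  mode <- match.arg(mode)
  validate_pairs(pairs)
  subj <- if (mode == "subject") pairs$subject_id else NULL
  pred <- predict_delta(fit, pairs$delta_initial, pairs$age_initial,
                        pairs$ivi, subject = subj)
  pred - pairs$delta_subsequent
}

#' Cross-validate the natural-history model
#'
#' Leave-one-subject-out (`scheme = "subject"`) or leave-one-week-out
#' (`scheme = "week"`, requiring a `week_subsequent` column; each fold holds
#' out every pair whose subsequent visit falls in one week). For each fold
#' the model is refit on the remainder and population-level residuals are
#' computed on the held-out pairs; folds that would leave fewer than 3
#' training pairs or 2 training subjects are skipped with a warning.
#'
#' @param pairs data frame of pairs.
#' @param scheme `"subject"` or `"week"`.
#' @param method passed to [fit_natural_history()].
#' @return an `nh_cv` list: `residuals` (named by fold), `rmse` (pooled),
#'   `in_sample_rmse`, `per_fold` summary data frame.
#' @export
cross_validate <- function(pairs, scheme = c("subject", "week"),
                           method = "ML") {
  scheme <- match.arg(scheme)
  validate_pairs(pairs)
  fold_id <- if (scheme == "subject") pairs$subject_id else {
    if (!"week_subsequent" %in% names(pairs))
      stop("scheme = 'week' requires a week_subsequent column")
    pairs$week_subsequent
  }
  folds <- unique(fold_id)
  if (length(folds) < 3L) stop("need >= 3 folds")
  res <- list(); per_fold <- list()
  for (f in folds) {
    train <- pairs[fold_id != f, , drop = FALSE]
    test <- pairs[fold_id == f, , drop = FALSE]
    if (nrow(train) < 3L || length(unique(train$subject_id)) < 2L) {
      warning(sprintf("fold '%s' skipped: too little training data", f))
      next
    }
    ft <- fit_natural_history(train, method = method)
    r <- residual_delta(ft, test, mode = "population")
    res[[as.character(f)]] <- r
    per_fold[[as.character(f)]] <-
      data.frame(fold = as.character(f), n_test = nrow(test),
                 rmse = sqrt(mean(r^2)))
  }
  if (length(res) == 0L) stop("no usable folds")
  full <- fit_natural_history(pairs, method = method)
  structure(list(residuals = res,
                 rmse = sqrt(mean(unlist(res)^2)),
                 in_sample_rmse = full$rmse,
                 per_fold = do.call(rbind, c(per_fold,
                                             list(make.row.names = FALSE))),
                 scheme = scheme), class = "nh_cv")
}

#' @export
print.nh_cv <- function(x, ...) {
  cat(sprintf("Cross-validation (leave-one-%s-out, %d folds)\n",
              x$scheme, nrow(x$per_fold)))
  cat(sprintf("pooled RMSE = %.4g (in-sample %.4g)\n",
              x$rmse, x$in_sample_rmse))
  invisible(x)
}
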