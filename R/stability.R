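#' Stability of the delta estimate versus amount of data
#'
#' Both functions resample a vector of per-interval (typically per-second)
#' relative delta values and report, per sample size, the empirical SEM of
#' the resulting mean-delta estimate -- defined as the standard deviation
#' (denominator `n_reps - 1`) across resampled means -- together with the
#' empirical 2.5%/97.5% bounds. An analytic SEM would differ whenever the
#' per-interval series drifts; the resampling definition is used throughout.
#'
#' `sem_random_epochs` draws, for each requested epoch count, `n_reps`
#' subsets of intervals without replacement. `sem_contiguous_epochs` draws
#' `n_reps` contiguous runs of each requested duration, with start times
#' uniform on `[0, span - duration]` and no wraparound (recordings are not
#' circular). Under iid intervals the two agree; under slow drift the
#' contiguous SEM is larger.
#'
#' @param per_interval numeric vector of per-interval delta values, one per
#'   second of data.
#' @param sizes epoch counts to draw (random mode).
#' @param durations_s contiguous durations in seconds.
#' @param n_reps resampling repetitions (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return a `stability_curve`: data frame with columns `size` (epochs or
#'   seconds), `sem`, `ci_lo`, `ci_hi`, `mean`, plus attributes `mode` and
#'   `n_reps`.
#' @export
sem_random_epochs <- function(per_interval, sizes, n_reps = 1000, seed = NULL) {
  stopifnot(is.numeric(per_interval), length(per_interval) >= 1L,
            n_reps >= 2)
  sizes <- as.integer(sizes)
  bad <- sizes > length(per_interval)
  if (any(bad))
    stop(sprintf("size(s) %s exceed the %d available intervals",
                 paste(sizes[bad], collapse = ", "), length(per_interval)))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(sizes, function(m) {
    means <- vapply(seq_len(n_reps), function(r)
      mean(per_interval[sample.int(length(per_interval), m)]), numeric(1))
    q <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
    data.frame(size = m, sem = stats::sd(means), ci_lo = q[1], ci_hi = q[2],
               mean = mean(means))
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- "random"
  attr(out, "n_reps") <- n_reps
  class(out) <- c("stability_curve", "data.frame")
  out
}

#' @rdname sem_random_epochs
#' @export
sem_contiguous_epochs <- function(per_interval, durations_s, n_reps = 1000,
                                  seed = NULL) {
  stopifnot(is.numeric(per_interval), n_reps >= 2)
  span <- length(per_interval)  # seconds, one value per second
  durations_s <- as.integer(durations_s)
  bad <- durations_s > span
  if (any(bad))
    stop(sprintf("duration(s) %s s exceed the %d s recording span",
                 paste(durations_s[bad], collapse = ", "), span))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(durations_s, function(dur) {
    starts <- sample.int(span - dur + 1L, n_reps, replace = TRUE) - 1L
    means <- vapply(starts, function(s0)
      mean(per_interval[(s0 + 1L):(s0 + dur)]), numeric(1))
    q <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
    data.frame(size = dur, sem = stats::sd(means), ci_lo = q[1], ci_hi = q[2],
               mean = mean(means))
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- "contiguous"
  attr(out, "n_reps") <- n_reps
  class(out) <- c("stability_curve", "data.frame")
  out
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> mode=%s, %d size(s), %d reps\n",
              attr(x, "mode"), nrow(x), attr(x, "n_reps")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
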