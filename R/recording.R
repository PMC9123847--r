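#' Multichannel time-series recording
#'
#' Container for a multichannel EEG or LFP recording: a samples matrix
#' (time along rows, channels along columns), a sampling rate, unique channel
#' labels, and an optional wake mask giving `[start, end)` intervals (in
#' seconds) that were manually staged as wake. Wake staging is always an
#' input, never computed.
#'
#' @param samples numeric matrix (time x channel), a numeric vector (single
#'   channel), or a named list of equal-length channel vectors. Units are
#'   microvolts for scalp EEG and millivolts for LFP; the ratio-based
#'   estimators are unit-agnostic.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector of unique labels, one per channel.
#'   Defaults to column / list names, else `ch1, ch2, ...`.
#' @param wake_mask optional two-column matrix or data frame of
#'   `[start, end)` wake intervals in seconds, within the recording duration.
#' @param units free-text unit label carried along for reporting ("uV", "mV").
#'
#' @return an object of class `time_series_recording`.
#' @export
time_series_recording <- function(samples, fs, channel_labels = NULL,
                                  wake_mask = NULL, units = "uV") {
  if (is.list(samples) && !is.data.frame(samples)) {
    lens <- lengths(samples)
    if (length(unique(lens)) != 1L)
      stop("all channels must have equal length")
    if (is.null(channel_labels) && !is.null(names(samples)))
      channel_labels <- names(samples)
    samples <- do.call(cbind, samples)
  }
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive finite scalar (Hz)")
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples)
    if (!is.null(channel_labels) &&
        (any(!nzchar(channel_labels)) || anyDuplicated(channel_labels)))
      channel_labels <- NULL
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(ncol(samples)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(samples))
    stop("need one channel label per column of 'samples'")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  colnames(samples) <- channel_labels
  dur <- nrow(samples) / fs
  if (!is.null(wake_mask)) {
    wake_mask <- as.matrix(wake_mask)
    if (ncol(wake_mask) != 2L)
      stop("wake_mask must have two columns: start, end (seconds)")
    storage.mode(wake_mask) <- "double"
    colnames(wake_mask) <- c("start", "end")
    if (any(wake_mask[, 1L] < 0) || any(wake_mask[, 2L] > dur + 1e-9) ||
        any(wake_mask[, 2L] <= wake_mask[, 1L]))
      stop("wake intervals must satisfy 0 <= start < end <= duration")
  }
  structure(list(samples = samples, fs = fs, channel_labels = channel_labels,
                 wake_mask = wake_mask, units = units),
            class = "time_series_recording")
}

#' @export
print.time_series_recording <- function(x, ...) {
  cat(sprintf("<time_series_recording> %d channel(s), %.1f s at %g Hz\n",
              ncol(x$samples), rec_duration(x), x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$wake_mask))
    cat(sprintf("  wake mask: %d interval(s), %.1f s total\n",
                nrow(x$wake_mask), sum(x$wake_mask[, 2] - x$wake_mask[, 1])))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [time_series_recording()].
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) {
  stopifnot(inherits(rec, "time_series_recording"))
  nrow(rec$samples) / rec$fs
}

match_channels <- function(rec, labels) {
  idx <- match(tolower(labels), tolower(rec$channel_labels))
  if (anyNA(idx))
    stop(sprintf("channel(s) not found: %s (available: %s)",
                 paste(labels[is.na(idx)], collapse = ", "),
                 paste(rec$channel_labels, collapse = ", ")))
  idx
}

#' Average re-referencing over a channel subset
#'
#' Re-references a subset of channels to their instantaneous group average:
#' the mean across the subset is subtracted from each channel at every sample,
#' so the returned channels sum to zero at every time point. This is the
#' posterior-montage referencing used before relative delta power estimation
#' (O1, O2, P3, Pz, P4 referenced to their group average).
#'
#' @param rec a [time_series_recording()].
#' @param subset channel labels to keep and re-reference (case-insensitive).
#'   Default: all channels.
#' @return a `time_series_recording` containing only the subset channels,
#'   re-referenced; the wake mask is carried over.
#' @export
rereference_average <- function(rec, subset = NULL) {
  stopifnot(inherits(rec, "time_series_recording"))
  if (is.null(subset)) subset <- rec$channel_labels
  idx <- match_channels(rec, subset)
  x <- rec$samples[, idx, drop = FALSE]
  y <- x - rowMeans(x)
  time_series_recording(y, rec$fs, rec$channel_labels[idx],
                        wake_mask = rec$wake_mask, units = rec$units)
}

#' Exclude noisy channels by robust power deviation or saturation
#'
#' Flags channels whose log total power deviates from the cohort median by
#' more than `z_thresh` robust z-units (median/MAD), or that sit pinned at a
#' rail value (their own minimum or maximum, repeated exactly) for at least
#' `rail_s` seconds. Stands in for the unpublished channel-rejection step used
#' for mouse LFP recordings; thresholds are configurable.
#'
#' @param rec a [time_series_recording()] with at least one channel.
#' @param z_thresh robust z threshold on log total power (default 3).
#' @param rail_s minimum saturation run length in seconds (default 0.1).
#' @return a list with `recording` (retained channels; `NULL` if all were
#'   excluded) and `report`, a data frame with one row per channel giving the
#'   log power, robust z, saturation flag, and exclusion reason.
#' @export
exclude_noisy_channels <- function(rec, z_thresh = 3, rail_s = 0.1) {
  stopifnot(inherits(rec, "time_series_recording"))
  x <- rec$samples
  nch <- ncol(x)
  if (nch < 1L) stop("recording has no channels")
  pw <- colMeans(sweep(x, 2L, colMeans(x))^2)
  lp <- log(pmax(pw, .Machine$double.xmin))
  dev <- lp - stats::median(lp)
  scale <- stats::mad(lp)
  if (scale == 0) scale <- stats::IQR(lp) / 1.349
  z <- if (scale == 0) ifelse(dev == 0, 0, Inf) else dev / scale
  min_run <- max(2L, ceiling(rail_s * rec$fs))
  saturated <- vapply(seq_len(nch), function(j) {
    v <- x[, j]
    rails <- unique(range(v))
    any(vapply(rails, function(r) {
      rl <- rle(v == r)
      any(rl$values & rl$lengths >= min_run)
    }, logical(1)))
  }, logical(1))
  excl_z <- abs(z) > z_thresh
  excluded <- excl_z | saturated
  reason <- rep("", nch)
  reason[excl_z] <- "power_outlier"
  reason[saturated] <- ifelse(reason[saturated] == "", "saturation",
                              "power_outlier+saturation")
  report <- data.frame(channel = rec$channel_labels, log_power = lp,
                       robust_z = z, saturated = saturated,
                       excluded = excluded, reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  keep <- which(!excluded)
  recording <- if (length(keep) == 0L) NULL else
    time_series_recording(x[, keep, drop = FALSE], rec$fs,
                          rec$channel_labels[keep],
                          wake_mask = rec$wake_mask, units = rec$units)
  list(recording = recording, report = report)
}
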