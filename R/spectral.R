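#' Spectral estimation settings
#'
#' Bundles the windowing, taper, and band conventions used by
#' [windowed_power_spectrum()], [relative_delta_power()] and
#' [absolute_delta_peak()].
#'
#' Band-edge convention: with the 1 Hz resolution of 1 s windows, the delta
#' band 2-4 Hz spans the three bins \{2, 3, 4\} Hz inclusive and the total
#' band 1-50 Hz the fifty bins \{1..50\} Hz inclusive; the mouse peak band is
#' \[1, 5\] Hz inclusive. Both bands are configurable.
#'
#' @param window_s window length in seconds (default 1).
#' @param overlap_s overlap between consecutive windows, `0 <= overlap_s <
#'   window_s` (default 0: non-overlapping).
#' @param taper `"hanning"` (human EEG default) or `"dpss"` multitaper
#'   (mouse LFP).
#' @param n_tapers number of DPSS tapers (default 5; ignored for hanning).
#' @param time_bandwidth DPSS time-bandwidth product (default 3).
#' @param band_delta delta band `[lo, hi]` Hz, bins inclusive.
#' @param band_total total band `[lo, hi]` Hz for the relative ratio.
#' @param channel_subset optional labels restricting the analysis.
#' @return a `spectral_config` list.
#' @export
spectral_config <- function(window_s = 1, overlap_s = 0,
                            taper = c("hanning", "dpss"),
                            n_tapers = 5, time_bandwidth = 3,
                            band_delta = c(2, 4), band_total = c(1, 50),
                            channel_subset = NULL) {
  taper <- match.arg(taper)
  stopifnot(window_s > 0, overlap_s >= 0, overlap_s < window_s,
            length(band_delta) == 2L, band_delta[1] <= band_delta[2],
            length(band_total) == 2L, band_total[1] <= band_total[2])
  structure(list(window_s = window_s, overlap_s = overlap_s, taper = taper,
                 n_tapers = as.integer(n_tapers),
                 time_bandwidth = time_bandwidth,
                 band_delta = band_delta, band_total = band_total,
                 channel_subset = channel_subset),
            class = "spectral_config")
}

#' Multitaper settings used for mouse LFP
#'
#' 5 DPSS tapers at time-bandwidth product 3, 5 s windows with 1 s overlap,
#' peak band 1-5 Hz.
#' @return a [spectral_config()].
#' @export
mouse_spectral_config <- function() {
  spectral_config(window_s = 5, overlap_s = 1, taper = "dpss",
                  n_tapers = 5, time_bandwidth = 3,
                  band_delta = c(1, 5), band_total = c(1, 5))
}

hann_taper <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

taper_matrix <- function(n, cfg) {
  if (cfg$taper == "hanning") matrix(hann_taper(n), ncol = 1L)
  else dpss_tapers(n, nw = cfg$time_bandwidth, k = cfg$n_tapers)
}

window_starts <- function(rec, cfg) {
  nwin <- round(cfg$window_s * rec$fs)
  nstep <- round((cfg$window_s - cfg$overlap_s) * rec$fs)
  nsamp <- nrow(rec$samples)
  if (nsamp < nwin)
    stop(sprintf("insufficient data: %.2f s recording, %.2f s window",
                 nsamp / rec$fs, cfg$window_s))
  starts <- seq.int(0L, nsamp - nwin, by = nstep)  # sample offsets, 0-based
  if (!is.null(rec$wake_mask)) {
    t0 <- starts / rec$fs
    t1 <- t0 + cfg$window_s
    ok <- vapply(seq_along(starts), function(i)
      any(rec$wake_mask[, 1] <= t0[i] + 1e-9 &
            rec$wake_mask[, 2] >= t1[i] - 1e-9), logical(1))
    starts <- starts[ok]
    if (length(starts) == 0L)
      stop("insufficient data: no complete window inside the wake mask")
  }
  list(starts = starts, nwin = nwin)
}

#' Windowed power spectra
#'
#' Cuts the recording into windows of `cfg$window_s` seconds (discarding any
#' partial trailing window; when a wake mask is present only windows fully
#' inside a wake interval are used), demeans each window, applies the
#' configured taper(s) and returns one-sided power spectral density estimates
#' on the frequency grid `k / window_s` Hz. With the PSD normalization used
#' (`2 |X_k|^2 / (fs * sum(h^2))`, tapers averaged), summing a spectrum over
#' all bins times the bin width recovers the tapered window's variance
#' (Parseval).
#'
#' @param rec a [time_series_recording()].
#' @param cfg a [spectral_config()].
#' @return a list of class `windowed_spectra`: `freq` (Hz), `power` (array
#'   `n_freq x n_windows x n_channels`), `window_s`, `fs`, `channels`.
#' @export
windowed_power_spectrum <- function(rec, cfg = spectral_config()) {
  stopifnot(inherits(rec, "time_series_recording"),
            inherits(cfg, "spectral_config"))
  if (!is.null(cfg$channel_subset)) {
    idx <- match_channels(rec, cfg$channel_subset)
    rec <- time_series_recording(rec$samples[, idx, drop = FALSE], rec$fs,
                                 rec$channel_labels[idx],
                                 wake_mask = rec$wake_mask, units = rec$units)
  }
  ws <- window_starts(rec, cfg)
  nwin <- ws$nwin
  starts <- ws$starts
  H <- taper_matrix(nwin, cfg)
  nfreq <- nwin %/% 2L + 1L
  scale <- 2 / (rec$fs * colSums(H^2))
  nchan <- ncol(rec$samples)
  pow <- array(0, dim = c(nfreq, length(starts), nchan))
  win_idx <- outer(seq_len(nwin), starts, "+")  # samples per window (1-based)
  for (ch in seq_len(nchan)) {
    W <- matrix(rec$samples[win_idx, ch], nrow = nwin)
    W <- sweep(W, 2L, colMeans(W))              # demean before tapering
    acc <- matrix(0, nfreq, ncol(W))
    for (j in seq_len(ncol(H))) {
      X <- stats::mvfft(W * H[, j])[seq_len(nfreq), , drop = FALSE]
      acc <- acc + scale[j] * (Mod(X)^2)
    }
    acc <- acc / ncol(H)
    acc[1L, ] <- acc[1L, ] / 2                  # DC is one-sided already
    if (nwin %% 2L == 0L) acc[nfreq, ] <- acc[nfreq, ] / 2
    pow[, , ch] <- acc
  }
  structure(list(freq = (seq_len(nfreq) - 1L) / cfg$window_s, power = pow,
                 window_s = cfg$window_s, fs = rec$fs,
                 channels = rec$channel_labels),
            class = "windowed_spectra")
}

band_bins <- function(freq, band) {
  which(freq >= band[1] - 1e-9 & freq <= band[2] + 1e-9 & freq > 0)
}

new_delta_estimate <- function(value, per_interval, mode, n_dropped = 0L,
                               units = "unitless", extra = list()) {
  est <- list(value = value, per_interval = per_interval,
              n_intervals = length(per_interval),
              sem = if (length(per_interval) > 1L)
                stats::sd(per_interval) / sqrt(length(per_interval)) else NA_real_,
              mode = mode, n_dropped = as.integer(n_dropped), units = units)
  structure(c(est, extra), class = "delta_estimate")
}

#' @export
print.delta_estimate <- function(x, ...) {
  cat(sprintf("<delta_estimate> mode=%s value=%.4g (%s), %d interval(s), SEM %.3g\n",
              x$mode, x$value, x$units, x$n_intervals, x$sem))
  if (x$n_dropped > 0L)
    cat(sprintf("  %d zero-power interval(s) dropped\n", x$n_dropped))
  invisible(x)
}

#' Relative delta power of a (re-referenced) EEG recording
#'
#' Per window, the summed delta-band power (bins 2-4 Hz inclusive) averaged
#' over channels is divided by the summed total-band power (bins 1-50 Hz
#' inclusive) averaged over channels -- a ratio of channel averages, the
#' default convention; per-channel ratios averaged afterwards are available
#' via `channel_combine = "average_of_ratios"`. The estimate is the mean of
#' the per-window ratios, a unitless value in \[0, 1\]. The recording should
#' already be posterior-referenced via [rereference_average()]; the ratio is
#' invariant to global amplitude scaling.
#'
#' Windows with zero total power are dropped and counted; an error is raised
#' if none survive.
#'
#' @param rec a [time_series_recording()], typically re-referenced.
#' @param cfg a [spectral_config()] (default: 1 s Hanning windows,
#'   delta 2-4 Hz, total 1-50 Hz).
#' @param channel_combine `"ratio_of_averages"` (default) or
#'   `"average_of_ratios"`.
#' @return a `delta_estimate` with `mode = "relative"`.
#' @export
relative_delta_power <- function(rec, cfg = spectral_config(),
                                 channel_combine = c("ratio_of_averages",
                                                     "average_of_ratios")) {
  channel_combine <- match.arg(channel_combine)
  sp <- windowed_power_spectrum(rec, cfg)
  di <- band_bins(sp$freq, cfg$band_delta)
  ti <- band_bins(sp$freq, cfg$band_total)
  if (!all(di %in% ti))
    stop("delta band must lie within the total band for relative mode")
  nw <- dim(sp$power)[2L]
  D <- apply(sp$power[di, , , drop = FALSE], c(2L, 3L), sum)
  Tt <- apply(sp$power[ti, , , drop = FALSE], c(2L, 3L), sum)
  D <- matrix(D, nrow = nw); Tt <- matrix(Tt, nrow = nw)
  if (channel_combine == "ratio_of_averages") {
    num <- rowMeans(D); den <- rowMeans(Tt)
    keep <- den > 0
    r <- num[keep] / den[keep]
  } else {
    ok <- Tt > 0
    keep <- rowSums(ok) > 0
    r <- vapply(which(keep), function(i) {
      j <- ok[i, ]
      mean(D[i, j] / Tt[i, j])
    }, numeric(1))
  }
  n_drop <- nw - sum(keep)
  if (length(r) == 0L) stop("all intervals had zero total power")
  new_delta_estimate(mean(r), r, mode = "relative", n_dropped = n_drop)
}

#' Absolute delta activity: multitaper spectral peak in 1-5 Hz
#'
#' Restricts the recording to its last `last_minutes` minutes (or the whole
#' recording if shorter), computes DPSS multitaper spectra per channel
#' (hemisphere), averages spectra over windows and then across channels, and
#' returns the maximum of the averaged spectrum over bins in the peak band
#' (1-5 Hz inclusive by default), in squared-signal-units per Hz. With a
#' single remaining channel a warning notes the single-hemisphere estimate.
#'
#' `per_interval` holds the per-window in-band peak of the channel-averaged
#' spectrum (used for uncertainty reporting); the headline `value` is the
#' peak of the window-averaged spectrum, so it is not constrained to equal
#' `mean(per_interval)`.
#'
#' @param rec a [time_series_recording()] (typically after
#'   [exclude_noisy_channels()]).
#' @param cfg a [spectral_config()]; default [mouse_spectral_config()].
#' @param last_minutes analysis span taken from the end of the recording
#'   (default 10).
#' @return a `delta_estimate` with `mode = "absolute_peak"`, including
#'   `peak_freq`.
#' @export
absolute_delta_peak <- function(rec, cfg = mouse_spectral_config(),
                                last_minutes = 10) {
  stopifnot(inherits(rec, "time_series_recording"))
  if (ncol(rec$samples) == 0L) stop("no channels available")
  if (ncol(rec$samples) == 1L)
    warning("single channel available; reporting a single-hemisphere estimate")
  keep_s <- min(rec_duration(rec), last_minutes * 60)
  n_keep <- round(keep_s * rec$fs)
  x <- rec$samples[(nrow(rec$samples) - n_keep + 1L):nrow(rec$samples), ,
                   drop = FALSE]
  rec2 <- time_series_recording(x, rec$fs, rec$channel_labels,
                                units = rec$units)
  sp <- windowed_power_spectrum(rec2, cfg)
  band <- band_bins(sp$freq, cfg$band_delta)
  mean_spec <- apply(sp$power, 1L, mean)            # windows then hemispheres
  peak_i <- band[which.max(mean_spec[band])]
  per_win <- apply(sp$power[band, , , drop = FALSE], 2L,
                   function(m) max(rowMeans(matrix(m, nrow = length(band)))))
  new_delta_estimate(mean_spec[peak_i], per_win, mode = "absolute_peak",
                     units = paste0(rec$units, "^2/Hz"),
                     extra = list(peak_freq = sp$freq[peak_i],
                                  mean_spectrum = mean_spec[band],
                                  band_freq = sp$freq[band]))
}
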