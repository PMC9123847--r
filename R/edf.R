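pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: one data record per second,
#' 16-bit integer samples scaled against per-channel physical extrema.
#' Requires an integer number of samples per second; any partial trailing
#' second is dropped. Intended for fixture generation and data exchange;
#' round-trips with [read_edf()] to within the 16-bit quantization step.
#'
#' @param rec a [time_series_recording()].
#' @param path output file path.
#' @param patient,recording_id free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "X") {
  stopifnot(inherits(rec, "time_series_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nrec <- nrow(rec$samples) %/% fs
  if (nrec < 1L) stop("recording shorter than one data record (1 s)")
  ns <- ncol(rec$samples)
  x <- rec$samples[seq_len(nrec * fs), , drop = FALSE]
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(patient, 80), pad_field(recording_id, 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256 * ns, 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field("1", 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    labels = vapply(rec$channel_labels, pad_field, "", width = 16),
    transducer = rep(pad_field("", 80), ns),
    dim = rep(pad_field(rec$units, 8), ns),
    pmin = vapply(sprintf("%.6g", pmin_), pad_field, "", width = 8),
    pmax = vapply(sprintf("%.6g", pmax_), pad_field, "", width = 8),
    dmin = rep(pad_field(dmin, 8), ns),
    dmax = rep(pad_field(dmax, 8), ns),
    prefilter = rep(pad_field("", 80), ns),
    spr = rep(pad_field(fs, 8), ns),
    reserved = rep(pad_field("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round(sweep(sweep(x, 2, pmin_), 2, gain, "*")) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(dig[rows, ]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  h <- list(version = rd(8), patient = rd(80), recording = rd(80),
            startdate = rd(8), starttime = rd(8))
  h$header_bytes <- as.integer(rd(8)); rd(44)
  h$n_records <- as.integer(rd(8))
  h$record_s <- as.numeric(rd(8))
  h$n_signals <- as.integer(rd(4))
  ns <- h$n_signals
  rdv <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  h$labels <- rdv(16); rdv(80)
  h$dim <- rdv(8)
  h$pmin <- as.numeric(rdv(8)); h$pmax <- as.numeric(rdv(8))
  h$dmin <- as.numeric(rdv(8)); h$dmax <- as.numeric(rdv(8))
  rdv(80)
  h$spr <- as.integer(rdv(8)); rdv(32)
  h
}

#' Read an EDF file into a recording
#'
#' Reads European Data Format (EDF) signals, selecting channels by label
#' (case-insensitive; an error lists the available labels when a requested
#' channel is absent). Digital values are rescaled to physical units. All
#' selected channels must share one sampling rate. An optional wake sidecar
#' (CSV with columns `start`, `end`, seconds) becomes the recording's wake
#' mask.
#'
#' @param path EDF file.
#' @param channels labels to load (default: all).
#' @param wake_sidecar optional CSV path of wake intervals.
#' @return a [time_series_recording()].
#' @export
read_edf <- function(path, channels = NULL, wake_sidecar = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- tryCatch(suppressWarnings(read_edf_header(con)),
                error = function(e)
                  stop("not a readable EDF file: ", path))
  if (length(h$n_signals) != 1L || is.na(h$n_signals) || h$n_signals < 1L ||
      length(h$n_records) != 1L || is.na(h$n_records) ||
      anyNA(h$spr) || anyNA(h$dmin) || anyNA(h$dmax))
    stop("not a readable EDF file: ", path)
  ns <- h$n_signals
  sel <- if (is.null(channels)) seq_len(ns) else {
    idx <- match(tolower(channels), tolower(h$labels))
    if (anyNA(idx))
      stop(sprintf("channel(s) not found: %s (available: %s)",
                   paste(channels[is.na(idx)], collapse = ", "),
                   paste(h$labels, collapse = ", ")))
    idx
  }
  if (length(unique(h$spr[sel])) != 1L)
    stop("selected channels have differing sampling rates")
  per_rec <- sum(h$spr)
  raw <- readBin(con, integer(), n = per_rec * h$n_records, size = 2L,
                 endian = "little", signed = TRUE)
  offs <- c(0L, cumsum(h$spr))
  fs <- h$spr[sel[1L]] / h$record_s
  out <- matrix(0, h$n_records * h$spr[sel[1L]], length(sel))
  for (k in seq_along(sel)) {
    j <- sel[k]
    cols <- outer(offs[j] + seq_len(h$spr[j]), (0:(h$n_records - 1L)) * per_rec,
                  "+")
    dig <- raw[as.vector(cols)]
    gain <- (h$pmax[j] - h$pmin[j]) / (h$dmax[j] - h$dmin[j])
    out[, k] <- (dig - h$dmin[j]) * gain + h$pmin[j]
  }
  wake <- NULL
  if (!is.null(wake_sidecar)) {
    wk <- utils::read.csv(wake_sidecar)
    if (!all(c("start", "end") %in% names(wk)))
      stop("wake sidecar must have columns start, end")
    wake <- as.matrix(wk[, c("start", "end")])
  }
  time_series_recording(out, fs, h$labels[sel], wake_mask = wake,
                        units = h$dim[sel[1L]])
}
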