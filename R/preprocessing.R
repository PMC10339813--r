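# Epoch segmentation, re-referencing, and FIR decomposition into the five
# canonical EEG bands.

#' Canonical EEG frequency bands
#'
#' Band edges in Hz for the five canonical bands: delta 1-4, theta 4-8,
#' alpha 8-12, beta 12-30, gamma 30-60.
#'
#' @format Named list of length-2 numeric vectors `c(lower, upper)`.
#' @export
eeg_bands <- list(
  delta = c(1, 4),
  theta = c(4, 8),
  alpha = c(8, 12),
  beta  = c(12, 30),
  gamma = c(30, 60)
)

#' Multichannel recording container
#'
#' @param samples numeric matrix, channels x time (any amplitude scale).
#' @param fs sampling rate in Hz.
#' @param channel_names optional character vector of channel labels.
#' @return an object of class `eeg_recording` with fields `samples`, `fs`,
#'   `channel_names`.
#' @export
eeg_recording <- function(samples, fs, channel_names = NULL) {
  samples <- as.matrix(samples)
  check_number(fs, "fs", lower = .Machine$double.eps)
  if (nrow(samples) < 2L) stop_field("samples", "need at least 2 channels")
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop_field("samples", "contains NA or non-finite values")
  }
  if (is.null(channel_names)) {
    channel_names <- default_channel_names(nrow(samples))
  }
  if (length(channel_names) != nrow(samples)) {
    stop_field("channel_names", "length must match channel count")
  }
  structure(list(samples = samples, fs = fs, channel_names = channel_names),
            class = "eeg_recording")
}

# 10-20 montage used in the 16-channel setup; generic labels otherwise.
default_channel_names <- function(n) {
  montage16 <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
                 "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6")
  if (n == 16L) montage16 else paste0("ch", seq_len(n))
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}

#' Segment a recording into fixed-length epochs
#'
#' Splits the recording into `floor(duration / epoch_len)` non-overlapping
#' epochs of `fs * epoch_len` samples; a trailing remainder shorter than one
#' epoch is discarded.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_len epoch length in seconds.
#' @return list of epochs; each epoch is a list with `samples`
#'   (channels x time), `epoch_id`, `fs`, `channel_names`, `group` (NA).
#' @export
segment_epochs <- function(rec, epoch_len) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_number(epoch_len, "epoch_len", lower = .Machine$double.eps)
  n_samp <- round(rec$fs * epoch_len)
  total <- ncol(rec$samples)
  if (total < n_samp) stop("recording shorter than one epoch", call. = FALSE)
  n_ep <- floor(total / n_samp)
  lapply(seq_len(n_ep), function(e) {
    idx <- ((e - 1L) * n_samp + 1L):(e * n_samp)
    list(samples = rec$samples[, idx, drop = FALSE],
         epoch_id = e, fs = rec$fs,
         channel_names = rec$channel_names, group = NA_character_)
  })
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, a
#' simple stand-in for reference-related spatial filtering. Idempotent.
#'
#' @param rec an [eeg_recording()].
#' @return the re-referenced [eeg_recording()].
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$samples <- sweep(rec$samples, 2L, colMeans(rec$samples), "-")
  rec
}

# FIR design cache: windowed-sinc (Hamming) band-pass, order chosen so the
# filter spans ~3 cycles of the band's lower edge, with a floor of 257 taps.
.fir_cache <- new.env(parent = emptyenv())

fir_taps <- function(fs, edges) {
  n <- max(round(3 * fs / edges[1L]), 257)
  if (n %% 2L == 0L) n <- n + 1L
  n
}

fir_coef <- function(fs, edges) {
  key <- paste(fs, edges[1L], edges[2L], sep = "_")
  h <- .fir_cache[[key]]
  if (is.null(h)) {
    n <- fir_taps(fs, edges)
    h <- signal::fir1(n - 1L, edges / (fs / 2), type = "pass")
    .fir_cache[[key]] <- h
  }
  h
}

# Zero-phase FIR application: odd-reflection padding of one filter length on
# both ends, forward pass then time-reversed pass (linear-phase FIR, so the
# group delays cancel), then the padding is dropped. Output length == input.
zero_phase_filter <- function(h, x) {
  L <- length(h)
  n <- length(x)
  if (n < 2L) stop("signal too short to filter", call. = FALSE)
  lpad <- 2 * x[1L] - x[pmin(seq(L + 1L, 2L), n)]
  rpad <- 2 * x[n] - x[pmax(seq(n - 1L, n - L), 1L)]
  xp <- c(lpad, x, rpad)
  y <- signal::fftfilt(h, xp)
  y <- rev(signal::fftfilt(h, rev(y)))
  y[(L + 1L):(L + n)]
}

#' Band-pass filter an epoch into one canonical band
#'
#' Zero-phase windowed-sinc (Hamming) FIR band-pass at the band's edges,
#' applied forward-backward with reflection padding; output length equals
#' input length.
#'
#' @param x numeric vector (one channel) or channels x time matrix, or an
#'   epoch list with a `samples` field.
#' @param fs sampling rate in Hz; taken from `x` if it is an epoch list.
#' @param band band name (one of `names(eeg_bands)`) or numeric
#'   `c(lower, upper)` in Hz.
#' @return an object of class `band_epoch`: list with `samples` (same shape
#'   as the input signal), `band`, `fs`, and optional `epoch_id`, `group`.
#' @export
bandpass <- function(x, fs = NULL, band) {
  epoch_id <- NA_integer_; group <- NA_character_
  if (is.list(x) && !is.null(x$samples)) {
    if (is.null(fs)) fs <- x$fs
    epoch_id <- if (is.null(x$epoch_id)) NA_integer_ else x$epoch_id
    group <- if (is.null(x$group)) NA_character_ else x$group
    x <- x$samples
  }
  if (is.null(fs)) stop_field("fs", "must be supplied")
  if (is.character(band)) {
    band_name <- match.arg(band, names(eeg_bands))
    edges <- eeg_bands[[band_name]]
  } else {
    edges <- as.numeric(band)
    stopifnot(length(edges) == 2L, edges[1L] > 0, edges[2L] > edges[1L])
    band_name <- paste0(edges[1L], "-", edges[2L], "Hz")
  }
  if (fs <= 2 * edges[2L]) {
    stop(sprintf("sampling rate %g Hz too low for band %s (upper edge %g Hz)",
                 fs, band_name, edges[2L]), call. = FALSE)
  }
  h <- fir_coef(fs, edges)
  filt <- if (is.matrix(x)) {
    t(apply(x, 1L, function(row) zero_phase_filter(h, row)))
  } else {
    zero_phase_filter(h, as.numeric(x))
  }
  structure(list(samples = filt, band = band_name, fs = fs,
                 epoch_id = epoch_id, group = group),
            class = "band_epoch")
}

#' Read a delimited-text recording
#'
#' One column per channel with a header row of channel names; whitespace,
#' comma or tab separated.
#'
#' @param path file path.
#' @param fs sampling rate in Hz (not stored in the text format).
#' @param sep field separator passed to [utils::read.table()]; default `""`
#'   (any whitespace).
#' @return an [eeg_recording()].
#' @export
read_recording_txt <- function(path, fs, sep = "") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  eeg_recording(t(as.matrix(df)), fs = fs, channel_names = colnames(df))
}

#' Write a recording as delimited text
#'
#' @param rec an [eeg_recording()] or an epoch list with `samples` and
#'   `channel_names`.
#' @param path output path.
#' @export
write_recording_txt <- function(rec, path) {
  m <- t(rec$samples)
  colnames(m) <- rec$channel_names
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
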