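# Minimal European Data Format (EDF) reader/writer for continuous
# multichannel recordings: ASCII headers and 16-bit little-endian integer
# data records, one-second records, identical sampling rate on all channels.
# Covers the interchange need of this package (no annotations, no
# discontinuous files).

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' Write a recording to an EDF file
#'
#' Physical scaling is chosen per channel from the data range, so the 16-bit
#' quantization error is at most the per-channel range divided by 2^16.
#'
#' @param rec an [eeg_recording()], or an epoch list with `samples`, `fs`,
#'   `channel_names`.
#' @param path output path.
#' @param patient,recording free-text EDF identification fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording = "X") {
  samples <- rec$samples
  fs <- rec$fs
  ch <- rec$channel_names
  ns <- nrow(samples)
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate",
                            call. = FALSE)
  spr <- as.integer(fs)               # samples per 1-s record
  n_rec <- floor(ncol(samples) / spr)
  if (n_rec < 1L) stop("recording shorter than one 1-s EDF record",
                       call. = FALSE)
  phys_min <- apply(samples, 1L, min)
  phys_max <- apply(samples, 1L, max)
  flat <- phys_max - phys_min == 0
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768L; dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8L), pad(patient, 80L), pad(recording, 80L),
    pad("01.01.00", 8L), pad("00.00.00", 8L),
    pad(256L + ns * 256L, 8L), pad("", 44L),
    pad(n_rec, 8L), pad("1", 8L), pad(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad, character(1L), width = width),
                     collapse = ""), con, eos = NULL)
  }
  fld(ch, 16L)                               # label
  fld(rep("", ns), 80L)                      # transducer
  fld(rep("uV", ns), 8L)                     # physical dimension
  fld(formatC(phys_min, digits = 6, format = "g"), 8L)
  fld(formatC(phys_max, digits = 6, format = "g"), 8L)
  fld(rep(dig_min, ns), 8L)
  fld(rep(dig_max, ns), 8L)
  fld(rep("", ns), 80L)                      # prefiltering
  fld(rep(spr, ns), 8L)
  fld(rep("", ns), 32L)                      # reserved
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((samples[s, idx] - phys_min[s]) * scale[s]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written with equal per-channel rates
#'
#' @param path EDF file path.
#' @return an [eeg_recording()]; channel labels come from the EDF header.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L)                                    # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  ch <- trimws(vapply(seq_len(ns), function(i) rd(16L), character(1L)))
  for (i in seq_len(ns)) rd(80L)
  for (i in seq_len(ns)) rd(8L)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  for (i in seq_len(ns)) rd(80L)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  for (i in seq_len(ns)) rd(32L)
  if (length(unique(spr)) != 1L) {
    stop("EDF reader supports equal per-channel sampling rates only",
         call. = FALSE)
  }
  fs <- spr[1L] / dur
  out <- matrix(0, ns, n_rec * spr[1L])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
      out[s, idx] <- phys_min[s] + (dig - dig_min[s]) * scale[s]
    }
  }
  eeg_recording(out, fs = fs, channel_names = ch)
}
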