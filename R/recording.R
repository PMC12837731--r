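#' Construct a scalp EEG recording
#'
#' Container for a multichannel scalp EEG signal. The signal is stored as a
#' channels x samples matrix in microvolts. The sampling rate must satisfy
#' the Nyquist requirement for the ripple band (>= 500 Hz for an upper band
#' edge of 250 Hz).
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param channels character vector of electrode labels (one per row).
#' @param montage `"referential"` or `"average"`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, sampling_rate,
                          channels = ten_twenty_channels()[seq_len(nrow(signal))],
                          montage = c("referential", "average")) {
  montage <- match.arg(montage)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric channels x samples matrix", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate < 500)
    stop("`sampling_rate` must be a single value >= 500 Hz (Nyquist for the ripple band)",
         call. = FALSE)
  if (length(channels) != nrow(signal))
    stop("`channels` must name every signal row", call. = FALSE)
  rownames(signal) <- channels
  structure(
    list(signal = signal, sampling_rate = sampling_rate,
         channels = channels, montage = montage),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s montage\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              n_samples(x) / x$sampling_rate, x$montage))
  invisible(x)
}

#' @rdname eeg_recording
#' @param rec an `eeg_recording`.
#' @export
n_samples <- function(rec) ncol(rec$signal)

#' @rdname eeg_recording
#' @export
duration_s <- function(rec) ncol(rec$signal) / rec$sampling_rate

# ---------------------------------------------------------------------------
# European Data Format (EDF) I/O.
#
# Minimal 16-bit EDF support: fixed-length data records of one second, all
# channels at the recording's sampling rate. Physical scaling is symmetric
# around zero so the round-trip error is bounded by (physical max)/32767.
# ---------------------------------------------------------------------------

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording as a 16-bit EDF file
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param patient,recording_id free-text EDF header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "scalphfo") {
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  ns <- nrow(rec$signal)
  n_rec <- floor(n_samples(rec) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)", call. = FALSE)
  sig <- rec$signal[, seq_len(n_rec * fs), drop = FALSE]

  phys_max <- pmax(apply(abs(sig), 1, max), 1)
  phys_max <- signif(phys_max * 1.0001, 6)
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(patient, 80), pad_field(recording_id, 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) writeChar(paste0(vapply(vals, pad_field, "", width = width),
                                                collapse = ""), con, eos = NULL)
  fld(rec$channels, 16)                       # label
  fld(rep("AgAgCl electrode", ns), 80)        # transducer
  fld(rep("uV", ns), 8)                       # physical dimension
  fld(-phys_max, 8)                           # physical minimum
  fld(phys_max, 8)                            # physical maximum
  fld(rep(-dig_max, ns), 8)                   # digital minimum
  fld(rep(dig_max, ns), 8)                    # digital maximum
  fld(rep("", ns), 80)                        # prefiltering
  fld(rep(fs, ns), 8)                         # samples per record
  fld(rep("", ns), 32)                        # reserved

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round(sig[ch, idx] / phys_max[ch] * dig_max)
      writeBin(as.integer(pmin(pmax(dig, -dig_max), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a 16-bit EDF file into an `eeg_recording`
#'
#' @param path EDF file path.
#' @return an [eeg_recording()] in referential montage.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported", call. = FALSE)
  fs <- spr[1] / rec_dur

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_max - gain * dig_max
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      sig[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- dig * gain[ch] + offset[ch]
    }
  }
  eeg_recording(sig, fs, channels = labels, montage = "referential")
}

# ---------------------------------------------------------------------------
# Annotation CSVs. Epochs: label, onset_s, offset_s. Spikes: channel, time_s.
# Events: channel, onset_s, offset_s, label. Intervals are half-open
# [onset, offset), all times in seconds from recording start.
# ---------------------------------------------------------------------------

#' Read and write annotation tables
#'
#' Epoch annotations have columns `label`, `onset_s`, `offset_s`; spike
#' annotations have `channel`, `time_s`; event tables have `channel`,
#' `onset_s`, `offset_s`, `label`. All times are seconds from recording
#' start with half-open intervals.
#'
#' @param x data frame to write.
#' @param path CSV path.
#' @return the annotation data frame (readers), or `path` invisibly (writer).
#' @export
write_annotations <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_epochs <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "onset_s", "offset_s")
  if (!all(need %in% names(x)))
    stop("epoch annotations need columns: ", paste(need, collapse = ", "), call. = FALSE)
  check_epochs(x)
  x
}

#' @rdname write_annotations
#' @export
read_spikes <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "time_s")
  if (!all(need %in% names(x)))
    stop("spike annotations need columns: ", paste(need, collapse = ", "), call. = FALSE)
  x
}

check_epochs <- function(epochs) {
  if (nrow(epochs) == 0) return(invisible(epochs))
  bad <- !epochs$label %in% c(epoch_levels(), "unassigned")
  if (any(bad))
    stop("unknown epoch label(s): ", paste(unique(epochs$label[bad]), collapse = ", "),
         call. = FALSE)
  if (any(epochs$offset_s <= epochs$onset_s))
    stop("epoch intervals must have offset_s > onset_s", call. = FALSE)
  o <- order(epochs$onset_s)
  e <- epochs[o, ]
  if (nrow(e) > 1 && any(e$onset_s[-1] < e$offset_s[-nrow(e)]))
    stop("epoch intervals overlap", call. = FALSE)
  invisible(epochs)
}
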