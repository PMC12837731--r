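# Morphological features of detected events: average frequency (from crest
# spacing), supra-threshold duration, baseline-normalised peak-to-peak
# amplitude, and cycle count.

#' Locate crests and troughs of an event waveform
#'
#' Finds alternating local maxima and minima of a band-passed waveform,
#' ignoring wiggles below a prominence floor (a fraction of the waveform's
#' absolute maximum). Crests and troughs interleave by construction.
#'
#' @param x band-passed sample vector (length >= 3).
#' @param fs sampling rate in Hz.
#' @param prominence_frac floor for extrema as a fraction of `max(abs(x))`.
#' @return list with `crest_times`, `trough_times` (seconds from the start
#'   of `x`), and the corresponding sample indices.
#' @export
find_extrema <- function(x, fs, prominence_frac = 0.1) {
  if (length(x) < 3) stop("waveform too short for extrema search", call. = FALSE)
  floor_amp <- prominence_frac * max(abs(x))
  d <- diff(x)
  crest <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  trough <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1
  crest <- crest[x[crest] > floor_amp]
  trough <- trough[x[trough] < -floor_amp]
  if (length(crest) < 2)
    stop("degenerate event: fewer than 2 crests", call. = FALSE)
  list(crest_idx = crest, trough_idx = trough,
       crest_times = (crest - 1) / fs, trough_times = (trough - 1) / fs)
}

#' Event duration from the supra-threshold envelope run
#'
#' Duration is the time the Hilbert envelope stays above the detection
#' threshold: the length of the contiguous supra-threshold run containing
#' the envelope maximum, in milliseconds.
#'
#' @param envelope envelope vector over the event window.
#' @param threshold detection threshold in envelope units.
#' @param fs sampling rate in Hz.
#' @return duration in milliseconds.
#' @export
compute_duration <- function(envelope, threshold, fs) {
  above <- envelope > threshold
  if (!any(above))
    stop("envelope never exceeds the threshold within the event window",
         call. = FALSE)
  runs <- threshold_runs(above)
  peak <- which.max(envelope)
  hit <- which(runs[, "start"] <= peak & runs[, "end"] >= peak)
  if (!length(hit)) hit <- which.max(runs[, "end"] - runs[, "start"])
  unname(runs[hit[1], "end"] - runs[hit[1], "start"] + 1) / fs * 1000
}

#' Average frequency from crest spacing
#'
#' The rate of crest-to-trough oscillation, operationalised as the
#' reciprocal of the mean successive crest-to-crest interval.
#'
#' @param crest_times crest times in seconds (>= 2 crests).
#' @return average frequency in Hz.
#' @export
compute_avg_frequency <- function(crest_times) {
  if (length(crest_times) < 2)
    stop("degenerate event: fewer than 2 crests", call. = FALSE)
  1 / mean(diff(crest_times))
}

#' Amplitude as a z-score against baseline
#'
#' The event's largest peak-to-peak excursion, z-scored against the
#' peak-to-peak values of baseline stretches of the same channel.
#'
#' @param x band-passed event waveform.
#' @param baseline_pp vector of baseline peak-to-peak values (>= 20 values,
#'   positive SD).
#' @return amplitude z-score.
#' @export
compute_amplitude_z <- function(x, baseline_pp) {
  if (length(baseline_pp) < 20)
    stop("baseline needs at least 20 peak-to-peak values", call. = FALSE)
  s <- sd(baseline_pp)
  if (s == 0) stop("baseline peak-to-peak SD is zero", call. = FALSE)
  (diff(range(x)) - mean(baseline_pp)) / s
}

#' Number of cycles in an event
#'
#' Event duration divided by the mean crest-to-crest interval; identically
#' equal to `duration_ms / 1000 * avg_frequency` when both use the same
#' crest statistics.
#'
#' @param duration_ms event duration in milliseconds.
#' @param crest_times crest times in seconds (>= 2 crests).
#' @return cycle count (fractional).
#' @export
compute_n_cycles <- function(duration_ms, crest_times) {
  if (duration_ms <= 0) stop("duration must be positive", call. = FALSE)
  if (length(crest_times) < 2)
    stop("degenerate event: fewer than 2 crests", call. = FALSE)
  (duration_ms / 1000) / mean(diff(crest_times))
}

# Baseline peak-to-peak sample: non-overlapping 100 ms windows over the
# channel's full band-passed signal, excluding detected events +/- 200 ms.
baseline_peak_to_peak <- function(x, fs, event_intervals,
                                  window_ms = 100, pad_ms = 200) {
  n <- length(x)
  w <- round(window_ms / 1000 * fs)
  excluded <- rep(FALSE, n)
  for (i in seq_len(nrow(event_intervals))) {
    a <- max(1, floor((event_intervals[i, 1] - pad_ms / 1000) * fs) + 1)
    b <- min(n, ceiling((event_intervals[i, 2] + pad_ms / 1000) * fs))
    excluded[a:b] <- TRUE
  }
  starts <- seq(1, n - w + 1, by = w)
  pp <- vapply(starts, function(s) {
    idx <- s:(s + w - 1)
    if (any(excluded[idx])) return(NA_real_)
    diff(range(x[idx]))
  }, 0)
  pp[!is.na(pp)]
}

#' Extract the four morphological features for every detected event
#'
#' Computes, per event, the crest-based average frequency, the
#' supra-threshold duration, the baseline-normalised amplitude z-score and
#' the cycle count, using the band-passed average-montage recording. Events
#' whose recomputed frequency leaves the analysis band or whose recomputed
#' cycle count drops below `min_cycles` are dropped (consistency re-check of
#' the event definition), as are events degenerate at the extrema search.
#'
#' @param filtered band-passed [eeg_recording()] (average montage).
#' @param events event data frame from [detect_events()] (its `thresholds`
#'   attribute is reused when present).
#' @param config the [detector_config()] used at detection.
#' @return feature data frame: `event_id`, `channel`, `onset_s`, `offset_s`,
#'   `kind`, `epoch`, `avg_frequency`, `duration`, `amplitude`, `n_cycles`.
#' @export
extract_features <- function(filtered, events, config = detector_config()) {
  stopifnot(inherits(filtered, "eeg_recording"))
  fs <- filtered$sampling_rate
  thresholds <- attr(events, "thresholds")
  out <- list()
  for (ch in unique(events$channel)) {
    x <- filtered$signal[match(ch, filtered$channels), ]
    env <- hilbert_envelope(x)
    thr <- if (!is.null(thresholds) && ch %in% names(thresholds))
      thresholds[[ch]]
    else mean(env) + config$threshold_multiplier * sd(env)
    idx_ev <- which(events$channel == ch)
    ints <- cbind(events$onset_s[idx_ev], events$offset_s[idx_ev])
    base_pp <- baseline_peak_to_peak(x, fs, ints)
    for (i in idx_ev) {
      a <- floor(events$onset_s[i] * fs) + 1
      b <- min(length(x), ceiling(events$offset_s[i] * fs))
      wav <- x[a:b]
      ex <- tryCatch(find_extrema(wav, fs), error = function(e) NULL)
      if (is.null(ex)) next
      dur <- tryCatch(compute_duration(env[a:b], thr, fs),
                      error = function(e) NULL)
      if (is.null(dur)) next
      f <- compute_avg_frequency(ex$crest_times)
      cyc <- compute_n_cycles(dur, ex$crest_times)
      if (f < config$band[1] || f > config$band[2]) next
      if (cyc < config$min_cycles) next
      amp <- tryCatch(compute_amplitude_z(wav, base_pp),
                      error = function(e) NA_real_)
      out[[length(out) + 1]] <- data.frame(
        event_id = i, channel = ch,
        onset_s = events$onset_s[i], offset_s = events$offset_s[i],
        kind = events$kind[i], epoch = events$epoch[i],
        avg_frequency = f, duration = dur, amplitude = amp, n_cycles = cyc,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(event_id = integer(0), channel = character(0),
               onset_s = numeric(0), offset_s = numeric(0),
               kind = character(0), epoch = character(0),
               avg_frequency = numeric(0), duration = numeric(0),
               amplitude = numeric(0), n_cycles = numeric(0),
               stringsAsFactors = FALSE)
  res <- res[order(res$onset_s), ]
  rownames(res) <- NULL
  res
}
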