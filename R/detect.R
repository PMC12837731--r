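# Two-stage Hilbert detector: band-pass filtering, envelope thresholding,
# cycle-rule validation, spike-ripple classification and epoch assignment.

#' Detector configuration
#'
#' @param band ripple band in Hz, default `c(80, 250)`.
#' @param threshold_multiplier number of envelope SDs above the envelope
#'   mean that defines the detection threshold; default 2.
#' @param peak_multiplier number of envelope SDs above the envelope mean the
#'   event's envelope peak must reach; default 5. The lower
#'   `threshold_multiplier` threshold defines the event extent and duration,
#'   while this peak criterion operationalises "clearly distinguishable from
#'   the background" and stands in for the visual review step of a clinical
#'   workflow.
#' @param min_cycles minimum oscillation cycles for a valid event; default 4.
#' @param merge_gap_ms supra-threshold runs closer than this are merged.
#' @param spike_window_ms half-window around a spike peak within which an
#'   event counts as superimposed ("spike ripple").
#' @param max_peak_to_peak amplitude sanity gate in microvolts: band-passed
#'   events with a larger peak-to-peak excursion are discarded as artifacts.
#' @param filter_order FIR order; `NULL` picks `round(0.3 * fs)`, which keeps
#'   the transition band narrower than 10 Hz after forward-backward
#'   application.
#' @return a `detector_config` list.
#' @export
detector_config <- function(band = c(80, 250), threshold_multiplier = 2,
                            peak_multiplier = 5, min_cycles = 4,
                            merge_gap_ms = 10, spike_window_ms = 75,
                            max_peak_to_peak = 500, filter_order = NULL) {
  stopifnot(length(band) == 2, band[1] < band[2], band[1] > 0,
            threshold_multiplier > 0, peak_multiplier >= threshold_multiplier,
            min_cycles >= 1, merge_gap_ms >= 0, spike_window_ms >= 0)
  structure(list(band = band, threshold_multiplier = threshold_multiplier,
                 peak_multiplier = peak_multiplier,
                 min_cycles = min_cycles, merge_gap_ms = merge_gap_ms,
                 spike_window_ms = spike_window_ms,
                 max_peak_to_peak = max_peak_to_peak,
                 filter_order = filter_order),
            class = "detector_config")
}

#' Re-reference a recording to the average montage
#'
#' Subtracts the instantaneous cross-channel mean from every channel. After
#' re-referencing the per-sample mean over channels is zero to numerical
#' precision.
#'
#' @param rec an [eeg_recording()].
#' @return the re-referenced [eeg_recording()] with `montage = "average"`.
#' @export
apply_average_montage <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$signal) < 2)
    stop("average montage needs at least 2 channels", call. = FALSE)
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal), "-")
  rec$montage <- "average"
  rec
}

#' Zero-phase band-pass filter for the ripple band
#'
#' Linear-phase FIR (Hamming-windowed) applied forward-backward, so events
#' keep their timing. Edges are padded by reflection before filtering.
#'
#' @param rec an [eeg_recording()].
#' @param band `c(low, high)` in Hz, inside (0, fs/2).
#' @param order FIR order; `NULL` for the default `round(0.3 * fs)`.
#' @return the filtered [eeg_recording()] (attribute `band` records the
#'   pass band).
#' @export
bandpass_ripple <- function(rec, band = c(80, 250), order = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (band[2] >= fs / 2 || band[1] <= 0 || band[1] >= band[2])
    stop("band must lie strictly inside (0, fs/2)", call. = FALSE)
  if (is.null(order)) order <- round(0.3 * fs)
  if (order %% 2 == 1) order <- order + 1
  b <- signal::fir1(order, band / (fs / 2), type = "pass")
  pad <- min(3 * order, ncol(rec$signal) - 1)
  for (ch in seq_len(nrow(rec$signal))) {
    x <- rec$signal[ch, ]
    xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
    y <- signal::filtfilt(filt = b, a = 1, x = xp)
    rec$signal[ch, ] <- y[(pad + 1):(pad + length(x))]
  }
  attr(rec, "band") <- band
  rec
}

#' Hilbert envelope of a signal
#'
#' Instantaneous amplitude from the magnitude of the analytic signal,
#' computed with the FFT-based one-sided spectrum construction.
#'
#' @param x numeric vector of samples (finite values).
#' @return non-negative envelope vector of the same length.
#' @export
hilbert_envelope <- function(x) {
  if (anyNA(x) || any(!is.finite(x)))
    stop("input contains NA or non-finite samples", call. = FALSE)
  n <- length(x)
  if (n == 0) return(numeric(0))
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

# Contiguous supra-threshold runs as an integer matrix [start, end].
threshold_runs <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

# Merge runs separated by less than max_gap samples, provided the envelope
# valley between them stays above half the threshold: a brief dip within one
# event rejoins, while an independent excursion separated by a return to
# baseline stays separate.
merge_runs <- function(runs, max_gap, env = NULL, thr = 0) {
  if (nrow(runs) < 2) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    gap <- (out[nrow(out), "end"] + 1):max(runs[i, "start"] - 1, out[nrow(out), "end"] + 1)
    deep <- !is.null(env) && min(env[gap]) < 0.5 * thr
    if (runs[i, "start"] - out[nrow(out), "end"] - 1 < max_gap && !deep)
      out[nrow(out), "end"] <- runs[i, "end"]
    else out <- rbind(out, runs[i, , drop = FALSE])
  }
  out
}

# Crest statistics within a candidate run. Cycles are counted as the crests
# of the band-passed waveform lying inside the run's half-peak envelope
# core. The core is amplitude-scale-invariant, so a broadband transient
# whose band-passed image is a short peaked wavelet (filter ringing, a
# "false ripple") contributes only one or two core crests at any amplitude,
# while a sustained oscillation with a flat envelope keeps essentially its
# full crest count. The frequency is the reciprocal mean core crest spacing.
run_crest_stats <- function(x, env, fs) {
  core <- env >= 0.5 * max(env)
  crests <- which(diff(sign(diff(x))) < 0) + 1
  crests <- crests[x[crests] > 0 & core[crests]]
  if (length(crests) < 2)
    return(list(frequency = NA_real_, cycles = length(crests)))
  list(frequency = fs / mean(diff(crests)), cycles = length(crests))
}

# Dominant frequency of the unfiltered segment by zero-padded periodogram,
# searched over [lo, hi] Hz. The wideband view exposes the true centre
# frequency of broadband transients whose band-passed image oscillates
# faster than the underlying event.
segment_peak_frequency <- function(x, fs, lo = 60, hi = 300) {
  hi <- min(hi, fs / 2 - 1)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(x)))
  nfft <- max(4096, 2^ceiling(log2(length(x))))
  X <- fft(c(x * w, rep(0, nfft - length(x))))
  f <- (seq_len(nfft) - 1) * fs / nfft
  sel <- f >= lo & f <= hi
  f[sel][which.max(Mod(X[sel]))]
}

#' Detect candidate HFO events on a band-passed recording
#'
#' Per channel, the detection threshold is the envelope mean plus
#' `threshold_multiplier` envelope SDs, both computed over the entire
#' recording. Contiguous supra-threshold envelope runs become candidates;
#' runs separated by less than `merge_gap_ms` are merged; candidates whose
#' envelope peak stays below the `peak_multiplier` criterion, whose
#' crest-spacing frequency falls outside the band, whose estimated cycle
#' count is below `min_cycles`, or whose peak-to-peak excursion exceeds the
#' artifact gate are discarded. Candidates co-occurring on several channels
#' (interval overlap of at least 50%) are deduplicated, keeping the channel
#' with the largest peak envelope.
#'
#' @param rec a band-passed [eeg_recording()] in average montage.
#' @param config a [detector_config()].
#' @param raw optional unfiltered average-montage [eeg_recording()] (same
#'   geometry as `rec`). When supplied, the candidate's centre frequency is
#'   estimated from the wideband spectral peak of the raw trace, which
#'   correctly rejects broadband transients whose band-passed image rings
#'   faster than the underlying event; otherwise the crest-spacing estimate
#'   of the filtered trace is used.
#' @return data frame of events: `channel`, `onset_s`, `offset_s`,
#'   `peak_envelope`, `est_frequency`, `est_cycles`, `kind`, `epoch`
#'   (the last two unset), with per-channel thresholds in attribute
#'   `thresholds`.
#' @export
detect_events <- function(rec, config = detector_config(), raw = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_samples(rec) == 0) stop("empty recording", call. = FALSE)
  if (rec$montage != "average")
    stop("detection requires the average montage; call apply_average_montage()",
         call. = FALSE)
  if (!is.null(raw)) {
    stopifnot(inherits(raw, "eeg_recording"),
              identical(dim(raw$signal), dim(rec$signal)))
    raw <- raw$signal
  }
  fs <- rec$sampling_rate
  gap <- round(config$merge_gap_ms / 1000 * fs)
  ev <- list()
  thresholds <- setNames(numeric(length(rec$channels)), rec$channels)
  for (ch in seq_along(rec$channels)) {
    x <- rec$signal[ch, ]
    env <- hilbert_envelope(x)
    m <- mean(env); s <- sd(env)
    thr <- m + config$threshold_multiplier * s
    peak_thr <- m + config$peak_multiplier * s
    thresholds[ch] <- thr
    runs <- threshold_runs(env > thr)
    if (nrow(runs) == 0) next
    runs <- merge_runs(runs, gap, env, thr)
    for (i in seq_len(nrow(runs))) {
      idx <- runs[i, "start"]:runs[i, "end"]
      if (max(env[idx]) < peak_thr) next
      cs <- run_crest_stats(x[idx], env[idx], fs)
      if (is.na(cs$frequency)) next
      core_dur <- sum(env[idx] >= 0.5 * max(env[idx])) / fs
      f <- if (!is.null(raw)) {
        segment_peak_frequency(raw[ch, idx], fs,
                               lo = max(30, config$band[1] - 20),
                               hi = config$band[2] + 50)
      } else cs$frequency
      if (f < config$band[1] || f > config$band[2]) next
      # both estimates must reach min_cycles: centre frequency times the
      # half-peak core duration (amplitude-invariant, rejects broadband
      # transients however large) and the core crest count (rejects short
      # noise excursions)
      cycles <- min(core_dur * f, cs$cycles)
      if (cycles < config$min_cycles) next
      if (diff(range(x[idx])) > config$max_peak_to_peak) next
      ev[[length(ev) + 1]] <- data.frame(
        channel = rec$channels[ch],
        onset_s = (runs[i, "start"] - 1) / fs,
        offset_s = runs[i, "end"] / fs,
        peak_envelope = max(env[idx]),
        est_frequency = f, est_cycles = cycles,
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(channel = character(0), onset_s = numeric(0),
               offset_s = numeric(0), peak_envelope = numeric(0),
               est_frequency = numeric(0), est_cycles = numeric(0),
               stringsAsFactors = FALSE)
  events <- dedup_events(events)
  events$kind <- rep(NA_character_, nrow(events))
  events$epoch <- rep("unassigned", nrow(events))
  rownames(events) <- NULL
  attr(events, "thresholds") <- thresholds
  events
}

# Cross-channel deduplication: merge events whose intervals overlap by at
# least 50% of either interval, keeping the one with the largest peak
# envelope. The study counts events, not channel-events.
dedup_events <- function(events) {
  if (nrow(events) < 2) return(events)
  o <- order(events$onset_s)
  events <- events[o, ]
  keep <- rep(TRUE, nrow(events))
  for (i in seq_len(nrow(events) - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):nrow(events)) {
      if (events$onset_s[j] >= events$offset_s[i]) break
      ov <- min(events$offset_s[i], events$offset_s[j]) -
        max(events$onset_s[i], events$onset_s[j])
      li <- events$offset_s[i] - events$onset_s[i]
      lj <- events$offset_s[j] - events$onset_s[j]
      if (ov >= 0.5 * min(li, lj)) {
        if (events$peak_envelope[j] > events$peak_envelope[i]) {
          keep[i] <- FALSE
        } else keep[j] <- FALSE
      }
    }
  }
  events[keep, , drop = FALSE]
}

#' Classify events as spike ripples or isolated ripples
#'
#' An event is a spike ripple iff its interval intersects
#' `[spike - window, spike + window]` for any annotated spike; otherwise it
#' is an isolated ripple. Downstream phenotyping keeps spike ripples only.
#'
#' @param events event data frame from [detect_events()].
#' @param spikes data frame `channel`, `time_s` of spike peaks (may be empty
#'   or `NULL`).
#' @param spike_window_ms half-window in milliseconds.
#' @return the event data frame with `kind` set to `"spike_ripple"` or
#'   `"ripple"`.
#' @export
classify_spike_ripple <- function(events, spikes, spike_window_ms = 75) {
  w <- spike_window_ms / 1000
  if (is.null(spikes) || nrow(spikes) == 0) {
    events$kind <- rep("ripple", nrow(events))
    return(events)
  }
  events$kind <- vapply(seq_len(nrow(events)), function(i) {
    hit <- any(events$onset_s[i] <= spikes$time_s + w &
               events$offset_s[i] >= spikes$time_s - w)
    if (hit) "spike_ripple" else "ripple"
  }, "")
  events
}

#' Assign events to annotated epochs
#'
#' Each event receives the label of the epoch interval containing its
#' midpoint, or `"unassigned"` if no interval does.
#'
#' @param events event data frame.
#' @param epochs data frame `label`, `onset_s`, `offset_s`, non-overlapping.
#' @return the event data frame with `epoch` filled in.
#' @export
assign_epochs <- function(events, epochs) {
  check_epochs(epochs)
  mid <- (events$onset_s + events$offset_s) / 2
  events$epoch <- vapply(mid, function(m) {
    hit <- which(epochs$onset_s <= m & m < epochs$offset_s)
    if (length(hit)) epochs$label[hit[1]] else "unassigned"
  }, "")
  events
}

#' Run the full detection stage on a raw recording
#'
#' Convenience wrapper: average montage, ripple band-pass, envelope
#' detection, spike-ripple classification and epoch assignment.
#'
#' @param rec a raw [eeg_recording()].
#' @param config a [detector_config()].
#' @param spikes,epochs annotation data frames (optional).
#' @return event data frame; attribute `filtered` holds the band-passed
#'   average-montage recording for feature extraction.
#' @export
detect_hfo <- function(rec, config = detector_config(), spikes = NULL,
                       epochs = NULL) {
  avg <- apply_average_montage(rec)
  filt <- bandpass_ripple(avg, config$band, config$filter_order)
  events <- detect_events(filt, config, raw = avg)
  events <- classify_spike_ripple(events, spikes, config$spike_window_ms)
  if (!is.null(epochs)) events <- assign_epochs(events, epochs)
  attr(events, "filtered") <- filt
  events
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement between two categorical rating vectors, with
#' expected agreement from the marginal products.
#'
#' @param ratings_a,ratings_b equal-length label vectors.
#' @return kappa statistic in \[-1, 1\].
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 1)
    stop("rating vectors must have equal positive length", call. = FALSE)
  lev <- union(unique(ratings_a), unique(ratings_b))
  a <- factor(ratings_a, levels = lev)
  b <- factor(ratings_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}
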