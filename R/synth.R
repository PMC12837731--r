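# Synthetic scalp EEG scenes and feature-space mixtures.
#
# The generator provides the ground truth the detector and feature stages are
# validated against: pink-noise background, 3-Hz spike-wave trains in ictal
# intervals, biphasic interictal spikes, and taper-windowed ripple bursts.

#' Specify a synthetic ripple burst
#'
#' @param channel electrode label the burst is injected on.
#' @param onset onset in seconds from recording start.
#' @param center_frequency burst frequency in Hz, within 80-250.
#' @param duration_ms burst duration in milliseconds.
#' @param amplitude sinusoid amplitude in microvolts.
#' @param taper_fraction Tukey-window taper fraction in (0, 1]; the default
#'   0.25 keeps a flat-envelope core so the supra-threshold duration is well
#'   defined.
#' @return a `burst_spec` list. The implied cycle count is
#'   `center_frequency * duration_ms / 1000`; bursts below 4 cycles are valid
#'   specs but are expected to be rejected by the detector's cycle rule.
#' @export
burst_spec <- function(channel, onset, center_frequency, duration_ms,
                       amplitude, taper_fraction = 0.25) {
  stopifnot(center_frequency >= 80, center_frequency <= 250,
            duration_ms > 0, amplitude > 0,
            taper_fraction > 0, taper_fraction <= 1)
  structure(list(channel = channel, onset = onset,
                 center_frequency = center_frequency,
                 duration_ms = duration_ms, amplitude = amplitude,
                 taper_fraction = taper_fraction),
            class = "burst_spec")
}

#' Specify a synthetic EEG scene
#'
#' @param duration_s total recording length in seconds.
#' @param n_channels number of channels (default 19, the 10-20 analysis set).
#' @param sampling_rate sampling rate in Hz (default 1024).
#' @param epochs data frame `label`, `onset_s`, `offset_s` with
#'   non-overlapping intervals; ictal intervals must last at least 3 s.
#' @param spikes data frame `channel`, `time_s` of spike (IED) peak times.
#' @param bursts list of [burst_spec()] objects.
#' @param noise_exponent spectral slope a of the 1/f^a background.
#' @param noise_rms per-channel background RMS in microvolts.
#' @param seed integer seed; mandatory for reproducibility.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(duration_s, n_channels = 19, sampling_rate = 1024,
                       epochs = NULL, spikes = NULL, bursts = list(),
                       noise_exponent = 1, noise_rms = 10, seed) {
  if (missing(seed)) stop("`seed` is mandatory in a scene spec", call. = FALSE)
  if (duration_s <= 0 || sampling_rate < 512 || n_channels < 1)
    stop("invalid scene: need duration_s > 0, sampling_rate >= 512, n_channels >= 1",
         call. = FALSE)
  if (!is.null(epochs)) {
    check_epochs(epochs)
    ict <- epochs$label == "ictal_active"
    if (any(ict) && any(epochs$offset_s[ict] - epochs$onset_s[ict] < 3))
      stop("ictal epochs must last at least 3 s", call. = FALSE)
    if (any(epochs$offset_s > duration_s))
      stop("epoch intervals exceed the recording length", call. = FALSE)
  }
  for (b in bursts) {
    if (!inherits(b, "burst_spec")) stop("`bursts` must be burst_spec objects", call. = FALSE)
    if (b$onset < 0 || b$onset + b$duration_ms / 1000 > duration_s)
      stop("burst outside recording bounds", call. = FALSE)
  }
  structure(list(duration_s = duration_s, n_channels = n_channels,
                 sampling_rate = sampling_rate, epochs = epochs,
                 spikes = spikes, bursts = bursts,
                 noise_exponent = noise_exponent, noise_rms = noise_rms,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate the pink-noise background of a scene
#'
#' Draws Gaussian noise shaped to a 1/f^a power spectrum by Fourier-domain
#' filtering, independently per channel, scaled to the scene's per-channel
#' RMS with zero mean. Bitwise reproducible given the scene seed.
#'
#' @param scene a [scene_spec()].
#' @return an [eeg_recording()] in referential montage.
#' @export
generate_background <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  n <- round(scene$duration_s * scene$sampling_rate)
  with_seed(scene$seed, {
    sig <- matrix(0, scene$n_channels, n)
    for (ch in seq_len(scene$n_channels))
      sig[ch, ] <- pink_noise(n, scene$sampling_rate,
                              scene$noise_exponent, scene$noise_rms)
    eeg_recording(sig, scene$sampling_rate,
                  channels = scene_channels(scene$n_channels))
  })
}

scene_channels <- function(n) {
  std <- ten_twenty_channels()
  if (n <= length(std)) std[seq_len(n)] else c(std, paste0("X", seq_len(n - length(std))))
}

pink_noise <- function(n, fs, exponent, rms) {
  w <- rnorm(n)
  if (exponent == 0) return((w - mean(w)) / sd(w) * rms)
  f <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  shape <- c(0, f[-1]^(-exponent / 2))          # zero out DC
  spec <- fft(w)
  half <- shape
  full <- c(half, rev(half[2:(n - length(half) + 1)]))
  x <- Re(fft(spec * full, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sd(x) * rms
}

tukey_window <- function(n, r) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < r / 2
  hi <- t > 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / r + 1)))
  w
}

#' Inject a ripple burst into a recording
#'
#' Adds a Tukey-tapered sinusoid at the specified centre frequency to the named
#' channel and returns the modified recording together with a ground-truth
#' event row (expected cycles = frequency x duration).
#'
#' @param rec an [eeg_recording()].
#' @param spec a [burst_spec()].
#' @return list with elements `recording` and `truth` (one-row data frame:
#'   channel, onset_s, offset_s, center_frequency, amplitude, n_cycles,
#'   detectable).
#' @export
inject_burst <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "burst_spec"))
  fs <- rec$sampling_rate
  dur <- spec$duration_ms / 1000
  if (spec$onset < 0 || spec$onset + dur > duration_s(rec))
    stop("burst onset/duration outside recording bounds", call. = FALSE)
  ch <- match(spec$channel, rec$channels)
  if (is.na(ch)) stop("unknown channel: ", spec$channel, call. = FALSE)
  i0 <- round(spec$onset * fs) + 1
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  wave <- spec$amplitude * tukey_window(n, spec$taper_fraction) *
    sin(2 * pi * spec$center_frequency * t)
  rec$signal[ch, i0:(i0 + n - 1)] <- rec$signal[ch, i0:(i0 + n - 1)] + wave
  cycles <- spec$center_frequency * dur
  truth <- data.frame(channel = spec$channel, onset_s = spec$onset,
                      offset_s = spec$onset + dur,
                      center_frequency = spec$center_frequency,
                      amplitude = spec$amplitude, n_cycles = cycles,
                      detectable = cycles >= 4,
                      stringsAsFactors = FALSE)
  list(recording = rec, truth = truth)
}

#' Inject a biphasic interictal spike
#'
#' Adds a biphasic transient (sharp negative phase followed by a slower
#' positive phase, 3:4 duration split) centred at `time` on one channel.
#' Samples outside `time +/- width_ms/2 * (7/3)` are untouched; the sharp
#' phase carries the full amplitude.
#'
#' @param rec an [eeg_recording()].
#' @param channel electrode label.
#' @param time spike peak time in seconds.
#' @param amplitude peak amplitude in microvolts (0 leaves the recording
#'   unchanged).
#' @param width_ms sharp-phase width in milliseconds, 20-70.
#' @return the modified [eeg_recording()].
#' @export
inject_spike <- function(rec, channel, time, amplitude = 80, width_ms = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (width_ms < 20 || width_ms > 70)
    stop("spike width must lie in the 20-70 ms IED range", call. = FALSE)
  if (amplitude == 0) return(rec)
  fs <- rec$sampling_rate
  ch <- match(channel, rec$channels)
  if (is.na(ch)) stop("unknown channel: ", channel, call. = FALSE)
  n_sharp <- round(width_ms / 1000 * fs)
  n_slow <- round(width_ms * 4 / 3 / 1000 * fs)
  tpl <- c(-amplitude * sin(pi * seq_len(n_sharp) / (n_sharp + 1)),
           0.4 * amplitude * sin(pi * seq_len(n_slow) / (n_slow + 1)))
  i0 <- round(time * fs) + 1 - round(n_sharp / 2)
  if (i0 < 1 || i0 + length(tpl) - 1 > n_samples(rec))
    stop("spike outside recording bounds", call. = FALSE)
  idx <- i0:(i0 + length(tpl) - 1)
  rec$signal[ch, idx] <- rec$signal[ch, idx] + tpl
  rec
}

#' Inject a generalized spike-wave discharge train
#'
#' Adds a periodic spike-plus-slow-wave template at `swd_frequency` on all
#' channels within the interval, emulating the regular ~3 Hz generalized
#' discharges of an absence seizure.
#'
#' @param rec an [eeg_recording()].
#' @param interval `c(onset_s, offset_s)`; must span at least 3 s (the
#'   minimum seizure duration for inclusion).
#' @param swd_frequency discharge rate in Hz, 2.5-5.5 (2.5-4 covers childhood
#'   absence epilepsy, 3-5.5 juvenile).
#' @param amplitude slow-wave amplitude in microvolts.
#' @return list with `recording` and `complexes` (data frame of spike-wave
#'   complex onset times).
#' @export
inject_swd_train <- function(rec, interval, swd_frequency = 3, amplitude = 150) {
  stopifnot(inherits(rec, "eeg_recording"), length(interval) == 2)
  if (diff(interval) < 3)
    stop("ictal interval must last at least 3 s", call. = FALSE)
  if (swd_frequency < 2.5 || swd_frequency > 5.5)
    stop("swd_frequency must lie in 2.5-5.5 Hz", call. = FALSE)
  fs <- rec$sampling_rate
  period <- 1 / swd_frequency
  n_p <- round(period * fs)
  n_spike <- max(3L, round(0.25 * n_p))
  n_wave <- n_p - n_spike
  tpl <- c(-1.6 * amplitude * sin(pi * seq_len(n_spike) / (n_spike + 1)),
           amplitude * sin(pi * seq_len(n_wave) / (n_wave + 1)))
  onsets <- seq(interval[1], interval[2] - period, by = period)
  for (t0 in onsets) {
    i0 <- round(t0 * fs) + 1
    idx <- i0:(i0 + n_p - 1)
    idx <- idx[idx <= n_samples(rec)]
    rec$signal[, idx] <- sweep(rec$signal[, idx, drop = FALSE], 2,
                               tpl[seq_along(idx)], "+")
  }
  list(recording = rec,
       complexes = data.frame(time_s = onsets))
}

#' Simulate a fully annotated scene
#'
#' Builds the background, injects a spike-wave train over every ictal epoch,
#' then the scene's spikes and bursts, and returns the recording alongside
#' the complete ground truth.
#'
#' @param scene a [scene_spec()].
#' @return list: `recording`, `truth` (list with `bursts`, `spikes`,
#'   `epochs`, `swd_complexes`).
#' @export
simulate_scene <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  rec <- generate_background(scene)
  swd <- data.frame(time_s = numeric(0))
  if (!is.null(scene$epochs)) {
    ict <- scene$epochs[scene$epochs$label == "ictal_active", , drop = FALSE]
    for (i in seq_len(nrow(ict))) {
      out <- inject_swd_train(rec, c(ict$onset_s[i], ict$offset_s[i]))
      rec <- out$recording
      swd <- rbind(swd, out$complexes)
    }
  }
  if (!is.null(scene$spikes)) {
    for (i in seq_len(nrow(scene$spikes)))
      rec <- inject_spike(rec, scene$spikes$channel[i], scene$spikes$time_s[i])
  }
  bursts <- NULL
  for (b in scene$bursts) {
    out <- inject_burst(rec, b)
    rec <- out$recording
    bursts <- rbind(bursts, out$truth)
  }
  list(recording = rec,
       truth = list(bursts = bursts, spikes = scene$spikes,
                    epochs = scene$epochs, swd_complexes = swd))
}

#' Build a detection fixture scene with planted spike-ripple bursts
#'
#' Generates a pink-noise scene and plants `n_bursts` ripple bursts at a
#' given signal-to-noise ratio (burst amplitude divided by the RMS of the
#' band-passed background), each co-onset with a biphasic spike so the
#' detected events classify as spike ripples. Burst frequencies, durations
#' and channels are drawn uniformly from the given ranges; onsets are spaced
#' at least 1 s apart and kept clear of the recording edges. Optionally
#' plants additional 3-cycle bursts that a 4-cycle detector must reject.
#'
#' @param n_bursts number of detectable bursts.
#' @param snr burst amplitude over band-passed background RMS (default 6).
#' @param duration_s recording length (default `max(30, n_bursts + 5)`).
#' @param freq_range,dur_range_ms uniform sampling ranges for burst
#'   frequency (Hz) and duration (ms); combinations below `min_cycles + 1`
#'   cycles are redrawn so every planted burst is comfortably detectable.
#' @param n_subthreshold number of extra 3-cycle bursts (ground truth flags
#'   them non-detectable).
#' @param epochs optional epoch annotation data frame for the scene.
#' @param with_spikes plant a spike under each burst (default TRUE).
#' @param seed integer seed.
#' @param n_channels,sampling_rate scene geometry.
#' @return list: `scene` (the [scene_spec()]), `recording`, `truth` (as from
#'   [simulate_scene()]), and `band_rms` (the background RMS used for SNR
#'   scaling).
#' @export
make_detection_scene <- function(n_bursts, snr = 6, duration_s = NULL,
                                 freq_range = c(100, 240),
                                 dur_range_ms = c(30, 90),
                                 n_subthreshold = 0, epochs = NULL,
                                 with_spikes = TRUE, seed = 1,
                                 n_channels = 19, sampling_rate = 1024) {
  if (is.null(duration_s)) duration_s <- max(30, n_bursts + 5)
  base <- scene_spec(duration_s = duration_s, n_channels = n_channels,
                     sampling_rate = sampling_rate, seed = seed)
  bg <- generate_background(base)
  band_rms <- sd(bandpass_ripple(apply_average_montage(bg))$signal[1, ])
  chans <- scene_channels(n_channels)
  n_total <- n_bursts + n_subthreshold
  with_seed(derive_seed(seed, "scene_plan"), {
    onsets <- 1 + (seq_len(n_total) - 1) * (duration_s - 2) / max(1, n_total) +
      runif(n_total, 0, 0.2)
    bursts <- vector("list", n_total)
    spikes <- NULL
    for (i in seq_len(n_total)) {
      if (i <= n_bursts) {
        repeat {
          f <- runif(1, freq_range[1], freq_range[2])
          d <- runif(1, dur_range_ms[1], dur_range_ms[2])
          if (f * d / 1000 >= 5) break
        }
      } else {
        f <- 80
        d <- 3 / f * 1000                     # exactly 3 cycles
      }
      ch <- sample(chans, 1)
      bursts[[i]] <- burst_spec(ch, onsets[i], f, d, amplitude = snr * band_rms)
      if (with_spikes && i <= n_bursts)
        spikes <- rbind(spikes, data.frame(channel = ch,
                                           time_s = onsets[i] + d / 2000,
                                           stringsAsFactors = FALSE))
    }
    scene <- scene_spec(duration_s = duration_s, n_channels = n_channels,
                        sampling_rate = sampling_rate, epochs = epochs,
                        spikes = spikes, bursts = bursts, seed = seed)
    sim <- simulate_scene(scene)
    list(scene = scene, recording = sim$recording, truth = sim$truth,
         band_rms = band_rms)
  })
}

# ---------------------------------------------------------------------------
# Feature-space mixture generator.
# ---------------------------------------------------------------------------

#' Specify a feature-space mixture
#'
#' Each component draws the four HFO features independently: average
#' frequency and duration from normal distributions, amplitude (z-score) and
#' cycle count from log-normals parameterised by median and interquartile
#' range.
#'
#' @param components data frame with one row per component and columns
#'   `size`, `freq_mean`, `freq_sd` (Hz), `dur_mean`, `dur_sd` (ms),
#'   `amp_median`, `amp_q25`, `amp_q75` (z-score), `cyc_median`, `cyc_q25`,
#'   `cyc_q75` (cycles).
#' @param seed integer seed; mandatory.
#' @return a `mixture_spec` list.
#' @export
mixture_spec <- function(components, seed) {
  if (missing(seed)) stop("`seed` is mandatory in a mixture spec", call. = FALSE)
  need <- c("size", "freq_mean", "freq_sd", "dur_mean", "dur_sd",
            "amp_median", "amp_q25", "amp_q75",
            "cyc_median", "cyc_q25", "cyc_q75")
  if (!all(need %in% names(components)))
    stop("mixture components need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(components$size < 1))
    stop("component sizes must be >= 1", call. = FALSE)
  disp <- components[c("freq_sd", "dur_sd")]
  if (any(unlist(disp) < 0) ||
      any(components$amp_q75 < components$amp_q25) ||
      any(components$cyc_q75 < components$cyc_q25))
    stop("dispersions must be non-negative with q75 >= q25", call. = FALSE)
  structure(list(components = components, seed = as.integer(seed)),
            class = "mixture_spec")
}

# log-normal location/scale from a printed median and IQR:
# median = exp(mu); q75/q25 = exp(2 * qnorm(0.75) * sigma)
lnorm_from_quantiles <- function(med, q25, q75) {
  list(meanlog = log(med),
       sdlog = if (q75 > q25) log(q75 / q25) / (2 * qnorm(0.75)) else 0)
}

#' The packaged three-phenotype feature mixture
#'
#' Default mixture emulating the three scalp-HFO phenotypes observed in
#' pediatric absence epilepsy, with component sizes 65/70/28 (n = 163):
#' component 1 short-duration / low-amplitude events (duration 35.3 +/- 7.3
#' ms, amplitude median 6.2 \[5.6-7.4\]), component 2 low-frequency events
#' (118.1 +/- 10.5 Hz), component 3 long-duration / high-cycle events
#' (duration 70.2 +/- 15.4 ms, cycles median 9.8 \[8.8-11.5\]). Cells not
#' pinned down by those phenotype summaries are filled from the epoch-level
#' feature statistics of the states each phenotype dominates (see the
#' methods vignette).
#'
#' @param seed integer seed.
#' @return a [mixture_spec()].
#' @export
hfo_mixture_fixture <- function(seed) {
  comp <- data.frame(
    size      = c(65, 70, 28),
    freq_mean = c(145.0, 118.1, 151.5),
    freq_sd   = c(12.0, 10.5, 12.0),
    dur_mean  = c(35.3, 44.7, 70.2),
    dur_sd    = c(7.3, 12.0, 15.4),
    amp_median = c(6.2, 8.9, 6.2),
    amp_q25   = c(5.6, 6.9, 5.3),
    amp_q75   = c(7.4, 11.7, 8.4),
    cyc_median = c(5.1, 5.3, 9.8),
    cyc_q25   = c(4.6, 4.4, 8.8),
    cyc_q75   = c(5.7, 6.1, 11.5)
  )
  mixture_spec(comp, seed = seed)
}

#' Draw a raw feature table from a mixture
#'
#' @param mix a [mixture_spec()].
#' @return list: `features` (data frame `avg_frequency`, `duration`,
#'   `amplitude`, `n_cycles`, rows shuffled) and `labels` (true component of
#'   each row).
#' @export
generate_feature_table <- function(mix) {
  stopifnot(inherits(mix, "mixture_spec"))
  cmp <- mix$components
  with_seed(mix$seed, {
    rows <- lapply(seq_len(nrow(cmp)), function(i) {
      n <- cmp$size[i]
      amp <- lnorm_from_quantiles(cmp$amp_median[i], cmp$amp_q25[i], cmp$amp_q75[i])
      cyc <- lnorm_from_quantiles(cmp$cyc_median[i], cmp$cyc_q25[i], cmp$cyc_q75[i])
      data.frame(
        avg_frequency = rnorm(n, cmp$freq_mean[i], cmp$freq_sd[i]),
        duration = rnorm(n, cmp$dur_mean[i], cmp$dur_sd[i]),
        amplitude = exp(rnorm(n, amp$meanlog, amp$sdlog)),
        n_cycles = exp(rnorm(n, cyc$meanlog, cyc$sdlog)),
        component = i
      )
    })
    tab <- do.call(rbind, rows)
    ord <- sample.int(nrow(tab))
    tab <- tab[ord, ]
    rownames(tab) <- NULL
    list(features = tab[, c("avg_frequency", "duration", "amplitude", "n_cycles")],
         labels = tab$component)
  })
}

# ---------------------------------------------------------------------------
# YAML configuration blocks.
# ---------------------------------------------------------------------------

#' Read a scene or mixture spec from a YAML file
#'
#' Scene YAML keys mirror [scene_spec()] arguments (`epochs`, `spikes` and
#' `bursts` as lists of records); mixture YAML holds `components` as a list
#' of records plus `seed`. The seed key is mandatory in both.
#'
#' @param path YAML file path.
#' @return a [scene_spec()] or [mixture_spec()].
#' @export
read_scene_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("scene config must set `seed`", call. = FALSE)
  to_df <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  bursts <- lapply(y$bursts, function(b) do.call(burst_spec, b))
  scene_spec(duration_s = y$duration_s,
             n_channels = y$n_channels %||% 19,
             sampling_rate = y$sampling_rate %||% 1024,
             epochs = to_df(y$epochs), spikes = to_df(y$spikes),
             bursts = bursts,
             noise_exponent = y$noise_exponent %||% 1,
             noise_rms = y$noise_rms %||% 10,
             seed = y$seed)
}

#' @rdname read_scene_config
#' @export
read_mixture_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("mixture config must set `seed`", call. = FALSE)
  comp <- do.call(rbind, lapply(y$components, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  mixture_spec(comp, seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
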