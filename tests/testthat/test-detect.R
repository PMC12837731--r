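test_that("average montage removes the common mode exactly", {
  n <- 1024
  sig <- matrix(rep(sin(2 * pi * 5 * (1:n) / 1024), each = 19), 19, n, byrow = FALSE)
  rec <- eeg_recording(sig, 1024)
  avg <- apply_average_montage(rec)
  expect_lt(max(abs(avg$signal)), 1e-12)
  expect_equal(avg$montage, "average")

  # per-sample channel mean is zero for arbitrary input
  set.seed(1)
  rec2 <- eeg_recording(matrix(rnorm(19 * n), 19, n), 1024)
  avg2 <- apply_average_montage(rec2)
  expect_lt(max(abs(colMeans(avg2$signal))), 1e-12)

  # single-channel perturbation of a zero recording: (1 - 1/19) scaling
  z <- matrix(0, 19, n)
  z[5, 100] <- 10
  avg3 <- apply_average_montage(eeg_recording(z, 1024))
  expect_equal(unname(avg3$signal[5, 100]), 10 * (1 - 1 / 19))
  expect_equal(unname(avg3$signal[4, 100]), -10 / 19)

  expect_error(apply_average_montage(eeg_recording(matrix(0, 1, 10), 1024, "Cz")),
               "2 channels")
})

test_that("ripple band-pass keeps in-band tones, rejects out-of-band, preserves timing", {
  fs <- 1024
  t <- (0:(6 * fs - 1)) / fs
  mk <- function(f) eeg_recording(rbind(sin(2 * pi * f * t), sin(2 * pi * f * t)),
                                  fs, c("Fp1", "Fp2"))
  inband <- bandpass_ripple(mk(150))
  expect_gt(max(abs(inband$signal[1, (2 * fs):(4 * fs)])), 0.95)
  out <- bandpass_ripple(mk(30))
  expect_lt(max(abs(out$signal[1, (2 * fs):(4 * fs)])), 0.01)

  # zero-phase: the envelope plateau of an injected burst stays centred on
  # the burst midpoint (the Tukey top is flat, so use the centre of the
  # supra-half-maximum region rather than a single argmax)
  silent <- eeg_recording(matrix(0, 2, 10 * fs), fs, c("Fp1", "Fp2"))
  inj <- inject_burst(silent, burst_spec("Fp1", 5.000, 150, 60, amplitude = 10))
  filt <- bandpass_ripple(inj$recording)
  env <- hilbert_envelope(filt$signal[1, ])
  core <- which(env >= 0.5 * max(env))
  t_center <- (mean(range(core)) - 1) / fs
  expect_lt(abs(t_center - (5.000 + 0.030)), 0.005)

  expect_error(bandpass_ripple(mk(100), band = c(80, 600)), "fs/2")
})

test_that("the Hilbert envelope tracks instantaneous amplitude", {
  fs <- 1024
  t <- (0:(2 * fs - 1)) / fs
  x <- 3 * sin(2 * pi * 120 * t)
  env <- hilbert_envelope(x)
  central <- env[round(0.05 * length(x)):round(0.95 * length(x))]
  expect_true(all(abs(central - 3) / 3 < 0.02))

  expect_identical(hilbert_envelope(rep(0, 100)), rep(0, 100))

  # slowly varying amplitude modulation is recovered
  A <- 2 + sin(2 * pi * 2 * t)
  xm <- A * sin(2 * pi * 150 * t)
  em <- hilbert_envelope(xm)
  mid <- round(0.1 * length(x)):round(0.9 * length(x))
  expect_lt(max(abs(em[mid] - A[mid]) / A[mid]), 0.05)

  expect_error(hilbert_envelope(c(1, NA, 2)), "NA")
})

test_that("a clean high-SNR burst is detected once with accurate boundaries", {
  fx <- make_detection_scene(n_bursts = 1, snr = 8, duration_s = 20, seed = 21,
                             freq_range = c(150, 150), dur_range_ms = c(60, 60))
  ev <- detect_hfo(fx$recording, spikes = fx$truth$spikes)
  expect_equal(nrow(ev), 1)
  tr <- fx$truth$bursts
  expect_lt(abs(ev$onset_s - tr$onset_s), 0.010)
  expect_lt(abs(ev$offset_s - tr$offset_s), 0.010)
  expect_equal(ev$kind, "spike_ripple")
})

test_that("raising the threshold multiplier never increases the event count", {
  fx <- make_detection_scene(n_bursts = 6, snr = 6, seed = 31)
  avg <- apply_average_montage(fx$recording)
  filt <- bandpass_ripple(avg)
  counts <- vapply(c(1, 2, 3, 5, 50), function(m)
    nrow(detect_events(filt, detector_config(threshold_multiplier = m,
                                             peak_multiplier = max(m, 5)),
                       raw = avg)), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0L)         # infinite-threshold limit
})

test_that("detection is idempotent and translation-equivariant", {
  fx <- make_detection_scene(n_bursts = 4, snr = 7, duration_s = 24, seed = 41)
  avg <- apply_average_montage(fx$recording)
  filt <- bandpass_ripple(avg)
  e1 <- detect_events(filt, raw = avg)
  e2 <- detect_events(filt, raw = avg)
  expect_identical(e1, e2)

  # circular shift by 2 s shifts all onsets by 2 s
  sh <- round(2 * 1024)
  shift_rec <- function(r) { r$signal <- r$signal[, c((ncol(r$signal) - sh + 1):ncol(r$signal), 1:(ncol(r$signal) - sh))]; r }
  avg_s <- shift_rec(avg)
  filt_s <- bandpass_ripple(avg_s)
  e3 <- detect_events(filt_s, raw = avg_s)
  interior <- e1$onset_s > 1 & e1$offset_s < 21
  expect_equal(nrow(e3), nrow(e1))
  expect_equal(sort(e3$onset_s[e3$onset_s > 2 & e3$onset_s < 23]),
               sort(e1$onset_s[interior]) + 2, tolerance = 0.005)
})

test_that("spike-ripple classification follows the co-occurrence window", {
  ev <- data.frame(channel = "C3", onset_s = 4.99, offset_s = 5.04,
                   peak_envelope = 1, est_frequency = 150, est_cycles = 6,
                   kind = NA_character_, epoch = "unassigned",
                   stringsAsFactors = FALSE)
  spikes <- data.frame(channel = "C3", time_s = 5.00)
  out <- classify_spike_ripple(ev, spikes, spike_window_ms = 75)
  expect_equal(out$kind, "spike_ripple")

  # event just outside the window is an isolated ripple
  far <- classify_spike_ripple(transform(ev, onset_s = 5.2, offset_s = 5.25),
                               spikes, spike_window_ms = 75)
  expect_equal(far$kind, "ripple")

  # no spikes: everything is a ripple
  none <- classify_spike_ripple(ev, NULL)
  expect_equal(none$kind, "ripple")

  # scene with a known number of co-onset spikes
  fx <- make_detection_scene(n_bursts = 8, snr = 7, seed = 51)
  ev8 <- detect_hfo(fx$recording, spikes = fx$truth$spikes[1:5, ])
  matched <- vapply(seq_len(nrow(ev8)), function(j)
    any(ev8$onset_s[j] < fx$truth$bursts$offset_s[1:5] &
        ev8$offset_s[j] > fx$truth$bursts$onset_s[1:5]), TRUE)
  expect_true(all(ev8$kind[matched] == "spike_ripple"))
  expect_true(all(ev8$kind[!matched] == "ripple"))
})

test_that("epoch assignment uses the event midpoint and flags overlap", {
  epochs <- data.frame(label = c("ictal_active", "interictal_active"),
                       onset_s = c(0, 20), offset_s = c(10, 30))
  ev <- data.frame(channel = "C3", onset_s = c(4, 15, 21), offset_s = c(5, 16, 22),
                   peak_envelope = 1, est_frequency = 150, est_cycles = 6,
                   kind = "spike_ripple", epoch = "unassigned",
                   stringsAsFactors = FALSE)
  out <- assign_epochs(ev, epochs)
  expect_equal(out$epoch, c("ictal_active", "unassigned", "interictal_active"))

  bad <- data.frame(label = c("ictal_active", "interictal_active"),
                    onset_s = c(0, 5), offset_s = c(10, 30))
  expect_error(assign_epochs(ev, bad), "overlap")

  # planned per-epoch counts are recovered on a scene
  epochs2 <- data.frame(label = c("ictal_active", "interictal_active",
                                  "interictal_seizure_free"),
                        onset_s = c(0, 12, 24), offset_s = c(10, 22, 34))
  fx <- make_detection_scene(n_bursts = 9, snr = 8, duration_s = 34,
                             epochs = epochs2, seed = 61, with_spikes = FALSE)
  ev2 <- assign_epochs(detect_hfo(fx$recording), epochs2)
  truth_counts <- table(cut(with(fx$truth$bursts, (onset_s + offset_s) / 2),
                            c(0, 10, 12, 22, 24, 34),
                            labels = c("ict", "gap1", "ia", "gap2", "sf")))
  got <- table(factor(ev2$epoch, levels = c("ictal_active", "interictal_active",
                                            "interictal_seizure_free", "unassigned")))
  expect_equal(unname(got[["ictal_active"]]), unname(truth_counts[["ict"]]))
  expect_equal(unname(got[["interictal_active"]]), unname(truth_counts[["ia"]]))
  expect_equal(unname(got[["interictal_seizure_free"]]), unname(truth_counts[["sf"]]))
})

test_that("Cohen's kappa matches hand-computed values and its limits", {
  a <- rep(c("x", "y"), each = 50)
  expect_equal(cohen_kappa(a, a), 1)

  # independent ratings at large n: kappa near 0
  set.seed(8)
  r1 <- sample(c("x", "y"), 20000, replace = TRUE)
  r2 <- sample(c("x", "y"), 20000, replace = TRUE)
  expect_lt(abs(cohen_kappa(r1, r2)), 0.03)

  # 2x2 agreement table (40, 10; 5, 45): po = .85, pe = .5, kappa = .7
  ra <- c(rep("p", 50), rep("n", 50))
  rb <- c(rep("p", 40), rep("n", 10), rep("p", 5), rep("n", 45))
  expect_equal(cohen_kappa(ra, rb), 0.7)

  expect_error(cohen_kappa(c("a", "b"), "a"), "equal")
})
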