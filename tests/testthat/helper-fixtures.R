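# Shared fixtures and oracles for the suite.

# Adjusted Rand index, brute force from the pair-counting definition.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  sab <- sum(choose(tab, 2))
  e <- sa * sb / choose(n, 2)
  (sab - e) / ((sa + sb) / 2 - e)
}

# The cluster x epoch counts printed for the three-phenotype solution.
table2_counts <- function() {
  matrix(c(23, 13, 29,
           10, 53, 7,
           2, 5, 21),
         nrow = 3, byrow = TRUE,
         dimnames = list(paste0("cluster", 1:3),
                         c("interictal_seizure_free", "interictal_active",
                           "ictal_active")))
}

# Expand a count matrix into per-event label vectors.
expand_counts <- function(counts) {
  cl <- rep(rep(rownames(counts), each = ncol(counts)), times = as.vector(t(counts)))
  ep <- rep(rep(colnames(counts), times = nrow(counts)), times = as.vector(t(counts)))
  list(cluster = sub("cluster", "", cl), epoch = ep)
}

# Match detected events to ground-truth bursts by interval overlap; returns
# per-truth-row the worst absolute onset/offset error in seconds (NA if
# undetected).
match_truth <- function(truth, events) {
  vapply(seq_len(nrow(truth)), function(i) {
    j <- which(events$onset_s < truth$offset_s[i] &
               events$offset_s > truth$onset_s[i])
    if (!length(j)) return(NA_real_)
    max(abs(c(events$onset_s[j[1]] - truth$onset_s[i],
              events$offset_s[j[1]] - truth$offset_s[i])))
  }, 0)
}

# Events not overlapping any truth interval (false detections).
count_false_events <- function(truth, events) {
  if (nrow(events) == 0) return(0L)
  sum(vapply(seq_len(nrow(events)), function(j)
    !any(events$onset_s[j] < truth$offset_s &
         events$offset_s[j] > truth$onset_s), TRUE))
}
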