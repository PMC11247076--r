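# Shared fixture builders. All fixtures are generated in code; no files
# ship with the package.

# A minimal in-memory recording with the given channel layout.
makeRecording <- function(id = "fix", fs = c(EEG1 = 200, EOG1 = 50,
                                             EMG1 = 100),
                          duration = 60,
                          roles = list(EEG = "EEG1", EOG = "EOG1",
                                       EMG = "EMG1"),
                          metadata = list()) {
  signals <- lapply(fs, function(r) sin(seq_len(round(duration * r)) / r))
  names(signals) <- names(fs)
  PSGRecording(id = id, signals = signals, sampleRate = fs, roles = roles,
               duration = duration, metadata = metadata)
}

# Random disjoint event list: durations in durRange, gaps >= minGap.
randomEvents <- function(n, durRange = c(3, 15), minGap = 10,
                         duration = 3600) {
  if (n == 0) return(EventList())
  onsets <- durs <- numeric(0)
  t <- runif(1, 0, 30)
  for (i in seq_len(n)) {
    d <- runif(1, durRange[1], durRange[2])
    if (t + d > duration) break
    onsets <- c(onsets, t); durs <- c(durs, d)
    t <- t + d + minGap + rexp(1, 1 / 40)
  }
  if (length(onsets) == 0) return(EventList())
  EventList(onsets, durs)
}

# Brute-force gap-scan oracle for segments_to_events: binarize, merge runs
# whose gap <= patience, drop short events. Independent of the rle-based
# implementation.
bruteForceEvents <- function(seg, threshold, patience, minLen) {
  pos <- which(seg >= threshold)
  if (length(pos) == 0) return(data.frame(onset = numeric(0),
                                          duration = numeric(0)))
  events <- list()
  start <- pos[1]; last <- pos[1]
  for (p in pos[-1]) {
    if ((p - last - 1) <= patience) last <- p
    else { events[[length(events) + 1]] <- c(start, last); start <- p; last <- p }
  }
  events[[length(events) + 1]] <- c(start, last)
  df <- do.call(rbind, lapply(events, function(e)
    data.frame(onset = e[1] - 1, duration = e[2] - e[1] + 1)))
  df[df$duration >= minLen, , drop = FALSE]
}

# Exhaustive-threshold AUPRC oracle: precision/recall at every distinct
# score cutoff, rectangle rule over recall increments.
bruteForceAUPRC <- function(p, y) {
  ths <- sort(unique(p), decreasing = TRUE)
  npos <- sum(y == 1)
  prevRec <- 0; area <- 0
  for (th in ths) {
    sel <- p >= th
    tp <- sum(y[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / npos
    area <- area + (rec - prevRec) * prec
    prevRec <- rec
  }
  area
}

# Small labelled record set where arousals carry a 12-20 Hz burst; shared
# by the learning smoke tests. The arousal rate sits at the lower end of
# the clinical cohort range so that extended-label prevalence stays in the
# sparse (<10%) regime the smoke test targets.
burstTrainingSet <- function(n, seed, duration = 600, targetARI = 20,
                             burstGain = 3) {
  simulateTrainingSet(n, synthConfig(duration = duration,
                                     targetARI = targetARI,
                                     burstGain = burstGain), seed = seed)
}
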