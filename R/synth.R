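## Synthetic polysomnogram generator.
##
## Emulates the statistical structure the detector relies on, not
## physiological realism: stage-dependent colored background noise, arousal
## events of 3-15 s marked by an abrupt high-frequency (12-20 Hz) additive
## EEG burst (arousals in stage R additionally raise chin-EMG amplitude),
## a semi-Markov hypnogram with 30-s epochs, a configurable arousal index
## with the 10-s minimum inter-arousal gap, and per-recording metadata
## (age, sex, diagnosis groups) with clinically plausible marginals.

#' Synthetic PSG configuration
#'
#' Defaults mirror a clinical overnight cohort: 8-h records, 200 Hz
#' acquisition, an arousal index of 25/h (cohort averages run 19-27/h),
#' arousal durations uniform on 3-15 s with at least 10 s between events.
#'
#' @param nRecords number of records (default 1).
#' @param duration record duration in seconds (default 28800 = 8 h).
#' @param fs acquisition sampling rate (default 200).
#' @param targetARI target arousal index in events per hour of sleep
#'   (default 25).
#' @param arousalDurRange duration range of arousals in seconds
#'   (default c(3, 15), the AASM floor and practical ceiling).
#' @param minGap minimum gap between arousals in seconds (default 10,
#'   the required preceding sleep).
#' @param remFraction approximate fraction of sleep spent in stage R
#'   (default 0.2).
#' @param burstGain EEG burst amplitude as a multiple of the local
#'   background amplitude (default 2).
#' @param emgBurstGain chin-EMG amplitude multiplier during stage-R
#'   arousals (default 3).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A validated configuration list.
#' @export
synthConfig <- function(nRecords = 1, duration = 28800, fs = 200,
                        targetARI = 25, arousalDurRange = c(3, 15),
                        minGap = 10, remFraction = 0.2, burstGain = 2,
                        emgBurstGain = 3, seed = NULL) {
  stopifnot(duration >= 120, fs >= 50, targetARI > 0,
            length(arousalDurRange) == 2,
            arousalDurRange[1] >= 3, arousalDurRange[2] <= 15,
            arousalDurRange[1] <= arousalDurRange[2], minGap >= 0)
  meanDur <- mean(arousalDurRange)
  if (3600 / targetARI <= meanDur + minGap)
    stop(sprintf(
      "targetARI = %g is infeasible: mean inter-arousal interval %.1f s does not exceed mean duration + minimum gap = %.1f s",
      targetARI, 3600 / targetARI, meanDur + minGap))
  list(nRecords = nRecords, duration = duration, fs = fs,
       targetARI = targetARI, arousalDurRange = arousalDurRange,
       minGap = minGap, remFraction = remFraction, burstGain = burstGain,
       emgBurstGain = emgBurstGain, seed = seed)
}

.STAGE_PARAMS <- list(
  W  = list(ar = 0.55, amp = 1.0),
  N1 = list(ar = 0.70, amp = 1.1),
  N2 = list(ar = 0.80, amp = 1.3),
  N3 = list(ar = 0.92, amp = 2.0),
  R  = list(ar = 0.60, amp = 1.0)
)

.simHypnogram <- function(nEpochs, remFraction = 0.2) {
  rScale <- remFraction / 0.2
  stages <- character(0)
  cur <- "W"
  first <- TRUE
  dwell <- function(st) switch(st,
    W = sample(2:6, 1), N1 = sample(2:6, 1), N2 = sample(15:40, 1),
    N3 = sample(10:30, 1), R = sample(10:25, 1))
  nxt <- function(st) switch(st,
    W = "N1", N1 = "N2",
    N2 = sample(c("N3", "R", "N1", "W"), 1,
                prob = c(0.40, 0.35 * rScale, 0.15, 0.10)),
    N3 = sample(c("N2", "R", "W"), 1, prob = c(0.60, 0.30 * rScale, 0.10)),
    R = sample(c("N1", "N2", "W"), 1, prob = c(0.30, 0.50, 0.20)))
  while (length(stages) < nEpochs) {
    d <- if (first) sample(1:3, 1) else dwell(cur)  # short initial wake
    first <- FALSE
    stages <- c(stages, rep(cur, d))
    cur <- nxt(cur)
  }
  Hypnogram(stages[seq_len(nEpochs)])
}

# Contiguous sleep bouts of a hypnogram, as [start, end) second intervals.
.sleepRuns <- function(hyp) {
  m <- sleepMask(hyp)
  if (!any(m)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = (starts[r$values] - 1) * 30, end = ends[r$values] * 30)
}

.simEvents <- function(hyp, cfg) {
  runs <- .sleepRuns(hyp)
  meanDur <- mean(cfg$arousalDurRange)
  mu <- 3600 / cfg$targetARI - meanDur - cfg$minGap  # exponential gap mean
  onsets <- durs <- numeric(0)
  for (i in seq_len(nrow(runs))) {
    t <- runs$start[i] + rexp(1, 1 / mu)
    while (TRUE) {
      d <- runif(1, cfg$arousalDurRange[1], cfg$arousalDurRange[2])
      if (t + d > runs$end[i]) break
      onsets <- c(onsets, t); durs <- c(durs, d)
      t <- t + d + cfg$minGap + rexp(1, 1 / mu)
    }
  }
  EventList(onsets, durs, "Arousal")
}

#' Simulate ground-truth annotations only
#'
#' Fast path generating the hypnogram and arousal events of one record
#' without signals; used where only the annotation statistics matter
#' (e.g. arousal-index calibration over many records).
#'
#' @param cfg a [synthConfig()] list.
#' @param seed optional seed overriding `cfg$seed`.
#' @return `list(hypnogram, events)`.
#' @export
simulateAnnotations <- function(cfg = synthConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed) else if (!is.null(cfg$seed))
    set.seed(cfg$seed)
  hyp <- .simHypnogram(floor(cfg$duration / 30), cfg$remFraction)
  list(hypnogram = hyp, events = .simEvents(hyp, cfg))
}

.ar1 <- function(n, a) as.numeric(stats::filter(rnorm(n), a, "recursive"))

.burstEnvelope <- function(n, fs, ramp = 0.5) {
  # cosine on/off ramps
  nr <- min(round(ramp * fs), floor(n / 2))
  env <- rep(1, n)
  if (nr > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- up
    env[n - nr + seq_len(nr)] <- rev(up)
  }
  env
}

.simSignals <- function(hyp, events, cfg) {
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  stages <- hypnoStages(hyp)
  sampleStage <- stages[pmin(floor((seq_len(n) - 1) / fs / 30) + 1,
                             length(stages))]
  amp <- vapply(.STAGE_PARAMS, `[[`, 0, "amp")[sampleStage]
  mkEEG <- function() {
    x <- .ar1(n, 0.8)
    x <- x / sd(x) * amp
    for (i in seq_len(length(events))) {
      i0 <- floor(eventOnset(events)[i] * fs) + 1
      i1 <- min(n, ceiling(eventEnd(events)[i] * fs))
      len <- i1 - i0 + 1
      if (len < 2) next
      f <- runif(1, 12, 20)
      tt <- (seq_len(len) - 1) / fs
      burst <- sin(2 * pi * f * tt + runif(1, 0, 2 * pi)) *
        .burstEnvelope(len, fs) * cfg$burstGain * amp[i0]
      x[i0:i1] <- x[i0:i1] + burst
    }
    x
  }
  mkEOG <- function() {
    x <- .ar1(n, 0.97)
    x / sd(x) * ifelse(sampleStage == "R", 2.0, 1.0)
  }
  mkEMG <- function() {
    base <- ifelse(sampleStage == "W", 1.5,
                   ifelse(sampleStage == "R", 0.4, 0.8))
    x <- rnorm(n) * base
    epochOf <- function(t) pmin(floor(t / 30) + 1, length(stages))
    for (i in seq_len(length(events))) {
      if (stages[epochOf(eventOnset(events)[i])] != "R") next
      i0 <- floor(eventOnset(events)[i] * fs) + 1
      i1 <- min(n, ceiling(eventEnd(events)[i] * fs))
      len <- i1 - i0 + 1
      if (len < 2) next
      gain <- 1 + (cfg$emgBurstGain - 1) * .burstEnvelope(len, fs)
      x[i0:i1] <- x[i0:i1] * gain
    }
    x
  }
  list(`C3-A2` = mkEEG(), `C4-A1` = mkEEG(), `EOG-L` = mkEOG(),
       `EOG-R` = mkEOG(), `Chin` = mkEMG())
}

.simMetadata <- function(groups = NULL) {
  age <- round(min(max(rnorm(1, 57.8, 15.8), 18), 92))
  sex <- sample(c("F", "M"), 1, prob = c(0.4, 0.6))
  if (is.null(groups)) {
    groups <- character(0)
    # non-exclusive draws with clinical-cohort marginals
    for (g in c("SRBD", "SRMD", "Insomnia", "Hypersomnia", "Parasomnia")) {
      pr <- c(SRBD = 0.73, SRMD = 0.17, Insomnia = 0.16,
              Hypersomnia = 0.05, Parasomnia = 0.13)[[g]]
      if (runif(1) < pr) groups <- c(groups, g)
    }
    if (length(groups) == 0) groups <- "NormalFinding"
  }
  list(age = age, sex = sex, diagnosis_groups = groups)
}

#' Simulate one synthetic polysomnogram
#'
#' Generates a full record: a semi-Markov hypnogram, arousal events placed
#' on sleep time as a renewal process calibrated to the target arousal
#' index (respecting the 10-s minimum gap and 3-15 s durations), and
#' five channels (two EEG with the arousal bursts, two EOG, one chin EMG
#' with stage-R arousal amplification) at the acquisition rate, plus
#' metadata. Bit-identical output for a fixed seed.
#'
#' @param cfg a [synthConfig()] list.
#' @param id record identifier (default "synth-1").
#' @param seed optional seed overriding `cfg$seed`.
#' @param groups optional fixed diagnosis groups for the metadata.
#' @return `list(recording, events, hypnogram)` where `recording` is a
#'   [PSGRecording-class].
#' @export
simulateRecording <- function(cfg = synthConfig(), id = "synth-1",
                              seed = NULL, groups = NULL) {
  if (!is.null(seed)) set.seed(seed) else if (!is.null(cfg$seed))
    set.seed(cfg$seed)
  hyp <- .simHypnogram(floor(cfg$duration / 30), cfg$remFraction)
  events <- .simEvents(hyp, cfg)
  signals <- .simSignals(hyp, events, cfg)
  meta <- .simMetadata(groups)
  rec <- PSGRecording(
    id = id, signals = signals,
    sampleRate = setNames(rep(cfg$fs, length(signals)), names(signals)),
    roles = list(EEG = c("C3-A2", "C4-A1"), EOG = c("EOG-L", "EOG-R"),
                 EMG = "Chin"),
    duration = cfg$duration, metadata = meta)
  list(recording = rec, events = events, hypnogram = hyp)
}

# Build a degraded copy of the truth annotation whose arousal index is off
# by approximately `err` events/h (positive shift = spurious extra events,
# negative = missed events), used to emulate an imperfect scorer.
.perturbEvents <- function(events, hyp, err, minGap) {
  tstH <- totalSleepTime(hyp) / 3600
  k <- round(abs(err) * tstH)
  if (k == 0 || length(events) == 0) return(events)
  if (err < 0) {
    keep <- sort(sample.int(length(events), max(0, length(events) - k)))
    if (length(keep) == 0) return(EventList())
    return(EventList(eventOnset(events)[keep], eventDuration(events)[keep],
                     eventLabel(events)[keep]))
  }
  # insert k extra events into sleep, clear of existing events
  runs <- .sleepRuns(hyp)
  ons <- eventOnset(events); ens <- eventEnd(events)
  extraOn <- extraDur <- numeric(0)
  tries <- 0
  while (length(extraOn) < k && tries < 50 * k) {
    tries <- tries + 1
    ri <- sample.int(nrow(runs), 1)
    d <- runif(1, 3, 10)
    if (runs$end[ri] - runs$start[ri] < d + 2) next
    t <- runif(1, runs$start[ri], runs$end[ri] - d)
    clear <- all(t + d + minGap <= ons | t >= ens + minGap) &&
      all(t + d + minGap <= extraOn | t >= extraOn + extraDur + minGap |
            length(extraOn) == 0)
    if (clear) { extraOn <- c(extraOn, t); extraDur <- c(extraDur, d) }
  }
  EventList(c(ons, extraOn), c(eventDuration(events), extraDur), "Arousal")
}

#' Simulate a cohort of records on disk
#'
#' Writes `recordsPerGroup` record bundles per diagnosis group into `dir`:
#' EDF signals (`<id>.edf`), reference events (`<id>_events.tsv`), a
#' hypnogram (`<id>_hypnogram.txt`), an emulated imperfect scoring
#' (`<id>_scored.tsv`) whose arousal-index error is drawn from a
#' half-normal baseline plus a per-group shift, and a cohort-level
#' `metadata.csv`. Everything is re-readable through the package's own
#' readers, so the evaluation and bias-analysis modules can run end to
#' end against it.
#'
#' @param cfg a [synthConfig()] list (small `duration` values keep the
#'   cohort light).
#' @param dir output directory (created if needed).
#' @param groups diagnosis group per stratum (default the six analysis
#'   groups).
#' @param recordsPerGroup records per group (default 20).
#' @param groupShifts named numeric, additive shift of the ArI-error
#'   baseline per group, in events/h (default none).
#' @param errorSd sd of the Gaussian whose absolute value forms the
#'   baseline ArI error (default 3 events/h).
#' @param writeSignals write EDF signal files (default TRUE; disable for
#'   annotation-only cohorts).
#' @param seed RNG seed.
#' @return data.frame index of the cohort (id, group, age, sex, paths).
#' @export
simulateCohort <- function(cfg = synthConfig(duration = 600),
                           dir = tempfile("cohort"),
                           groups = c("SRBD", "SRMD", "Insomnia",
                                      "Hypersomnia", "Parasomnia",
                                      "NormalFinding"),
                           recordsPerGroup = 20, groupShifts = numeric(0),
                           errorSd = 3, writeSignals = TRUE, seed = 1) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (g in groups) for (i in seq_len(recordsPerGroup)) {
    id <- sprintf("%s-%03d", gsub("[^A-Za-z]", "", g), i)
    if (writeSignals) {
      sim <- simulateRecording(cfg, id = id, groups = g)
      rec <- sim$recording
    } else {
      ann <- simulateAnnotations(cfg)
      sim <- list(events = ann$events, hypnogram = ann$hypnogram)
      rec <- NULL
    }
    shift <- if (g %in% names(groupShifts)) groupShifts[[g]] else 0
    err <- (abs(rnorm(1, 0, errorSd)) + shift) * sample(c(-1, 1), 1)
    scored <- .perturbEvents(sim$events, sim$hypnogram, err, cfg$minGap)
    edf <- file.path(dir, paste0(id, ".edf"))
    if (writeSignals) writeRecording(rec, edf)
    writeEvents(sim$events, file.path(dir, paste0(id, "_events.tsv")))
    writeEvents(scored, file.path(dir, paste0(id, "_scored.tsv")))
    writeHypnogram(sim$hypnogram, file.path(dir, paste0(id, "_hypnogram.txt")))
    meta <- if (writeSignals) recordingMeta(rec) else .simMetadata(g)
    rows[[length(rows) + 1]] <- data.frame(
      id = id, group = g, age = meta$age, sex = meta$sex,
      groups = paste(meta$diagnosis_groups, collapse = ";"),
      edf = if (writeSignals) edf else NA_character_,
      stringsAsFactors = FALSE)
  }
  index <- do.call(rbind, rows)
  writeMetadataTable(index[, c("id", "age", "sex", "groups")],
                     file.path(dir, "metadata.csv"))
  attr(index, "dir") <- dir
  index
}

#' Simulate a labelled training set in memory
#'
#' Generates `n` records, preprocesses each into the three-channel 50 Hz
#' model input and builds the extended 50 Hz label track — the bundle
#' [trainModel()] consumes.
#'
#' @param n number of records.
#' @param cfg a [synthConfig()] list.
#' @param seed base seed; record `i` uses `seed + i`.
#' @param fsModel model rate (default 50).
#' @return list of `list(x, y, events, hypnogram, duration)` records.
#' @export
simulateTrainingSet <- function(n, cfg = synthConfig(duration = 600),
                                seed = 1, fsModel = 50) {
  lapply(seq_len(n), function(i) {
    sim <- simulateRecording(cfg, id = sprintf("rec-%03d", i),
                             seed = seed + i)
    x <- preprocessRecording(sim$recording, fsModel = fsModel)
    y <- makeLabelTrack(sim$events, recordingDuration(sim$recording),
                        fsModel = fsModel)
    list(x = x, y = y, events = sim$events, hypnogram = sim$hypnogram,
         duration = recordingDuration(sim$recording))
  })
}
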