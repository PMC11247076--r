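test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- synthConfig(duration = 300, targetARI = 20, seed = 17)
  a <- simulateRecording(cfg)
  b <- simulateRecording(cfg)
  expect_identical(a$recording@signals, b$recording@signals)
  expect_identical(eventOnset(a$events), eventOnset(b$events))
  expect_identical(hypnoStages(a$hypnogram), hypnoStages(b$hypnogram))
})

test_that("generated events respect the AASM duration and gap constraints", {
  cfg <- synthConfig(duration = 14400, targetARI = 30)
  for (seed in 1:5) {
    a <- simulateAnnotations(cfg, seed = seed)
    ev <- a$events
    if (length(ev) == 0) next
    expect_true(all(eventDuration(ev) >= 3 & eventDuration(ev) <= 15))
    if (length(ev) > 1) {
      gaps <- eventOnset(ev)[-1] - eventEnd(ev)[-length(ev)]
      expect_gte(min(gaps), 10)
    }
    # every event lies inside sleep epochs
    stages <- hypnoStages(a$hypnogram)
    for (i in seq_len(length(ev))) {
      epochs <- floor(eventOnset(ev)[i] / 30):floor((eventEnd(ev)[i] - 1e-9) / 30)
      expect_true(all(stages[epochs + 1] != "W"))
    }
  }
})

test_that("infeasible arousal-index targets are rejected at configuration", {
  expect_error(synthConfig(targetARI = 300), "infeasible")
})

test_that("realized arousal index tracks the configured target", {
  cfg <- synthConfig(duration = 28800, targetARI = 25)
  ari <- vapply(1:30, function(i) {
    a <- simulateAnnotations(cfg, seed = 1000 + i)
    arousalIndex(a$events, a$hypnogram)
  }, 0)
  expect_lt(abs(mean(ari) - 25), 2)
})

test_that("records carry the expected channels, rates and metadata", {
  sim <- simulateRecording(synthConfig(duration = 300), seed = 23)
  rec <- sim$recording
  expect_setequal(channelNames(rec),
                  c("C3-A2", "C4-A1", "EOG-L", "EOG-R", "Chin"))
  expect_true(validObject(rec))
  expect_equal(channelRate(rec, "C3-A2"), 200)
  expect_length(channelSignal(rec, "Chin"), 300 * 200)
  meta <- recordingMeta(rec)
  expect_true(meta$age >= 18 && meta$age <= 92)
  expect_true(meta$sex %in% c("F", "M"))
  expect_true(length(meta$diagnosis_groups) >= 1)
  # generated data satisfy the preprocessing preconditions end to end
  x <- preprocessRecording(rec)
  expect_equal(ncol(x), 300 * 50)
  expect_true(all(is.finite(x)))
})

test_that("EEG bursts raise 12-20 Hz band power inside arousals", {
  sim <- simulateRecording(synthConfig(duration = 600, targetARI = 30,
                                       burstGain = 3), seed = 29)
  expect_gte(length(sim$events), 2)
  eeg <- channelSignal(sim$recording, "C3-A2")
  # band-pass 12-20 Hz, compare power inside vs outside events
  b <- as.numeric(signal::fir1(200, c(12, 20) / 100, type = "pass"))
  bandpassed <- signal::filtfilt(b, 1, eeg)
  n <- length(eeg)
  inside <- rep(FALSE, n)
  for (i in seq_len(length(sim$events))) {
    a <- floor(eventOnset(sim$events)[i] * 200) + 1
    z <- min(n, ceiling(eventEnd(sim$events)[i] * 200))
    inside[a:z] <- TRUE
  }
  ratio <- mean(bandpassed[inside]^2) / mean(bandpassed[!inside]^2)
  expect_gt(ratio, 2)
})

test_that("cohort bundles round-trip through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- synthConfig(duration = 300, targetARI = 25)
  idx <- simulateCohort(cfg, dir = dir, recordsPerGroup = 2, seed = 31,
                        groups = c("SRBD", "NormalFinding"))
  expect_equal(nrow(idx), 4)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  for (i in seq_len(nrow(idx))) {
    rec <- readRecording(idx$edf[i], channelMap = list(
      EEG = c("C3-A2", "C4-A1"), EOG = c("EOG-L", "EOG-R"), EMG = "Chin"))
    expect_equal(recordingDuration(rec), 300)
    ev <- readEvents(file.path(dir, paste0(idx$id[i], "_events.tsv")))
    hyp <- readHypnogram(file.path(dir, paste0(idx$id[i], "_hypnogram.txt")))
    expect_equal(length(hyp), 10)
    sc <- readEvents(file.path(dir, paste0(idx$id[i], "_scored.tsv")))
    # scored and truth annotations both evaluate cleanly
    row <- evaluateRecord(ev, sc, hyp, id = idx$id[i])
    expect_gte(row$ari_error, 0)
  }
  meta <- readMetadataTable(file.path(dir, "metadata.csv"))
  expect_setequal(meta$id, idx$id)
})

test_that("an injected group shift is recovered by the bias analysis", {
  set.seed(37)
  cfg <- synthConfig(duration = 3600, targetARI = 25)
  groupErr <- function(shift, n = 25) {
    vapply(seq_len(n), function(i) {
      a <- simulateAnnotations(cfg, seed = sample.int(2^30, 1))
      err <- (abs(rnorm(1, 0, 3)) + shift) * sample(c(-1, 1), 1)
      sc <- arousalNet:::.perturbEvents(a$events, a$hypnogram, err, 10)
      abs(arousalIndex(sc, a$hypnogram) - arousalIndex(a$events, a$hypnogram))
    }, 0)
  }
  errs <- list(NormalFinding = groupErr(0), SRMD = groupErr(0),
               SRBD = groupErr(6))   # ~2 sd of the half-normal baseline
  res <- groupBiasAnalysis(errs)
  tab <- res$groups
  expect_true(tab$significant[tab$group == "SRBD"])
  expect_true(tab$effect_bin[tab$group == "SRBD"] %in%
                c("moderate", "large"))
  expect_equal(tab$effect_bin[tab$group == "SRMD"], "none")
})
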