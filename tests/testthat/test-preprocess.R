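test_that("antialiased resampling preserves the passband and kills the stopband", {
  t <- (0:(200 * 60 - 1)) / 200
  # 10 Hz tone survives 200 -> 50 Hz within 1% amplitude (spectral measure)
  r10 <- antialiasResample(sin(2 * pi * 10 * t), 200, 50)
  expect_length(r10, 3000)
  expect_lt(abs(sqrt(2 * mean(r10^2)) - 1), 0.01)
  # 30 Hz tone (above the 25 Hz output Nyquist) attenuated >= 40 dB
  r30 <- antialiasResample(sin(2 * pi * 30 * t), 200, 50)
  expect_lt(sqrt(mean(r30^2)), 0.01)
  # DC preserved exactly
  expect_equal(antialiasResample(rep(3.5, 1000), 200, 50), rep(3.5, 250))
  # non-integer rate ratios produce the contracted length
  expect_length(antialiasResample(rnorm(256 * 30), 256, 50), 1500)
  expect_error(antialiasResample(rnorm(100), 50, 200), "upsampling")
})

test_that("moving normalization standardizes local mean and RMS", {
  expect_equal(movingNormalize(rep(4.2, 1000), 50), rep(0, 1000))
  set.seed(31)
  x <- rnorm(180000, mean = 2, sd = 5)  # 1 h at 50 Hz
  z <- movingNormalize(x, 50)
  interior <- z[54000:126000]           # away from the 18-min edges
  expect_lt(abs(mean(interior)), 0.05)
  expect_lt(abs(sqrt(mean(interior^2)) - 1), 0.1)
  # scale invariance across a 10x amplitude step
  x2 <- c(rnorm(90000), 10 * rnorm(90000))
  z2 <- movingNormalize(x2, 50)
  expect_lt(abs(sqrt(mean(z2[20000:70000]^2)) - 1), 0.1)
  expect_lt(abs(sqrt(mean(z2[110000:160000]^2)) - 1), 0.1)
})

test_that("label extension applies the -2 s / +10 s margins with clipping and merging", {
  # a 3 s arousal becomes a 15 s training label
  e1 <- extendLabels(EventList(100, 3), duration = 3600)
  expect_equal(eventOnset(e1), 98)
  expect_equal(eventDuration(e1), 15)
  # clipped at record start
  e2 <- extendLabels(EventList(1, 3), duration = 3600)
  expect_equal(eventOnset(e2), 0)
  expect_equal(eventDuration(e2), 14)
  # overlapping extensions merge into their union
  e3 <- extendLabels(EventList(c(100, 110), c(3, 3)), duration = 3600)
  expect_equal(length(e3), 1L)
  expect_equal(eventOnset(e3), 98)
  expect_equal(eventDuration(e3), 25)
})

test_that("label extension is idempotent at zero margins and never shrinks coverage", {
  set.seed(11)
  for (rep in 1:20) {
    ev <- randomEvents(12, duration = 1200)
    ext <- extendLabels(ev, duration = 1200)
    again <- extendLabels(ext, pre = 0, post = 0, duration = 1200)
    expect_equal(eventOnset(again), eventOnset(ext))
    expect_equal(eventDuration(again), eventDuration(ext))
    # coverage superset: every original event lies inside some extended one
    for (i in seq_len(length(ev))) {
      inside <- any(eventOnset(ext) <= eventOnset(ev)[i] &
                      eventEnd(ext) >= eventEnd(ev)[i])
      expect_true(inside)
    }
  }
})

test_that("rasterization follows the half-open sample-time convention", {
  expect_equal(rasterizeLabels(EventList(), nSamples = 100), integer(100))
  y <- rasterizeLabels(EventList(2, 1), fs = 50, nSamples = 500)
  expect_equal(sum(y), 50)
  expect_equal(which(y == 1), 101:150)  # 0-based samples 100..149
})

test_that("rasterized coverage matches the interval-union length", {
  set.seed(21)
  for (rep in 1:10) {
    ev <- randomEvents(10, duration = 600)
    # grid-aligned endpoints: coverage equals the union length exactly
    snapped <- mergeIntervals(round(eventOnset(ev) * 50) / 50,
                              round(eventEnd(ev) * 50) / 50)
    y <- rasterizeLabels(snapped, fs = 50, nSamples = 30000)
    expect_equal(sum(y) / 50, sum(eventDuration(snapped)))
    # arbitrary endpoints: off by at most one sample per boundary
    merged <- mergeIntervals(eventOnset(ev), eventEnd(ev))
    y2 <- rasterizeLabels(merged, fs = 50, nSamples = 30000)
    expect_lt(abs(sum(y2) / 50 - sum(eventDuration(merged))),
              2 * length(merged) / 50)
  }
})

test_that("full preprocessing yields three aligned rows at the model rate", {
  rec <- makeRecording(fs = c(EEG1 = 200, EOG1 = 50, EMG1 = 100),
                       duration = 60)
  x <- preprocessRecording(rec)
  expect_equal(dim(x), c(3L, 3000L))
  expect_true(all(is.finite(x)))
  expect_equal(rownames(x), c("EEG", "EOG", "EMG"))
})

test_that("channel selection is uniform over a role and reproducible", {
  rec <- makeRecording(fs = c(E1 = 50, E2 = 50, O1 = 50, O2 = 50, M1 = 50),
                       duration = 10,
                       roles = list(EEG = c("E1", "E2"),
                                    EOG = c("O1", "O2"), EMG = "M1"))
  # singleton roles always return their channel
  expect_equal(unname(selectChannels(rec)[["EMG"]]), "M1")
  set.seed(5)
  draws <- replicate(10000, selectChannels(rec)[["EOG"]])
  expect_lt(abs(mean(draws == "O1") - 0.5), 0.03)
  set.seed(99); a <- selectChannels(rec)
  set.seed(99); b <- selectChannels(rec)
  expect_identical(a, b)
  recBad <- makeRecording(fs = c(E1 = 50), duration = 10,
                          roles = list(EEG = "E1"))
  expect_error(selectChannels(recBad), "EOG")
})

test_that("extension then rasterization never yields short interior label runs", {
  set.seed(41)
  fs <- 50
  for (rep in 1:10) {
    ev <- randomEvents(8, durRange = c(3, 15), duration = 900)
    if (length(ev) == 0) next
    y <- makeLabelTrack(ev, duration = 900, fsModel = fs)
    r <- rle(y)
    runs <- r$lengths[r$values == 1]
    # interior runs carry at least the minimum event plus both margins
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    interior <- r$values == 1 & starts > 1 & ends < length(y)
    if (any(interior))
      expect_gte(min(r$lengths[interior]), round((3 + 12) * fs) - 1)
  }
})
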