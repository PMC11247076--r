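test_that("sample AUPRC handles perfect, constant and adversarial rankings", {
  y <- c(rep(1, 20), rep(0, 80))
  pPerfect <- c(runif(20, 0.6, 1), runif(80, 0, 0.4))
  expect_equal(sampleAUPRC(pPerfect, y), 1.0)
  # constant score collapses to a single PR point at the prevalence
  expect_equal(sampleAUPRC(rep(0.5, 100), y), 0.2)
  expect_error(sampleAUPRC(rep(0.5, 10), rep(1, 10)), "single class")
})

test_that("sample AUPRC equals the exhaustive-threshold oracle", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    p <- switch(sample(3, 1),
                runif(n),                       # random scores
                round(runif(n), 1),             # heavy ties
                1 - y * runif(n, 0.3, 1))       # anti-ranked
    expect_equal(sampleAUPRC(p, y), bruteForceAUPRC(p, y), tolerance = 1e-12)
  }
})

test_that("event matching implements the printed double-overlap special cases", {
  # two predictions over one reference: one TP, one FN
  cc <- matchEvents(EventList(10, 10), EventList(c(12, 18), c(3, 4)))
  expect_equal(cc, list(tp = 1L, fp = 0L, fn = 1L))
  # two references under one prediction: two TP, one FP
  cc2 <- matchEvents(EventList(c(10, 20), c(5, 5)), EventList(12, 14))
  expect_equal(cc2, list(tp = 2L, fp = 1L, fn = 0L))
  # plain miss
  expect_equal(matchEvents(EventList(10, 5), EventList()),
               list(tp = 0L, fp = 0L, fn = 1L))
  # plain false alarm
  expect_equal(matchEvents(EventList(), EventList(10, 5)),
               list(tp = 0L, fp = 1L, fn = 0L))
  # overlap within one list is rejected
  expect_error(matchEvents(new("EventList", onset = c(0, 3),
                               duration = c(5, 5),
                               label = c("A", "A")), EventList()),
               "disjoint")
})

test_that("matching counts conserve event totals under the generalized rules", {
  set.seed(29)
  for (rep in 1:100) {
    # spacing regime where one event can never span two of the other list
    truth <- randomEvents(sample(0:12, 1), durRange = c(3, 9), minGap = 10,
                          duration = 1800)
    pred <- randomEvents(sample(0:12, 1), durRange = c(3, 9), minGap = 10,
                         duration = 1800)
    cc <- matchEvents(truth, pred)
    expect_equal(cc$tp + cc$fn, length(truth))
    expect_lte(cc$tp, length(truth))
    expect_equal(cc$tp + cc$fp, length(pred))
  }
  # unconstrained regime: totals hold up to the multi-overlap allowances
  for (rep in 1:100) {
    truth <- randomEvents(sample(0:10, 1), durRange = c(3, 15), minGap = 2,
                          duration = 600)
    pred <- randomEvents(sample(0:10, 1), durRange = c(3, 15), minGap = 2,
                         duration = 600)
    cc <- matchEvents(truth, pred)
    expect_gte(cc$tp + cc$fn, length(truth))
    expect_lte(cc$tp, length(truth))
    expect_gte(cc$fp, 0); expect_gte(cc$fn, 0)
  }
})

test_that("role swap exchanges FP and FN on the printed scenarios", {
  a <- EventList(10, 10); b <- EventList(c(12, 18), c(3, 4))
  fwd <- matchEvents(a, b)
  rev <- matchEvents(b, a)
  expect_equal(rev$tp, 2L)  # both b-events are covered
  expect_equal(rev$fp, fwd$fn)
  expect_equal(rev$fn, fwd$fp)
})

test_that("micro F1 pools confusion counts before the ratio", {
  expect_equal(microF1(list(tp = 8, fp = 2, fn = 2)), 0.8)
  two <- list(list(tp = 4, fp = 1, fn = 1), list(tp = 4, fp = 1, fn = 1))
  expect_equal(microF1(two), 0.8)
  expect_equal(microF1(two), microF1(list(tp = 8, fp = 2, fn = 2)))
  expect_equal(microF1(list(tp = 5, fp = 0, fn = 0)), 1.0)
  expect_error(microF1(list(tp = 0, fp = 0, fn = 0)), "undefined")
  # splitting one record's events across two records leaves micro F1 fixed
  set.seed(37)
  cc <- list(tp = 11, fp = 4, fn = 6)
  split <- list(list(tp = 5, fp = 1, fn = 2), list(tp = 6, fp = 3, fn = 4))
  expect_equal(microF1(split), microF1(cc))
})

test_that("arousal index divides event count by hours of sleep", {
  h <- Hypnogram(rep(c("W", "N2"), c(20, 240)))  # 2 h sleep + wake
  ev <- EventList(seq(600, 600 + 59 * 100, by = 100), rep(5, 60))
  expect_equal(arousalIndex(ev, h), 30)
  expect_equal(arousalIndex(EventList(), h), 0)
  expect_error(arousalIndex(ev, Hypnogram(rep("W", 10))), "sleep")
  # Table-2-scale sanity: 160 events over 360 min TST -> 26.7/h
  h2 <- Hypnogram(rep("N2", 720))
  ev2 <- EventList(seq(0, 159) * 130, rep(5, 160))
  expect_equal(arousalIndex(ev2, h2), 160 / 6, tolerance = 1e-12)
})

test_that("set evaluation aggregates counts, ArI statistics and correlation", {
  h <- Hypnogram(rep("N2", 240))
  mkRow <- function(id, nTrue, nPred) {
    truth <- EventList(seq_len(nTrue) * 40, rep(5, nTrue))
    pred <- EventList(seq_len(nPred) * 40 + 1, rep(5, nPred))
    evaluateRecord(truth, pred, h, id = id)
  }
  # identical prediction: F1 = 1, zero ArI error, degenerate r -> NA
  rows <- rbind(mkRow("a", 10, 10), mkRow("b", 20, 20))
  rep1 <- evaluateSet(rows)
  expect_equal(reportSummary(rep1)$micro_f1, 1.0)
  expect_equal(reportSummary(rep1)$ari_error_mean, 0)
  # constant offset: mean signed diff = c, error = |c|, r = 1
  rows2 <- rbind(mkRow("a", 10, 14), mkRow("b", 20, 24), mkRow("c", 6, 10))
  rep2 <- evaluateSet(rows2)
  expect_equal(reportSummary(rep2)$ari_diff_mean, 2)   # 4 events / 2 h
  expect_equal(reportSummary(rep2)$ari_error_mean, 2)
  expect_equal(reportSummary(rep2)$ari_r, 1)
  # degenerate variance reports r as NA, not 1
  rows3 <- rbind(mkRow("a", 10, 10), mkRow("b", 10, 12))
  expect_true(is.na(reportSummary(evaluateSet(rows3))$ari_r))
})

test_that("ArI error median and IQR match direct order statistics", {
  set.seed(41)
  h <- Hypnogram(rep("N2", 240))
  rows <- do.call(rbind, lapply(1:15, function(i) {
    nT <- sample(5:30, 1); nP <- sample(5:30, 1)
    evaluateRecord(EventList(seq_len(nT) * 40, rep(5, nT)),
                   EventList(seq_len(nP) * 40 + 1, rep(5, nP)),
                   h, id = paste0("r", i))
  }))
  s <- reportSummary(evaluateSet(rows))
  expect_equal(s$ari_error_median, median(rows$ari_error))
  expect_equal(s$ari_error_q1, quantile(rows$ari_error, 0.25, names = FALSE))
  expect_equal(s$ari_error_q3, quantile(rows$ari_error, 0.75, names = FALSE))
  expect_true(all(rows$ari_error >= 0))
})
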