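test_that("participant-wise split partitions ids at the 80/20 fractions", {
  ids <- paste0("p", 1:10)
  sp <- makeSplit(ids, testIds = c("p1", "p2"), seed = 3)
  expect_setequal(names(sp), ids)
  expect_equal(unname(sp[c("p1", "p2")]), c("test", "test"))
  expect_equal(sum(sp == "val"), round(0.2 * 8))
  expect_equal(sum(sp == "train"), 8 - round(0.2 * 8))
  # all recordings of one patient inherit one split label
  recs <- data.frame(rec = 1:30, patient = sample(ids, 30, replace = TRUE))
  recSplit <- sp[recs$patient]
  expect_true(all(tapply(recSplit, recs$patient,
                         function(z) length(unique(z))) == 1))
  # determinism and validation
  expect_identical(makeSplit(ids, c("p1", "p2"), seed = 3), sp)
  expect_error(makeSplit(ids, "p99"), "p99")
  expect_error(makeSplit(c("a", "a", "b")), "unique")
})

test_that("noise augmentation scales channels by uniform factors", {
  x <- matrix(1, 3, 100)
  # degenerate bounds give the identity
  cfg1 <- trainConfig(noiseLow = 1 - 1e-9, noiseHigh = 1 + 1e-9)
  expect_equal(augmentInput(x, cfg1), x, tolerance = 1e-6)
  set.seed(67)
  cfg <- trainConfig()
  f <- replicate(10000, augmentInput(x, cfg)[1, 1])
  expect_equal(mean(f), 1.05, tolerance = 0.01)    # mean of U(0.8, 1.3)
  expect_true(all(f >= 0.8 & f <= 1.3))
  set.seed(5); a <- augmentInput(x, cfg)
  set.seed(5); b <- augmentInput(x, cfg)
  expect_identical(a, b)
})

test_that("learning rate follows the 4-epoch triangular cycle", {
  lr <- lrSchedule(1:17)
  expect_equal(lr[1], 0.003)
  expect_equal(lr[5], 0.00075)   # low point after four epochs
  expect_equal(lr[9], 0.003)     # back after eight
  expect_equal(lr[13], 0.00075)
  expect_equal(lr[17], 0.003)
  expect_true(all(lr >= 0.00075 & lr <= 0.003))
  expect_true(all(diff(lr[1:5]) < 0) && all(diff(lr[5:9]) > 0))
})

test_that("training records the schedule, stops early, and rejects degenerate labels", {
  set.seed(71)
  mkRec <- function(pos) {
    x <- matrix(rnorm(3 * 256), 3, 256)
    y <- integer(256)
    if (pos) y[100:140] <- 1L
    list(x = x, y = y)
  }
  spec <- unetSpec(depth = 2, baseFilters = 2, kernel = 5, poolFactor = 2)
  # lr 0 freezes the model -> first epoch is never beaten -> patience 1 stops at epoch 2
  cfg <- trainConfig(lrLow = 1e-12, lrHigh = 2e-12, earlyStopPatience = 1,
                     maxEpochs = 50, batchSize = 2, chunkLength = 256,
                     stepsPerEpoch = 2, seed = 2)
  fit <- trainModel(spec, list(mkRec(TRUE), mkRec(TRUE)),
                    list(mkRec(TRUE)), cfg)
  expect_equal(nrow(fit$history), 2L)
  expect_equal(fit$bestEpoch, 1L)
  # history carries one lr per epoch matching the schedule formula
  expect_equal(fit$history$lr,
               lrSchedule(fit$history$epoch, cfg$lrLow, cfg$lrHigh,
                          cfg$cycleEpochs))
  expect_error(
    trainModel(spec, list(mkRec(FALSE)), list(mkRec(TRUE)), cfg),
    "degenerate")
})

test_that("training runs are reproducible with augmentation off and a fixed seed", {
  set.seed(73)
  recs <- lapply(1:3, function(i) {
    x <- matrix(rnorm(3 * 256), 3, 256)
    y <- integer(256); y[50:90] <- 1L
    list(x = x, y = y)
  })
  spec <- unetSpec(depth = 2, baseFilters = 2, kernel = 5, poolFactor = 2)
  cfg <- trainConfig(maxEpochs = 2, batchSize = 2, chunkLength = 256,
                     stepsPerEpoch = 3, augment = FALSE, seed = 11)
  run <- function() {
    set.seed(99)
    trainModel(buildUNet(spec, seed = 1), recs[1:2], recs[3], cfg)$history
  }
  expect_identical(run(), run())
})

test_that("lr-bound selection brackets the steepest-descent region", {
  pick <- arousalNet:::.lrBoundsFromLosses
  grid <- c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2, 3e-2)
  # loss improves then explodes: bounds stay inside the improving run
  deltas <- c(-0.01, -0.05, -0.2, -0.1, 0.5, Inf)
  b <- pick(grid, deltas)
  expect_equal(unname(b), c(1e-4, 3e-3))
  # single-element grid returns that rate twice
  expect_equal(unname(pick(0.003, -0.1)), c(0.003, 0.003))
  # monotone-flat loss: widest bounds with a warning
  expect_warning(bf <- pick(grid, rep(0, 6)), "flat")
  expect_equal(unname(bf), range(grid))
  # divergence everywhere is an error
  expect_error(pick(grid, rep(Inf, 6)), "diverged")
})

test_that("lr range test runs end to end on a tiny problem", {
  set.seed(79)
  recs <- lapply(1:2, function(i) {
    x <- matrix(rnorm(3 * 256), 3, 256)
    y <- integer(256); y[1:256 %% 7 == 0] <- 1L
    pos <- which(y == 1)
    x[1, pos] <- x[1, pos] + 3
    list(x = x, y = y)
  })
  spec <- unetSpec(depth = 2, baseFilters = 2, kernel = 5, poolFactor = 2)
  cfg <- trainConfig(batchSize = 1, chunkLength = 256)
  b <- lrRangeTest(spec, recs, c(1e-4, 1e-3, 1e-2), stepsPerRate = 8,
                   cfg = cfg, seed = 4)
  expect_true(b["low"] <= b["high"])
  expect_true(all(b %in% c(1e-4, 1e-3, 1e-2)))
})
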