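## Training: binary cross-entropy + Adam, a triangular cyclical learning
## rate between 0.003 and 0.00075 with a four-epoch half-period, per-channel
## multiplicative noise augmentation (factor uniform in [0.8, 1.3]) plus
## random channel choice, validation on sample AUPRC, and early stopping
## after 15 epochs without improvement.

#' Training configuration
#'
#' @param lrLow,lrHigh cyclical learning-rate bounds (defaults 0.00075 and
#'   0.003).
#' @param cycleEpochs epochs per half cycle: the rate moves from `lrHigh`
#'   to `lrLow` over this many epochs and back over the next (default 4).
#' @param earlyStopPatience epochs without validation-AUPRC improvement
#'   before training stops (default 15).
#' @param noiseLow,noiseHigh bounds of the per-channel multiplicative
#'   amplitude factor used as augmentation (defaults 0.8 and 1.3).
#' @param batchSize chunks per optimization step (default 8).
#' @param chunkLength training chunk length in samples (default 2048).
#' @param maxEpochs hard epoch cap (default 150).
#' @param stepsPerEpoch optimization steps per epoch; default covers the
#'   training set once at the configured chunk length.
#' @param posBoost probability that a sampled chunk is forced to contain a
#'   positive label (class-imbalance handling; default 0.5).
#' @param augment logical, apply the noise augmentation (default TRUE).
#' @param seed optional RNG seed for batch sampling and augmentation.
#' @return A validated configuration list.
#' @export
trainConfig <- function(lrLow = 0.00075, lrHigh = 0.003, cycleEpochs = 4,
                        earlyStopPatience = 15, noiseLow = 0.8,
                        noiseHigh = 1.3, batchSize = 8, chunkLength = 2048,
                        maxEpochs = 150, stepsPerEpoch = NULL,
                        posBoost = 0.5, augment = TRUE, seed = NULL) {
  stopifnot(lrLow > 0, lrLow < lrHigh, noiseLow < noiseHigh,
            earlyStopPatience >= 1, cycleEpochs >= 1, batchSize >= 1)
  list(lrLow = lrLow, lrHigh = lrHigh, cycleEpochs = cycleEpochs,
       earlyStopPatience = earlyStopPatience, noiseLow = noiseLow,
       noiseHigh = noiseHigh, batchSize = batchSize,
       chunkLength = chunkLength, maxEpochs = maxEpochs,
       stepsPerEpoch = stepsPerEpoch, posBoost = posBoost,
       augment = augment, seed = seed)
}

#' Triangular cyclical learning rate
#'
#' Starts at `lrHigh`, decays linearly to `lrLow` after `cycleEpochs`
#' epochs, climbs back over the next `cycleEpochs`, and repeats.
#'
#' @param epoch 1-based epoch number.
#' @param lrLow,lrHigh rate bounds.
#' @param cycleEpochs half-period in epochs.
#' @return The learning rate for `epoch`.
#' @export
lrSchedule <- function(epoch, lrLow = 0.00075, lrHigh = 0.003,
                       cycleEpochs = 4) {
  phase <- (epoch - 1) %% (2 * cycleEpochs)
  ifelse(phase < cycleEpochs,
         lrHigh + (lrLow - lrHigh) * phase / cycleEpochs,
         lrLow + (lrHigh - lrLow) * (phase - cycleEpochs) / cycleEpochs)
}

#' Participant-wise train/validation/test split
#'
#' All recordings of one participant land in the same split, so no
#' participant contributes to both fitting and evaluation. Non-test
#' participants are divided 80/20 into training and validation (within one
#' participant of the exact fractions).
#'
#' @param patients character vector of unique participant ids.
#' @param testIds participant ids reserved for the test split (must be a
#'   subset of `patients`).
#' @param valFraction validation fraction of non-test participants
#'   (default 0.2).
#' @param seed optional RNG seed.
#' @return Named character vector participant id -> "train"/"val"/"test".
#' @export
makeSplit <- function(patients, testIds = character(0), valFraction = 0.2,
                      seed = NULL) {
  if (anyDuplicated(patients)) stop("participant ids must be unique")
  unknown <- setdiff(testIds, patients)
  if (length(unknown))
    stop("test ids not among participants: ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  rest <- setdiff(patients, testIds)
  nVal <- round(valFraction * length(rest))
  valIds <- if (nVal > 0) sample(rest, nVal) else character(0)
  out <- setNames(rep("train", length(patients)), patients)
  out[testIds] <- "test"
  out[valIds] <- "val"
  out
}

#' Noise augmentation of a model input
#'
#' Scales each channel by an independent factor drawn uniformly from
#' `[noiseLow, noiseHigh]`, emulating electrode-gain variability. Channel
#' choice among redundant montage channels is handled upstream by
#' [selectChannels()].
#'
#' @param x channels x samples matrix.
#' @param cfg a [trainConfig()] list.
#' @return The scaled matrix.
#' @export
augmentInput <- function(x, cfg = trainConfig()) {
  f <- runif(nrow(x), cfg$noiseLow, cfg$noiseHigh)
  x * f
}

.sampleChunk <- function(rec, L, posBoost) {
  Tn <- ncol(rec$x)
  if (Tn <= L) {
    pad <- L - Tn
    return(list(x = cbind(rec$x, matrix(0, nrow(rec$x), pad)),
                y = c(rec$y, integer(pad))))
  }
  pos <- rec$posIdx
  if (length(pos) && runif(1) < posBoost) {
    c0 <- pos[sample.int(length(pos), 1)]
    s <- c0 - sample.int(L, 1)
    s <- min(max(s, 0L), Tn - L)
  } else {
    s <- sample.int(Tn - L + 1L, 1) - 1L
  }
  list(x = rec$x[, (s + 1L):(s + L), drop = FALSE], y = rec$y[(s + 1L):(s + L)])
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       v = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    for (nm in c("W", "b")) {
      g <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g * g
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / c1) / (sqrt(state$v[[i]][[nm]] / c2) + eps)
    }
  }
  list(params = params, state = state)
}

.prepSet <- function(data) {
  lapply(data, function(rec) {
    stopifnot(is.matrix(rec$x), length(rec$y) == ncol(rec$x))
    rec$posIdx <- which(rec$y == 1L)
    rec
  })
}

#' Validation sample AUPRC of a model over a record set
#'
#' Concatenates chunk-stitched predictions and labels over all records and
#' computes the sample-level area under the precision-recall curve.
#'
#' @param model a [UNetModel-class].
#' @param data list of records, each `list(x = channels x T matrix, y =
#'   0/1 labels of length T)`.
#' @param chunkLength inference chunk length (default 4096).
#' @return AUPRC in `[0, 1]`.
#' @export
validationAUPRC <- function(model, data, chunkLength = 4096) {
  p <- unlist(lapply(data, function(rec)
    predictProbabilities(model, rec$x, chunkLength)))
  y <- unlist(lapply(data, function(rec) rec$y))
  sampleAUPRC(p, y)
}

#' Train a U-net on labelled 50 Hz record data
#'
#' Optimizes binary cross-entropy with Adam. The learning rate follows the
#' triangular cycle of [lrSchedule()]; each epoch's validation sample
#' AUPRC decides the retained checkpoint, and training stops once the
#' metric has not improved for `earlyStopPatience` epochs (or at
#' `maxEpochs`). Batches are random fixed-length chunks; half of them are
#' steered to contain at least one positive sample to counter the strong
#' class imbalance of arousal labels.
#'
#' @param spec a [unetSpec()] or an already-built [UNetModel-class].
#' @param trainData,valData lists of records (`list(x, y)` as in
#'   [validationAUPRC()]); training labels must contain both classes.
#' @param cfg a [trainConfig()] list.
#' @param verbose print one line per epoch (default FALSE).
#' @return `list(model, history)` where `history` is a data.frame with
#'   columns epoch, lr, loss, val_auprc.
#' @export
trainModel <- function(spec, trainData, valData, cfg = trainConfig(),
                       verbose = FALSE) {
  if (length(trainData) == 0 || length(valData) == 0)
    stop("train and validation sets must be non-empty")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  model <- if (is(spec, "UNetModel")) spec else buildUNet(spec)
  trainData <- .prepSet(trainData)
  valData <- .prepSet(valData)
  if (sum(vapply(trainData, function(r) length(r$posIdx), 0L)) == 0)
    stop("degenerate training data: no positive labels (AUPRC undefined)")

  unit <- model@spec$poolFactor^model@spec$depth
  L <- unit * ceiling(cfg$chunkLength / unit)
  nTrainSamples <- sum(vapply(trainData, function(r) ncol(r$x), 0))
  steps <- cfg$stepsPerEpoch
  if (is.null(steps))
    steps <- max(1L, ceiling(nTrainSamples / (L * cfg$batchSize)))

  state <- .adamInit(model@params)
  best <- list(params = model@params, auprc = -Inf, epoch = 0L)
  hist <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                     val_auprc = numeric(0))
  for (epoch in seq_len(cfg$maxEpochs)) {
    lr <- lrSchedule(epoch, cfg$lrLow, cfg$lrHigh, cfg$cycleEpochs)
    lossAcc <- 0
    for (step in seq_len(steps)) {
      grads <- NULL
      batchLoss <- 0
      for (bi in seq_len(cfg$batchSize)) {
        rec <- trainData[[sample.int(length(trainData), 1)]]
        ch <- .sampleChunk(rec, L, cfg$posBoost)
        if (cfg$augment) ch$x <- augmentInput(ch$x, cfg)
        fwd <- .unetForward(model, ch$x, keepCache = TRUE)
        g <- .unetBackward(model, fwd, ch$y)
        batchLoss <- batchLoss + .bce(fwd$p, ch$y)
        grads <- if (is.null(grads)) g else
          Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b), grads, g)
      }
      grads <- lapply(grads, function(g)
        list(W = g$W / cfg$batchSize, b = g$b / cfg$batchSize))
      upd <- .adamStep(model@params, grads, state, lr)
      model@params <- upd$params
      state <- upd$state
      lossAcc <- lossAcc + batchLoss / cfg$batchSize
    }
    auprc <- validationAUPRC(model, valData, chunkLength = max(L, 4096L))
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   loss = lossAcc / steps, val_auprc = auprc))
    if (verbose)
      message(sprintf("epoch %3d lr %.5f loss %.4f val AUPRC %.4f",
                      epoch, lr, lossAcc / steps, auprc))
    if (auprc > best$auprc)
      best <- list(params = model@params, auprc = auprc, epoch = epoch)
    if (epoch - best$epoch >= cfg$earlyStopPatience) break
  }
  model@params <- best$params
  list(model = model, history = hist, bestEpoch = best$epoch,
       bestAUPRC = best$auprc)
}

# Pick learning-rate bounds from per-rate loss changes: the bounds bracket
# the contiguous run of improving rates that contains the steepest descent.
.lrBoundsFromLosses <- function(lrGrid, deltas) {
  stopifnot(length(lrGrid) == length(deltas), !is.unsorted(lrGrid))
  tol <- 1e-6 * max(abs(deltas[is.finite(deltas)]), 1)
  improving <- is.finite(deltas) & deltas < -tol
  if (!any(improving)) {
    if (all(!is.finite(deltas)))
      stop("loss diverged at every learning rate in the grid")
    if (all(abs(deltas[is.finite(deltas)]) <= tol)) {
      warning("loss flat across the whole grid; returning the full range")
      return(c(low = lrGrid[1], high = lrGrid[length(lrGrid)]))
    }
    stop("no learning rate in the grid improves the loss")
  }
  star <- which.min(ifelse(improving, deltas, Inf))
  lo <- star; while (lo > 1 && improving[lo - 1]) lo <- lo - 1
  hi <- star; while (hi < length(lrGrid) && improving[hi + 1]) hi <- hi + 1
  c(low = lrGrid[lo], high = lrGrid[hi])
}

#' Learning-rate range test
#'
#' For each candidate rate, trains a freshly initialized model for a few
#' steps and records the change in training loss. The suggested bounds
#' bracket the contiguous region of rates that improve the loss and
#' contain the steepest descent; rates where the loss explodes (or is
#' non-finite) fall outside.
#'
#' @param spec a [unetSpec()].
#' @param trainData training records (`list(x, y)`).
#' @param lrGrid increasing vector of candidate learning rates.
#' @param stepsPerRate optimization steps per candidate (default 15).
#' @param cfg a [trainConfig()] list (batch and chunk sizes are reused).
#' @param seed RNG seed used to re-initialize identically per candidate.
#' @return `c(low = , high = )` suggested bounds.
#' @export
lrRangeTest <- function(spec, trainData, lrGrid, stepsPerRate = 15,
                        cfg = trainConfig(), seed = 1) {
  stopifnot(length(lrGrid) >= 1, !is.unsorted(lrGrid))
  trainData <- .prepSet(trainData)
  unit <- spec$poolFactor^spec$depth
  L <- unit * ceiling(cfg$chunkLength / unit)
  deltas <- vapply(lrGrid, function(lr) {
    set.seed(seed)
    model <- buildUNet(spec)
    state <- .adamInit(model@params)
    losses <- numeric(stepsPerRate)
    for (step in seq_len(stepsPerRate)) {
      rec <- trainData[[sample.int(length(trainData), 1)]]
      ch <- .sampleChunk(rec, L, cfg$posBoost)
      fwd <- .unetForward(model, ch$x, keepCache = TRUE)
      losses[step] <- .bce(fwd$p, ch$y)
      if (!is.finite(losses[step])) return(Inf)
      g <- .unetBackward(model, fwd, ch$y)
      upd <- .adamStep(model@params, g, state, lr)
      model@params <- upd$params; state <- upd$state
    }
    half <- ceiling(stepsPerRate / 2)
    mean(losses[(stepsPerRate - half + 1):stepsPerRate]) - mean(losses[1:half])
  }, 0)
  .lrBoundsFromLosses(lrGrid, deltas)
}
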