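## Preprocessing chain: antialiased downsampling of every channel to the
## model rate (50 Hz), moving mean/RMS normalization over an 18-minute
## window, and construction of the 50 Hz binary label track from the
## annotated arousal intervals (with the -2 s / +10 s autonomic-response
## extension applied before rasterization).

#' Antialiased resampling of a signal
#'
#' Applies a zero-phase windowed-sinc FIR low-pass (Hamming window, cutoff
#' at the output Nyquist frequency) before resampling to the target rate.
#' Zero-phase application (forward-backward filtering) preserves event
#' timing, which matters because detected events are later matched to
#' annotations by temporal overlap; it also squares the stopband
#' attenuation of the single-pass design (>= 40 dB per pass above the
#' output Nyquist).
#'
#' @param s numeric signal.
#' @param fsIn input sampling rate (samples/s); must be >= `fsOut`.
#' @param fsOut output sampling rate (default 50).
#' @return Numeric vector of length `round(length(s) * fsOut / fsIn)`. DC is
#'   preserved exactly (filter taps normalized to unit sum).
#' @export
antialiasResample <- function(s, fsIn, fsOut = 50) {
  if (fsIn < fsOut) stop("upsampling not supported (fsIn < fsOut)")
  n <- length(s)
  nOut <- round(n * fsOut / fsIn)
  if (fsIn == fsOut) return(s)
  cutoff <- fsOut / 2
  # Hamming-window design: the ~3.3/N transition must fit between the
  # cutoff and 1.2x cutoff, where aliases would fold into the output band.
  ntaps <- max(101, ceiling(3.3 * fsIn / (0.2 * cutoff)))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  b <- as.numeric(signal::fir1(ntaps - 1, cutoff / (fsIn / 2), type = "low"))
  b <- b / sum(b)
  # odd (anti-symmetric) reflection padding keeps value and slope
  # continuous at the record edges, minimizing filter onset transients
  npad <- min(ntaps, n - 1)
  xp <- c(2 * s[1] - s[(npad + 1):2], s, 2 * s[n] - s[(n - 1):(n - npad)])
  xf <- signal::filtfilt(b, 1, xp)
  xf <- xf[(npad + 1):(npad + n)]
  tOut <- (seq_len(nOut) - 1) / fsOut
  approx(x = (seq_len(n) - 1) / fsIn, y = xf, xout = tOut, rule = 2)$y
}

.runningSum <- function(x, half) {
  # centered moving sum with edge truncation, O(n) via cumsum
  n <- length(x)
  cs <- c(0, cumsum(x))
  hi <- pmin(seq_len(n) + half, n)
  lo <- pmax(seq_len(n) - half, 1L)
  list(sum = cs[hi + 1] - cs[lo], count = hi - lo + 1)
}

#' Moving mean/RMS normalization
#'
#' Standardizes a signal against its local statistics: the moving mean over
#' a centered window (18 min by default) is removed, and the residual is
#' divided by its moving RMS over the same window. The window is truncated
#' at the record edges; a small floor on the RMS guards flat segments. This
#' makes the input scale-free, so electrode gain and montage differences do
#' not reach the model.
#'
#' @param s numeric signal.
#' @param fs sampling rate (samples/s).
#' @param windowLength window length in seconds (default 1080 = 18 min).
#' @param eps RMS floor (default 1e-8).
#' @return Numeric vector, same length as `s`.
#' @export
movingNormalize <- function(s, fs, windowLength = 1080, eps = 1e-8) {
  n <- length(s)
  if (n == 0) return(s)
  half <- max(1L, round(windowLength * fs / 2))
  m <- .runningSum(s, half)
  r <- s - m$sum / m$count
  q <- .runningSum(r * r, half)
  rms <- sqrt(q$sum / q$count)
  r / pmax(rms, eps)
}

#' Extend arousal labels for training
#'
#' Arousals are accompanied by autonomic responses that precede and outlast
#' the cortical EEG shift, so training labels are widened: each event is
#' extended 2 s before its onset and 10 s past its end (defaults), clipped
#' to the record, and overlapping extended intervals are merged into their
#' union (a binary label track cannot represent overlap).
#'
#' @param events an [EventList-class].
#' @param pre seconds added before each onset (default 2).
#' @param post seconds added after each end (default 10).
#' @param duration record duration in seconds (clipping bound).
#' @return An [EventList-class] of disjoint, merged, extended events.
#' @examples
#' extendLabels(EventList(100, 3), duration = 3600)  # [98, 113): 15 s
#' @export
extendLabels <- function(events, pre = 2, post = 10, duration) {
  stopifnot(is(events, "EventList"))
  if (length(events) == 0) return(events)
  start <- pmax(0, eventOnset(events) - pre)
  end <- pmin(duration, eventEnd(events) + post)
  keep <- end > start
  mergeIntervals(start[keep], end[keep])
}

#' Merge overlapping or touching intervals into their union
#'
#' @param start,end numeric vectors of interval bounds (half-open).
#' @param label label for the merged events.
#' @return An [EventList-class] of disjoint intervals.
#' @export
mergeIntervals <- function(start, end, label = "Arousal") {
  if (length(start) == 0) return(EventList())
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- oute <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { outs <- c(outs, ms); oute <- c(oute, me); ms <- start[i]; me <- end[i] }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  EventList(outs, oute - outs, label)
}

#' Rasterize events into a binary label track
#'
#' Sample `t` (0-based) of the output is 1 exactly when its time `t / fs`
#' falls inside some event interval `[onset, onset + duration)`.
#'
#' @param events an [EventList-class] (clipped to the record).
#' @param fs track sampling rate (default 50).
#' @param nSamples track length in samples.
#' @return Integer vector of 0/1 of length `nSamples`.
#' @export
rasterizeLabels <- function(events, fs = 50, nSamples) {
  y <- integer(nSamples)
  tol <- 1e-9
  for (i in seq_len(length(events))) {
    from <- ceiling(eventOnset(events)[i] * fs - tol)
    to <- ceiling(eventEnd(events)[i] * fs - tol) - 1
    from <- max(0, from); to <- min(nSamples - 1, to)
    if (to >= from) y[(from:to) + 1L] <- 1L
  }
  y
}

#' Randomly select one channel per role
#'
#' Draws one channel uniformly at random for each of the EEG, EOG and EMG
#' roles. Used both at training time (as augmentation over redundant
#' montage channels) and at inference.
#'
#' @param rec a [PSGRecording-class] whose role map covers EEG, EOG, EMG.
#' @param roles which roles to draw (default all three).
#' @return Named character vector role -> channel name.
#' @export
selectChannels <- function(rec, roles = c("EEG", "EOG", "EMG")) {
  out <- character(0)
  for (role in roles) {
    chs <- roleChannels(rec, role)
    if (is.null(chs) || length(chs) == 0)
      stop("no channel available for role ", role)
    out[role] <- if (length(chs) == 1) chs else chs[sample.int(length(chs), 1)]
  }
  out
}

#' Preprocess a recording into the model's three-channel input
#'
#' Runs the full chain on one channel per role: antialiased resampling to
#' `fsModel`, then moving mean/RMS normalization. All three rows share the
#' common length `round(duration * fsModel)`.
#'
#' @param rec a [PSGRecording-class].
#' @param channels named character vector role -> channel (as returned by
#'   [selectChannels()]); default selects randomly.
#' @param fsModel model sampling rate (default 50).
#' @param windowLength normalization window in seconds (default 1080).
#' @return A numeric matrix with rows EEG, EOG, EMG at `fsModel`.
#' @export
preprocessRecording <- function(rec, channels = NULL, fsModel = 50,
                                windowLength = 1080) {
  if (is.null(channels)) channels <- selectChannels(rec)
  Tn <- round(recordingDuration(rec) * fsModel)
  x <- matrix(0, nrow = length(channels), ncol = Tn,
              dimnames = list(names(channels), NULL))
  for (i in seq_along(channels)) {
    s <- channelSignal(rec, channels[[i]])
    fsIn <- channelRate(rec, channels[[i]])
    r <- antialiasResample(s, fsIn, fsModel)
    if (length(r) != Tn) r <- r[seq_len(Tn)]
    x[i, ] <- movingNormalize(r, fsModel, windowLength)
  }
  x
}

#' Build the 50 Hz training label track for a recording
#'
#' Applies the label extension ([extendLabels()]) and rasterizes the result
#' at the model rate.
#'
#' @param events annotated arousal [EventList-class].
#' @param duration record duration (s).
#' @param fsModel model sampling rate (default 50).
#' @param pre,post extension margins in seconds (defaults 2 and 10).
#' @return Integer 0/1 vector of length `round(duration * fsModel)`.
#' @export
makeLabelTrack <- function(events, duration, fsModel = 50, pre = 2, post = 10) {
  ext <- extendLabels(events, pre = pre, post = post, duration = duration)
  rasterizeLabels(ext, fs = fsModel, nSamples = round(duration * fsModel))
}
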