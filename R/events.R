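## Probability-to-event conversion: the 50 Hz probability track is averaged
## to 1-s segments, thresholded, positive runs separated by gaps of at most
## the patience (3 s) are merged, and events shorter than the minimum
## length (15 s, matching the -2 s/+10 s label extension) are discarded.
## The decision threshold is chosen on a validation set by micro event F1.

#' Post-processing configuration
#'
#' @param segmentLength averaging segment in seconds (default 1).
#' @param threshold decision threshold in (0, 1) (default 0.5).
#' @param patience maximum gap in seconds between positive runs that are
#'   merged into one event (default 3; gaps `<= patience` merge).
#' @param minEventLength minimum retained event length in seconds (default
#'   15, consistent with the training-label extension).
#' @param aasmMinLength the 3-s AASM floor, applied instead of
#'   `minEventLength` when label extension is disabled upstream.
#' @return A validated configuration list.
#' @export
postprocessConfig <- function(segmentLength = 1, threshold = 0.5,
                              patience = 3, minEventLength = 15,
                              aasmMinLength = 3) {
  stopifnot(threshold > 0, threshold < 1, patience >= 0,
            minEventLength >= aasmMinLength, segmentLength > 0)
  list(segmentLength = segmentLength, threshold = threshold,
       patience = patience, minEventLength = minEventLength,
       aasmMinLength = aasmMinLength)
}

#' Average a probability track into fixed-length segments
#'
#' @param p probability track (numeric).
#' @param fs track sampling rate (default 50).
#' @param segmentLength segment length in seconds (default 1).
#' @return Numeric vector of segment means; a trailing partial segment is
#'   averaged over its actual samples.
#' @export
probsToSegments <- function(p, fs = 50, segmentLength = 1) {
  n <- length(p)
  spseg <- round(fs * segmentLength)
  nFull <- n %/% spseg
  out <- numeric(0)
  if (nFull > 0)
    out <- colMeans(matrix(p[seq_len(nFull * spseg)], nrow = spseg))
  if (n > nFull * spseg)
    out <- c(out, mean(p[(nFull * spseg + 1):n]))
  out
}

#' Convert thresholded segments into discrete arousal events
#'
#' Binarizes the segment sequence at the threshold, merges positive runs
#' separated by gaps of at most the patience, and drops merged events
#' shorter than the minimum length.
#'
#' @param seg numeric vector of segment scores (one per `segmentLength` s).
#' @param cfg a [postprocessConfig()] list.
#' @return An [EventList-class]; events are disjoint, sorted, and each at
#'   least `minEventLength` seconds long.
#' @examples
#' seg <- rep(c(0, 1, 0, 1, 0), c(10, 10, 2, 13, 10))
#' segmentsToEvents(seg, postprocessConfig(threshold = 0.5))
#' @export
segmentsToEvents <- function(seg, cfg = postprocessConfig()) {
  sl <- cfg$segmentLength
  pos <- seg >= cfg$threshold
  if (!any(pos)) return(EventList())
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = (starts[r$values] - 1) * sl,
                     end = ends[r$values] * sl)
  # merge runs whose gap is <= patience
  ms <- runs$start[1]; me <- runs$end[1]
  outs <- oute <- numeric(0)
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - me <= cfg$patience) me <- runs$end[i]
    else { outs <- c(outs, ms); oute <- c(oute, me)
           ms <- runs$start[i]; me <- runs$end[i] }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  keep <- (oute - outs) >= cfg$minEventLength
  EventList(outs[keep], (oute - outs)[keep], "Arousal")
}

#' Convert a probability track to events
#'
#' Convenience composition of [probsToSegments()] and [segmentsToEvents()].
#'
#' @param p probability track at `fs`.
#' @param fs track sampling rate (default 50).
#' @param cfg a [postprocessConfig()] list.
#' @return An [EventList-class].
#' @export
probsToEvents <- function(p, fs = 50, cfg = postprocessConfig()) {
  segmentsToEvents(probsToSegments(p, fs, cfg$segmentLength), cfg)
}

#' Optimize the decision threshold on a validation set
#'
#' Scans a threshold grid and returns the value maximizing the micro event
#' F1 (confusion counts summed over records before the ratio) of the
#' post-processed events against the reference annotations. Ties break
#' toward the lower threshold. Thresholds producing no usable confusion
#' counts at all score 0.
#'
#' @param valProbs list of probability tracks (one per record, at `fs`).
#' @param valTruth list of reference [EventList-class] objects.
#' @param grid candidate thresholds in (0, 1); default 0.05 to 0.95 by 0.05.
#' @param cfg a [postprocessConfig()] list (its `threshold` is ignored).
#' @param fs track sampling rate (default 50).
#' @return The selected threshold.
#' @export
optimizeThreshold <- function(valProbs, valTruth,
                              grid = seq(0.05, 0.95, by = 0.05),
                              cfg = postprocessConfig(), fs = 50) {
  if (length(valProbs) == 0 || length(valProbs) != length(valTruth))
    stop("validation set must be non-empty with matching truth")
  stopifnot(all(grid > 0), all(grid < 1), length(grid) >= 1)
  grid <- sort(grid)
  segs <- lapply(valProbs, probsToSegments, fs = fs,
                 segmentLength = cfg$segmentLength)
  f1s <- vapply(grid, function(th) {
    cfgi <- cfg; cfgi$threshold <- th
    counts <- Map(function(sg, tr)
      matchEvents(tr, segmentsToEvents(sg, cfgi)), segs, valTruth)
    tp <- sum(vapply(counts, `[[`, 0, "tp"))
    fp <- sum(vapply(counts, `[[`, 0, "fp"))
    fn <- sum(vapply(counts, `[[`, 0, "fn"))
    if (tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  grid[which.max(f1s)]   # which.max returns the first (lowest) maximizer
}
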