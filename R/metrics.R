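## Evaluation: sample-level AUPRC on the probability track, event-level
## overlap matching with the asymmetric double-overlap rules, micro F1
## pooled over records, and the clinically oriented arousal-index (ArI)
## error with its distributional summaries and Pearson correlation.

#' Sample-level area under the precision-recall curve
#'
#' Computes AUPRC over all decision thresholds of the score track against
#' binary labels, with ties handled by grouping equal scores into a single
#' threshold step (average-precision form: `sum((R_i - R_{i-1}) * P_i)`
#' over descending-threshold steps). A constant score yields a single PR
#' point whose precision is the label prevalence.
#'
#' @param p numeric scores (higher = more arousal-like).
#' @param y binary labels (0/1), same length as `p`; both classes must be
#'   present.
#' @return AUPRC in `[0, 1]`.
#' @export
sampleAUPRC <- function(p, y) {
  if (length(p) != length(y)) stop("p and y must have the same length")
  y <- as.integer(y != 0)
  npos <- sum(y)
  if (npos == 0 || npos == length(y))
    stop("AUPRC undefined: labels contain a single class")
  o <- order(p, decreasing = TRUE)
  ys <- y[o]; ps <- p[o]
  ctp <- cumsum(ys)
  n <- length(ys)
  # threshold steps at the last index of each tied score block
  stepIdx <- which(ps != c(ps[-1], NA))
  stepIdx[length(stepIdx) + 1] <- n
  stepIdx <- unique(stepIdx)
  tp <- ctp[stepIdx]
  prec <- tp / stepIdx
  rec <- tp / npos
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

.overlaps <- function(s1, e1, s2, e2) (s1 < e2) & (s2 < e1)

#' Match predicted events against reference events
#'
#' Any temporal overlap (non-empty intersection of half-open intervals)
#' between a reference and a predicted event marks a true positive, with
#' two asymmetric rules for double coverage: two predicted events
#' overlapping a single reference event count one true positive and one
#' false negative, while two reference events overlapping one predicted
#' event count two true positives and one false positive. These rules
#' extend to k-fold coverage: a reference overlapped by k predictions
#' contributes 1 TP and k-1 FN; a prediction overlapping k references
#' contributes k-1 FP beyond its matches. Unmatched predictions are FP,
#' unmatched references FN.
#'
#' @param truth reference [EventList-class] (internally disjoint).
#' @param pred predicted [EventList-class] (internally disjoint).
#' @return `list(tp, fp, fn)` non-negative integer counts.
#' @examples
#' matchEvents(EventList(10, 10), EventList(c(12, 18), c(3, 4)))
#' # one TP, one FN
#' @export
matchEvents <- function(truth, pred) {
  stopifnot(is(truth, "EventList"), is(pred, "EventList"))
  for (ev in list(truth, pred)) {
    if (length(ev) > 1 && any(eventOnset(ev)[-1] < eventEnd(ev)[-length(ev)]))
      stop("events within one list must be disjoint")
  }
  nt <- length(truth); np <- length(pred)
  if (nt == 0 && np == 0) return(list(tp = 0L, fp = 0L, fn = 0L))
  ts <- eventOnset(truth); te <- eventEnd(truth)
  ps <- eventOnset(pred); pe <- eventEnd(pred)
  oT <- integer(nt)  # predictions overlapping each truth
  oP <- integer(np)  # truths overlapping each prediction
  for (i in seq_len(nt)) {
    hit <- .overlaps(ts[i], te[i], ps, pe)
    oT[i] <- sum(hit)
    oP[hit] <- oP[hit] + 1L
  }
  tp <- sum(oT > 0)
  fn <- sum(oT == 0) + sum(pmax(oT - 1L, 0L))
  fp <- sum(oP == 0) + sum(pmax(oP - 1L, 0L))
  list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' Micro F1 over pooled confusion counts
#'
#' Record-wise confusion matrices are summed before the ratio:
#' `2*sum(TP) / (2*sum(TP) + sum(FP) + sum(FN))`.
#'
#' @param counts list of `list(tp, fp, fn)` (one per record), or a single
#'   such list.
#' @return Micro F1 in `[0, 1]`.
#' @export
microF1 <- function(counts) {
  if (!is.null(counts$tp)) counts <- list(counts)
  if (length(counts) == 0) stop("no confusion counts supplied")
  tp <- sum(vapply(counts, `[[`, 0, "tp"))
  fp <- sum(vapply(counts, `[[`, 0, "fp"))
  fn <- sum(vapply(counts, `[[`, 0, "fn"))
  if (tp + fp + fn == 0)
    stop("micro F1 undefined: all confusion counts are zero")
  2 * tp / (2 * tp + fp + fn)
}

#' Arousal index
#'
#' Number of arousal events per hour of sleep. Total sleep time follows
#' the AASM convention: 30 s times the number of non-wake hypnogram
#' epochs.
#'
#' @param events an [EventList-class].
#' @param hyp a [Hypnogram-class] with positive total sleep time.
#' @return Events per hour of sleep.
#' @examples
#' h <- Hypnogram(rep("N2", 240))           # 2 h of sleep
#' arousalIndex(EventList(seq(0, 5900, 100), rep(5, 60)), h)  # 30/h
#' @export
arousalIndex <- function(events, hyp) {
  stopifnot(is(events, "EventList"), is(hyp, "Hypnogram"))
  tst <- totalSleepTime(hyp)
  if (tst <= 0) stop("arousal index undefined: zero total sleep time")
  length(events) / (tst / 3600)
}

#' Evaluate one record
#'
#' @param truth reference [EventList-class].
#' @param pred predicted [EventList-class].
#' @param hyp the record's [Hypnogram-class].
#' @param p optional probability track, with `y` the matching 0/1 label
#'   track, for sample AUPRC (NA if omitted or single-class).
#' @param y see `p`.
#' @param id record identifier.
#' @return One-row data.frame: id, tp, fp, fn, auprc, ari_pred, ari_true,
#'   ari_error.
#' @export
evaluateRecord <- function(truth, pred, hyp, p = NULL, y = NULL, id = "rec") {
  cc <- matchEvents(truth, pred)
  auprc <- NA_real_
  if (!is.null(p) && !is.null(y) && length(unique(as.integer(y != 0))) == 2)
    auprc <- sampleAUPRC(p, y)
  ariT <- arousalIndex(truth, hyp)
  ariP <- arousalIndex(pred, hyp)
  data.frame(id = id, tp = cc$tp, fp = cc$fp, fn = cc$fn, auprc = auprc,
             ari_pred = ariP, ari_true = ariT, ari_error = abs(ariP - ariT),
             stringsAsFactors = FALSE)
}

#' Aggregate per-record evaluations into a report
#'
#' Pools confusion counts into the micro F1 and summarizes the ArI error
#' (mean +/- sd, median, IQR) and the Pearson correlation between
#' predicted and reference ArI across records. A degenerate correlation
#' (zero variance on either side, or fewer than 2 records) is reported as
#' NA, not coerced to 1.
#'
#' @param rows data.frame of [evaluateRecord()] rows (rbind-ed).
#' @return A [SleepEvalReport-class].
#' @export
evaluateSet <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1)
  counts <- lapply(seq_len(nrow(rows)), function(i)
    list(tp = rows$tp[i], fp = rows$fp[i], fn = rows$fn[i]))
  q <- quantile(rows$ari_error, c(0.25, 0.5, 0.75), names = FALSE)
  r <- NA_real_
  if (nrow(rows) >= 2 && sd(rows$ari_pred) > 0 && sd(rows$ari_true) > 0)
    r <- cor(rows$ari_pred, rows$ari_true)
  new("SleepEvalReport", records = rows, summary = list(
    micro_f1 = microF1(counts),
    mean_auprc = if (all(is.na(rows$auprc))) NA_real_ else
      mean(rows$auprc, na.rm = TRUE),
    ari_error_mean = mean(rows$ari_error),
    ari_error_sd = if (nrow(rows) >= 2) sd(rows$ari_error) else NA_real_,
    ari_error_q1 = q[1], ari_error_median = q[2], ari_error_q3 = q[3],
    ari_diff_mean = mean(rows$ari_pred - rows$ari_true),
    ari_diff_sd = if (nrow(rows) >= 2) sd(rows$ari_pred - rows$ari_true)
      else NA_real_,
    ari_r = r))
}
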