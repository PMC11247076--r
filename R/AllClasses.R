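#' @import methods
#' @importFrom stats approx cor cor.test kruskal.test pnorm quantile rexp
#'   rnorm runif sd setNames shapiro.test var
#' @importFrom utils read.table write.table head tail
NULL

## Central S4 containers. Events and hypnograms use the package-wide time
## convention: seconds from record start, half-open intervals [onset,
## onset + duration), hypnogram epoch i (1-based) covering [30(i-1), 30i).

#' EventList: typed intervals in seconds
#'
#' An ordered list of annotated events, each a half-open interval
#' `[onset, onset + duration)` in seconds from record start. Construction
#' sorts events by onset; onsets must be non-negative and durations strictly
#' positive.
#'
#' @slot onset numeric vector of event onsets (s).
#' @slot duration numeric vector of event durations (s).
#' @slot label character vector of event labels.
#' @export
setClass("EventList",
  representation(onset = "numeric", duration = "numeric", label = "character"),
  prototype(onset = numeric(0), duration = numeric(0), label = character(0))
)

setValidity("EventList", function(object) {
  n <- length(object@onset)
  if (length(object@duration) != n || length(object@label) != n)
    return("onset, duration and label must have equal length")
  if (n == 0L) return(TRUE)
  if (any(!is.finite(object@onset)) || any(!is.finite(object@duration)))
    return("onsets and durations must be finite")
  if (any(object@onset < 0)) return("onsets must be >= 0")
  if (any(object@duration <= 0)) return("durations must be > 0")
  if (is.unsorted(object@onset)) return("events must be sorted by onset")
  TRUE
})

#' Construct an EventList
#'
#' @param onset numeric, onsets in seconds from record start.
#' @param duration numeric, durations in seconds (> 0).
#' @param label character, event labels (recycled).
#' @return An [EventList-class] sorted by onset.
#' @examples
#' ev <- EventList(onset = c(30, 10), duration = c(5, 3))
#' eventOnset(ev)   # 10 30  (sorted)
#' @export
EventList <- function(onset = numeric(0), duration = numeric(0),
                      label = "Arousal") {
  onset <- as.numeric(onset); duration <- as.numeric(duration)
  label <- rep_len(as.character(label), length(onset))
  o <- order(onset, duration)
  new("EventList", onset = onset[o], duration = duration[o], label = label[o])
}

#' @describeIn EventList number of events
#' @param x an EventList
#' @export
setMethod("length", "EventList", function(x) length(x@onset))

#' Event accessors
#'
#' @param x an [EventList-class].
#' @return `eventOnset`, `eventDuration`, `eventEnd`: numeric vectors in
#'   seconds; `eventLabel`: character.
#' @export
eventOnset <- function(x) x@onset
#' @rdname eventOnset
#' @export
eventDuration <- function(x) x@duration
#' @rdname eventOnset
#' @export
eventEnd <- function(x) x@onset + x@duration
#' @rdname eventOnset
#' @export
eventLabel <- function(x) x@label

#' @export
setMethod("show", "EventList", function(object) {
  cat(sprintf("EventList with %d event(s)\n", length(object)))
  if (length(object)) {
    df <- as.data.frame(object)
    print(head(df, 6))
    if (nrow(df) > 6) cat(sprintf("... and %d more\n", nrow(df) - 6L))
  }
  invisible(object)
})

#' @export
as.data.frame.EventList <- function(x, ...) {
  data.frame(onset_s = x@onset, duration_s = x@duration, label = x@label,
             stringsAsFactors = FALSE)
}

#' Hypnogram: 30-s epoch sleep-stage sequence
#'
#' Sleep stages scored in fixed 30-s epochs. Stage vocabulary follows AASM:
#' W (wake), N1, N2, N3 (NREM depths) and R (REM). Epoch i covers
#' `[30(i-1), 30i)` seconds.
#'
#' @slot stages character vector of stages in \{W, N1, N2, N3, R\}.
#' @slot epochLength numeric, fixed at 30 s.
#' @export
setClass("Hypnogram",
  representation(stages = "character", epochLength = "numeric"),
  prototype(stages = character(0), epochLength = 30)
)

.STAGES <- c("W", "N1", "N2", "N3", "R")

setValidity("Hypnogram", function(object) {
  if (!identical(object@epochLength, 30)) return("epochLength is fixed at 30 s")
  bad <- setdiff(unique(object@stages), .STAGES)
  if (length(bad)) return(paste("unknown stages:", paste(bad, collapse = ", ")))
  TRUE
})

#' Construct a Hypnogram
#'
#' @param stages character vector of 30-s epoch stages (W, N1, N2, N3, R).
#' @return A [Hypnogram-class].
#' @export
Hypnogram <- function(stages) {
  new("Hypnogram", stages = as.character(stages), epochLength = 30)
}

#' @describeIn Hypnogram number of 30-s epochs
#' @param x a Hypnogram
#' @export
setMethod("length", "Hypnogram", function(x) length(x@stages))

#' Hypnogram accessors
#'
#' `hypnoStages` returns the stage vector; `totalSleepTime` the total sleep
#' time in seconds (30 s times the number of non-wake epochs, the AASM TST
#' convention); `sleepMask` a logical vector marking non-wake epochs.
#'
#' @param x a [Hypnogram-class].
#' @export
hypnoStages <- function(x) x@stages
#' @rdname hypnoStages
#' @export
totalSleepTime <- function(x) 30 * sum(x@stages != "W")
#' @rdname hypnoStages
#' @export
sleepMask <- function(x) x@stages != "W"

#' @export
setMethod("show", "Hypnogram", function(object) {
  tst <- totalSleepTime(object)
  cat(sprintf("Hypnogram: %d epochs (%.1f h), TST %.1f min\n",
              length(object), length(object) * 30 / 3600, tst / 60))
  print(table(factor(object@stages, levels = .STAGES)))
  invisible(object)
})

#' PSGRecording: multichannel polysomnogram
#'
#' A polysomnographic recording: named channels with per-channel sample
#' rates, a role map assigning channels to the signal types the detector
#' consumes (EEG, EOG, chin EMG), total duration, and per-recording
#' metadata (age, sex, diagnosis groups).
#'
#' @slot id character recording identifier.
#' @slot signals named list of numeric vectors, one per channel.
#' @slot sampleRate named numeric vector, samples/s per channel.
#' @slot roles named list mapping "EEG"/"EOG"/"EMG" to channel names.
#' @slot duration numeric, record duration in seconds.
#' @slot metadata list with optional `age`, `sex`, `diagnosis_groups`.
#' @export
setClass("PSGRecording",
  representation(id = "character", signals = "list", sampleRate = "numeric",
                 roles = "list", duration = "numeric", metadata = "list")
)

.DIAGNOSIS_GROUPS <- c("SRBD", "SRBD-Therapy", "SRMD", "Insomnia",
                       "Hypersomnia", "Parasomnia", "NormalFinding")

setValidity("PSGRecording", function(object) {
  if (length(object@duration) != 1 || !is.finite(object@duration) ||
      object@duration <= 0)
    return("duration must be a single positive number")
  chn <- names(object@signals)
  if (is.null(chn) || any(chn == "")) return("all channels must be named")
  if (!setequal(chn, names(object@sampleRate)))
    return("signals and sampleRate must name the same channels")
  for (ch in chn) {
    expected <- round(object@duration * object@sampleRate[[ch]])
    if (length(object@signals[[ch]]) != expected)
      return(sprintf("channel '%s': length %d != round(duration * rate) = %d",
                     ch, length(object@signals[[ch]]), expected))
  }
  badrole <- setdiff(names(object@roles), c("EEG", "EOG", "EMG"))
  if (length(badrole))
    return(paste("unknown roles:", paste(badrole, collapse = ", ")))
  for (role in names(object@roles)) {
    missing <- setdiff(object@roles[[role]], chn)
    if (length(missing))
      return(sprintf("role %s refers to unknown channel(s): %s", role,
                     paste(missing, collapse = ", ")))
  }
  dg <- object@metadata$diagnosis_groups
  if (!is.null(dg)) {
    bad <- setdiff(dg, .DIAGNOSIS_GROUPS)
    if (length(bad))
      return(paste("unknown diagnosis groups:", paste(bad, collapse = ", ")))
    if ("SRBD-Therapy" %in% dg && "NormalFinding" %in% dg)
      return("SRBD-Therapy is exclusive of NormalFinding")
  }
  TRUE
})

#' Construct a PSGRecording
#'
#' @param id recording identifier.
#' @param signals named list of numeric channel vectors.
#' @param sampleRate named numeric vector of per-channel rates (samples/s).
#' @param roles named list mapping roles (EEG, EOG, EMG) to channel names.
#' @param duration record duration in seconds; defaults to the duration
#'   implied by the first channel.
#' @param metadata list with optional `age` (years), `sex`,
#'   `diagnosis_groups` (subset of SRBD, SRBD-Therapy, SRMD, Insomnia,
#'   Hypersomnia, Parasomnia, NormalFinding).
#' @return A [PSGRecording-class].
#' @export
PSGRecording <- function(id, signals, sampleRate, roles = list(),
                         duration = NULL, metadata = list()) {
  sampleRate <- unlist(sampleRate)
  if (is.null(duration))
    duration <- length(signals[[1]]) / sampleRate[[names(signals)[1]]]
  new("PSGRecording", id = as.character(id), signals = signals,
      sampleRate = sampleRate, roles = roles, duration = as.numeric(duration),
      metadata = metadata)
}

#' PSGRecording accessors
#'
#' @param x a [PSGRecording-class].
#' @param role one of "EEG", "EOG", "EMG".
#' @param channel a channel name.
#' @export
recordingId <- function(x) x@id
#' @rdname recordingId
#' @export
recordingDuration <- function(x) x@duration
#' @rdname recordingId
#' @export
channelNames <- function(x) names(x@signals)
#' @rdname recordingId
#' @export
channelSignal <- function(x, channel) x@signals[[channel]]
#' @rdname recordingId
#' @export
channelRate <- function(x, channel) x@sampleRate[[channel]]
#' @rdname recordingId
#' @export
roleChannels <- function(x, role) x@roles[[role]]
#' @rdname recordingId
#' @export
recordingMeta <- function(x) x@metadata

#' @export
setMethod("show", "PSGRecording", function(object) {
  cat(sprintf("PSGRecording '%s': %.2f h, %d channel(s)\n", object@id,
              object@duration / 3600, length(object@signals)))
  for (ch in names(object@signals))
    cat(sprintf("  %-12s %6g Hz  (%d samples)\n", ch,
                object@sampleRate[[ch]], length(object@signals[[ch]])))
  if (length(object@roles))
    cat("  roles:", paste(sprintf("%s=%s", names(object@roles),
        vapply(object@roles, paste, "", collapse = "/")), collapse = ", "),
        "\n")
  invisible(object)
})

#' SleepEvalReport: per-record and pooled evaluation results
#'
#' Holds per-record confusion counts, sample AUPRC and arousal-index values
#' together with pooled summaries: micro F1 (record-wise confusion matrices
#' are summed before the ratio), mean/sd and median/IQR of the ArI error,
#' and the Pearson correlation between predicted and reference ArI.
#'
#' @slot records data.frame with one row per record (id, tp, fp, fn, auprc,
#'   ari_pred, ari_true, ari_error).
#' @slot summary list of pooled metrics.
#' @export
setClass("SleepEvalReport",
  representation(records = "data.frame", summary = "list")
)

#' @rdname SleepEvalReport-class
#' @param x a SleepEvalReport
#' @export
reportRecords <- function(x) x@records
#' @rdname SleepEvalReport-class
#' @export
reportSummary <- function(x) x@summary

#' @export
setMethod("show", "SleepEvalReport", function(object) {
  s <- object@summary
  cat(sprintf("SleepEvalReport over %d record(s)\n", nrow(object@records)))
  cat(sprintf("  micro F1      : %.3f\n", s$micro_f1))
  if (!is.null(s$mean_auprc) && is.finite(s$mean_auprc))
    cat(sprintf("  mean AUPRC    : %.3f\n", s$mean_auprc))
  cat(sprintf("  ArI error     : mean %.2f +/- %.2f, median %.2f (IQR %.2f-%.2f) /h\n",
              s$ari_error_mean, s$ari_error_sd, s$ari_error_median,
              s$ari_error_q1, s$ari_error_q3))
  cat(sprintf("  ArI Pearson r : %s\n",
              if (is.na(s$ari_r)) "NA" else sprintf("%.3f", s$ari_r)))
  invisible(object)
})
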