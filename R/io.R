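## PSG input/output.
##
## Signals travel as EDF (European Data Format), the de-facto interchange
## format for polysomnography: a 256-byte fixed header, one 256-byte header
## block per signal, then data records of 16-bit little-endian integers with
## linear physical scaling. Annotations use the package's native plain-text
## dialect: a TSV with columns onset_s, duration_s, label. Hypnograms are
## one stage symbol per line; cohort metadata is a CSV.

.pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

.edfNum <- function(x, width) .pad(format(x, trim = TRUE, scientific = FALSE), width)

#' Write a recording to an EDF file
#'
#' Serializes all channels of a [PSGRecording-class] as EDF. Signals are
#' linearly quantized to 16-bit integers over their observed physical range,
#' so a write/read round-trip is exact only up to the digitization step
#' (range / 65535). The data-record length is chosen as the smallest whole
#' number of seconds for which every channel contributes an integer number
#' of samples; the record duration must be an integer multiple of it.
#'
#' @param rec a [PSGRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "PSGRecording"))
  validObject(rec)
  chn <- channelNames(rec)
  rates <- rec@sampleRate[chn]
  recdur <- NA_integer_
  for (d in 1:10) {
    if (all(abs(rates * d - round(rates * d)) < 1e-9)) { recdur <- d; break }
  }
  if (is.na(recdur))
    stop("cannot express channel rates as integer samples over <= 10 s records")
  if (abs(rec@duration / recdur - round(rec@duration / recdur)) > 1e-9)
    stop("record duration must be an integer multiple of ", recdur, " s for EDF export")
  nrec <- as.integer(round(rec@duration / recdur))
  ns <- length(chn)
  spr <- as.integer(round(rates * recdur))  # samples per data record

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    .pad("0", 8), .pad("X X X X", 80),
    .pad(paste("Startdate 01-JAN-2000", rec@id), 80),
    .pad("01.01.00", 8), .pad("00.00.00", 8),
    .edfNum(256L * (ns + 1L), 8), .pad("", 44),
    .edfNum(nrec, 8), .edfNum(recdur, 8), .edfNum(ns, 4)
  ), con, eos = NULL)

  pmin <- pmax_ <- numeric(ns)
  for (i in seq_len(ns)) {
    s <- rec@signals[[chn[i]]]
    lo <- min(s); hi <- max(s)
    if (hi - lo < 1e-12) { lo <- lo - 1; hi <- hi + 1 }
    pmin[i] <- lo; pmax_[i] <- hi
  }
  field <- function(vals, width) writeChar(
    paste(vapply(vals, .pad, "", width = width), collapse = ""), con, eos = NULL)
  field(chn, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(pmin, format = "g", digits = 7), 8)
  field(formatC(pmax_, format = "g", digits = 7), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(spr, 8)
  field(rep("", ns), 32)

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    s <- rec@signals[[chn[i]]]
    d <- round((s - pmin[i]) / (pmax_[i] - pmin[i]) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }
  # interleave per data record
  idx <- lapply(seq_len(ns), function(i) matrix(dig[[i]], nrow = spr[i]))
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns))
      writeBin(idx[[i]][, r], con, size = 2L, endian = "little")
  }
  invisible(path)
}

.readEDFHeader <- function(con) {
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  startdate <- rd(8); starttime <- rd(8)
  nbytes <- as.integer(rd(8)); reserved <- rd(44)
  nrec <- as.integer(rd(8)); recdur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); transducer <- fld(80); dim <- fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  prefilter <- fld(80); spr <- as.integer(fld(8)); fld(32)
  list(recording = recording, nrec = nrec, recdur = recdur, ns = ns,
       labels = labels, pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax,
       spr = spr)
}

#' Read a PSG recording from an EDF file
#'
#' Reads all signals of an EDF file and attaches the channel-role map the
#' detector needs. Channels are referenced by an explicit role map rather
#' than name heuristics because electrode montages differ between
#' laboratories and datasets.
#'
#' @param path an EDF file written by [writeRecording()] or any
#'   EDF-compliant recorder (continuous records, 16-bit samples).
#' @param channelMap named list mapping roles ("EEG", "EOG", "EMG") to one
#'   or more channel names that must exist in the file. Roles may be
#'   omitted; requesting a role whose channels are absent is an error
#'   naming the role.
#' @param metadata optional metadata list attached to the recording.
#' @return A [PSGRecording-class] with per-channel native sample rates.
#' @export
readRecording <- function(path, channelMap = list(), metadata = list()) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .readEDFHeader(con)
  ns <- h$ns
  raw <- vector("list", ns)
  store <- lapply(seq_len(ns), function(i)
    matrix(0L, nrow = h$spr[i], ncol = h$nrec))
  for (r in seq_len(h$nrec)) {
    for (i in seq_len(ns)) {
      store[[i]][, r] <- readBin(con, "integer", n = h$spr[i], size = 2L,
                                 signed = TRUE, endian = "little")
    }
  }
  signals <- list()
  rates <- numeric(0)
  for (i in seq_len(ns)) {
    scale <- (h$pmax[i] - h$pmin[i]) / (h$dmax[i] - h$dmin[i])
    signals[[h$labels[i]]] <- (as.vector(store[[i]]) - h$dmin[i]) * scale + h$pmin[i]
    rates[h$labels[i]] <- h$spr[i] / h$recdur
  }
  for (role in names(channelMap)) {
    missing <- setdiff(channelMap[[role]], names(signals))
    if (length(missing))
      stop(sprintf("role %s: channel(s) %s not present in %s", role,
                   paste(missing, collapse = ", "), path))
  }
  id <- sub("^Startdate \\S+ ?", "", h$recording)
  if (!nzchar(id)) id <- basename(path)
  PSGRecording(id = id, signals = signals, sampleRate = rates,
               roles = channelMap, duration = h$nrec * h$recdur,
               metadata = metadata)
}

#' Read or write arousal event annotations
#'
#' The native annotation dialect is a tab-separated table with header
#' `onset_s  duration_s  label`, one event per row, seconds from record
#' start. Rows are sorted by onset on reading; writing preserves the sorted
#' order, so write-then-read is the identity.
#'
#' @param path file path.
#' @return `readEvents`: an [EventList-class].
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("cannot read events file: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("numeric", "numeric", "character"))
  if (nrow(df) == 0) return(EventList())
  if (any(!is.finite(df$onset_s)) || any(!is.finite(df$duration_s)))
    stop("events file contains non-numeric onset/duration")
  if (any(df$duration_s <= 0))
    stop("events file contains non-positive durations")
  if (any(df$onset_s < 0))
    stop("events file contains negative onsets")
  EventList(df$onset_s, df$duration_s, df$label)
}

#' @rdname readEvents
#' @param events an [EventList-class].
#' @export
writeEvents <- function(events, path) {
  stopifnot(is(events, "EventList"))
  write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read or write a hypnogram
#'
#' Plain text, one 30-s epoch stage symbol (W, N1, N2, N3, R) per line.
#'
#' @param path file path.
#' @return `readHypnogram`: a [Hypnogram-class].
#' @export
readHypnogram <- function(path) {
  if (!file.exists(path)) stop("cannot read hypnogram file: ", path)
  stages <- readLines(path)
  stages <- stages[nzchar(stages)]
  Hypnogram(stages)
}

#' @rdname readHypnogram
#' @param hyp a [Hypnogram-class].
#' @export
writeHypnogram <- function(hyp, path) {
  stopifnot(is(hyp, "Hypnogram"))
  writeLines(hypnoStages(hyp), path)
  invisible(path)
}

#' Read or write cohort metadata
#'
#' One row per recording: `id`, `age` (years), `sex`, `groups` (diagnosis
#' groups, `;`-separated; groups other than SRBD-Therapy are non-exclusive).
#'
#' @param path CSV file path.
#' @return `readMetadataTable`: a data.frame.
#' @export
readMetadataTable <- function(path) {
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' @rdname readMetadataTable
#' @param meta data.frame with columns id, age, sex, groups.
#' @export
writeMetadataTable <- function(meta, path) {
  write.table(meta, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Record-selection filter for overnight PSG
#'
#' A recording enters an analysis set only if it is a plausible full
#' overnight study (at least 5 h by default) and every EEG channel is
#' sampled at 200 Hz or more, the AASM-recommended rate for arousal
#' scoring. Both cutoffs are configurable.
#'
#' @param rec a [PSGRecording-class].
#' @param minDuration minimum record duration in seconds (default 18000,
#'   i.e. 5 h).
#' @param minEEGRate minimum EEG sampling rate in samples/s (default 200).
#' @return `TRUE` if the recording passes both filters.
#' @examples
#' r <- PSGRecording("a", list(C3 = numeric(6 * 3600 * 256)),
#'                   c(C3 = 256), roles = list(EEG = "C3"))
#' eligibleRecord(r)  # TRUE
#' @export
eligibleRecord <- function(rec, minDuration = 18000, minEEGRate = 200) {
  stopifnot(is(rec, "PSGRecording"))
  if (recordingDuration(rec) < minDuration) return(FALSE)
  eeg <- roleChannels(rec, "EEG")
  if (length(eeg) && any(rec@sampleRate[eeg] < minEEGRate)) return(FALSE)
  TRUE
}
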