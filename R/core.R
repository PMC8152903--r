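#' Construct an EpochSet
#'
#' @param data numeric array, trials x channels x time samples (microvolts).
#' @param fs sampling rate, Hz.
#' @param tStart epoch start relative to stimulus onset, ms.
#' @param channelNames channel identifiers; defaults to \code{Ch1..ChN}.
#' @param participantId opaque participant identifier.
#' @param labels data.frame of per-trial labels (see [EpochSet-class]);
#'   columns \code{is_post_test} and \code{is_first} default to
#'   \code{FALSE} / first-trial-only if missing.
#' @return An [EpochSet-class] object.
#' @export
EpochSet <- function(data, fs, tStart, channelNames = NULL,
                     participantId = "p01", labels) {
  d <- dim(data)
  if (is.null(channelNames)) channelNames <- sprintf("Ch%d", seq_len(d[2]))
  if (is.null(labels$trial_index)) labels$trial_index <- seq_len(nrow(labels))
  if (is.null(labels$is_post_test)) labels$is_post_test <- FALSE
  if (is.null(labels$is_first)) labels$is_first <- labels$trial_index == min(labels$trial_index)
  labels <- labels[, c("trial_index", "identity", "expression",
                       "is_post_test", "is_first")]
  new("EpochSet", data = data, fs = fs, tStart = tStart,
      channelNames = as.character(channelNames),
      participantId = participantId, labels = labels)
}

#' @describeIn EpochSet voltage tensor (trials x channels x times)
#' @param x an EpochSet
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @describeIn EpochSet sampling rate in Hz
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @describeIn EpochSet ms time axis: \code{tStart + (0:(T-1)) * 1000/fs}
#' @export
setMethod("epochTimes", "EpochSet", function(x)
  x@tStart + (seq_len(dim(x@data)[3]) - 1) * 1000 / x@fs)

#' @describeIn EpochSet per-trial label table
#' @export
setMethod("trialLabels", "EpochSet", function(x) x@labels)

#' @describeIn EpochSet participant identifier
#' @export
setMethod("participantId", "EpochSet", function(x) x@participantId)

#' @describeIn EpochSet number of trials
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1])

#' @describeIn EpochSet number of channels
#' @export
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2])

#' @describeIn EpochSet number of time samples
#' @export
setMethod("nTimes", "EpochSet", function(x) dim(x@data)[3])

#' @describeIn EpochSet channel identifiers
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channelNames)

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  tm <- epochTimes(object)
  cat(sprintf("EpochSet '%s': %d trials x %d channels x %d samples\n",
              object@participantId, d[1], d[2], d[3]))
  cat(sprintf("  fs = %g Hz, epoch [%g, %g] ms\n", object@fs, tm[1], tm[length(tm)]))
  cat(sprintf("  excluded flags: %d post-test, %d first\n",
              sum(object@labels$is_post_test), sum(object@labels$is_first)))
})

#' Save an EpochSet to disk
#'
#' Writes one raw little-endian float32 payload (\code{<stem>.dat}; trials x
#' channels x times in C order, i.e. time fastest) and a JSON sidecar
#' (\code{<stem>.json}) carrying sampling metadata and the label table.
#' Round-trips bit-exactly through [loadEpochs()] at float32 precision; use
#' float64 payloads (\code{bytes = 8}) for exact doubles.
#'
#' @param epochs an [EpochSet-class].
#' @param stem path stem; \code{.dat} and \code{.json} are appended.
#' @param bytes payload precision, 4 (float32) or 8 (float64).
#' @return \code{stem}, invisibly.
#' @export
saveEpochs <- function(epochs, stem, bytes = 4L) {
  stopifnot(is(epochs, "EpochSet"), bytes %in% c(4L, 8L))
  d <- dim(epochs@data)
  # C order trials x channels x times == column-major times x channels x trials
  payload <- aperm(epochs@data, c(3, 2, 1))
  con <- file(paste0(stem, ".dat"), "wb")
  writeBin(as.numeric(payload), con, size = bytes, endian = "little")
  close(con)
  meta <- list(
    n_trials = d[1], n_channels = d[2], n_times = d[3],
    fs = epochs@fs, t_start_ms = epochs@tStart,
    bytes = bytes,
    channel_names = epochs@channelNames,
    participant_id = epochs@participantId,
    labels = epochs@labels
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(stem)
}

#' Load an EpochSet from disk
#'
#' Counterpart of [saveEpochs()]. Fails with a format error naming the
#' offending field when payload and sidecar disagree.
#'
#' @param stem path stem written by [saveEpochs()].
#' @return An [EpochSet-class].
#' @export
loadEpochs <- function(stem) {
  datPath <- paste0(stem, ".dat")
  jsonPath <- paste0(stem, ".json")
  if (!file.exists(datPath)) stop("epoch payload not found: ", datPath)
  if (!file.exists(jsonPath)) stop("epoch sidecar not found: ", jsonPath)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  need <- c("n_trials", "n_channels", "n_times", "fs", "t_start_ms",
            "channel_names", "participant_id", "labels")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("epoch sidecar missing field(s): ", paste(miss, collapse = ", "))
  bytes <- if (is.null(meta$bytes)) 4L else as.integer(meta$bytes)
  nVals <- meta$n_trials * meta$n_channels * meta$n_times
  fsize <- file.info(datPath)$size
  if (fsize != nVals * bytes)
    stop(sprintf(paste0("format error: payload has %d values but sidecar ",
                        "declares n_trials x n_channels x n_times = %d ",
                        "(check field n_channels et al.)"),
                 fsize %/% bytes, nVals))
  con <- file(datPath, "rb")
  raw <- readBin(con, "numeric", n = nVals, size = bytes, endian = "little")
  close(con)
  arr <- aperm(array(raw, dim = c(meta$n_times, meta$n_channels, meta$n_trials)),
               c(3, 2, 1))
  labels <- as.data.frame(meta$labels)
  EpochSet(arr, fs = meta$fs, tStart = meta$t_start_ms,
           channelNames = meta$channel_names,
           participantId = meta$participant_id, labels = labels)
}

#' Export the label table as TSV
#'
#' @param epochs an [EpochSet-class].
#' @param path output TSV path.
#' @export
exportLabels <- function(epochs, path) {
  utils::write.table(trialLabels(epochs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop flagged trials
#'
#' Removes trials flagged as following a memory test and/or the session's
#' first trial; the session design records 720 trials of which 80 follow
#' tests, so dropping post-test trials leaves the 640 analysis trials.
#'
#' @param epochs an [EpochSet-class].
#' @param dropPostTest drop trials with \code{is_post_test}.
#' @param dropFirst drop trials with \code{is_first}.
#' @return A new [EpochSet-class] without the flagged trials.
#' @export
excludeTrials <- function(epochs, dropPostTest = TRUE, dropFirst = FALSE) {
  lab <- trialLabels(epochs)
  keep <- rep(TRUE, nrow(lab))
  if (dropPostTest) keep <- keep & !lab$is_post_test
  if (dropFirst) keep <- keep & !lab$is_first
  if (!any(keep)) stop("all trials excluded")
  EpochSet(epochs@data[keep, , , drop = FALSE], fs = epochs@fs,
           tStart = epochs@tStart, channelNames = epochs@channelNames,
           participantId = epochs@participantId,
           labels = lab[keep, , drop = FALSE])
}

#' Collapse the label table onto one face dimension
#'
#' Organizing trials by identity collapses across expressions and vice
#' versa; with the balanced 640-trial design each of the 4 classes then has
#' 160 trials.
#'
#' @param labels a label data.frame (from [trialLabels()]).
#' @param target \code{"identity"} or \code{"expression"}.
#' @return Integer class labels 1..4, one per trial.
#' @export
collapseDimension <- function(labels, target = c("identity", "expression")) {
  target <- match.arg(target)
  as.integer(labels[[target]])
}

#' Relabel trials by the previous trial's face
#'
#' Trial i receives the target-dimension label of trial i-1 in session
#' order; the session's first trial is removed because its predecessor is
#' undefined. By the design constraint that consecutive faces never share
#' identity or expression, the new label always differs from the trial's own
#' label on the same dimension.
#'
#' @param labels a label data.frame ordered by \code{trial_index}.
#' @param target \code{"identity"} or \code{"expression"}.
#' @return list with \code{keep} (row indices into \code{labels} retained,
#'   i.e. all but the first trial) and \code{classLabels} (the previous
#'   trial's target label for each kept trial).
#' @export
relabelPreviousTrial <- function(labels, target = c("identity", "expression")) {
  target <- match.arg(target)
  if (nrow(labels) < 2L) stop("need at least 2 trials to define a previous trial")
  ord <- order(labels$trial_index)
  cur <- as.integer(labels[[target]])[ord]
  keep <- ord[-1L]
  list(keep = keep, classLabels = cur[-length(cur)])
}

#' Crop the epoch time axis
#'
#' Restricts the epochs to a half-open ms window (e.g. the post-onset
#' interval), typically after filtering so that edge effects fall outside
#' the analyzed range.
#'
#' @param epochs an [EpochSet-class].
#' @param window ms interval \code{c(from, to)}; samples with
#'   \code{from <= t < to} are kept.
#' @return An [EpochSet-class] with the reduced time axis.
#' @export
cropEpochs <- function(epochs, window) {
  tm <- epochTimes(epochs)
  sel <- tm >= window[1] & tm < window[2]
  if (!any(sel)) stop("crop window contains no samples")
  res <- epochs
  res@data <- epochs@data[, , sel, drop = FALSE]
  res@tStart <- tm[which(sel)[1]]
  res
}
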