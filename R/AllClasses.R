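#' @useDynLib erpdecode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Epoched multichannel EEG container
#'
#' Holds a participant-level voltage tensor (trials x channels x time
#' samples, microvolts) together with sampling metadata and per-trial
#' labels on the two face dimensions. The time axis is half-open in
#' samples: sample \code{i} (0-based) sits at \code{tStart + i * 1000 / fs}
#' ms, so an epoch spanning \code{[-500, 1500)} ms at 250 Hz has exactly
#' 500 samples (the last at +1496 ms).
#'
#' @slot data three-dimensional numeric array, trials x channels x times.
#' @slot fs sampling rate in Hz.
#' @slot tStart epoch start relative to stimulus onset, ms.
#' @slot channelNames ordered channel identifiers.
#' @slot participantId opaque participant identifier.
#' @slot labels data.frame with columns \code{trial_index}, \code{identity},
#'   \code{expression}, \code{is_post_test}, \code{is_first}, aligned to the
#'   trial axis.
#'
#' @seealso [EpochSet()] for construction, [loadEpochs()], [saveEpochs()]
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    fs = "numeric",
    tStart = "numeric",
    channelNames = "character",
    participantId = "character",
    labels = "data.frame"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (trials x channels x times)")
  else {
    if (d[2] < 1L) msg <- c(msg, "channel count must be positive")
    if (d[2] != length(object@channelNames))
      msg <- c(msg, sprintf("channelNames length (%d) != channel dimension (%d)",
                            length(object@channelNames), d[2]))
    if (nrow(object@labels) != d[1])
      msg <- c(msg, sprintf("labels rows (%d) != trial dimension (%d)",
                            nrow(object@labels), d[1]))
  }
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  need <- c("trial_index", "identity", "expression", "is_post_test", "is_first")
  miss <- setdiff(need, names(object@labels))
  if (length(miss))
    msg <- c(msg, paste("labels missing columns:", paste(miss, collapse = ", ")))
  else if (nrow(object@labels)) {
    if (!all(object@labels$identity %in% 1:4))
      msg <- c(msg, "identity labels must be in {1,2,3,4}")
    if (!all(object@labels$expression %in% 1:4))
      msg <- c(msg, "expression labels must be in {1,2,3,4}")
  }
  if (length(msg)) msg else TRUE
})

#' Decoding configuration
#'
#' Bundles the tunable parameters of the decoding pipeline. Defaults mirror
#' the study design: 4 classes (chance 1/4), 3-fold averaged cross-validation,
#' 10 random subsampling iterations, a 6-Hz low-pass before decoding, 5-point
#' moving-average smoothing of the accuracy series (±8 ms at 250 Hz), a
#' 100-ms window for temporal generalization, and a linear soft-margin SVM
#' with cost 1 on per-fold standardized features.
#'
#' @slot nClasses number of classes per dimension.
#' @slot nFolds cross-validation folds (>= 2).
#' @slot nIterations random subsampling iterations (>= 1).
#' @slot lowpassHz low-pass cutoff in Hz applied before decoding
#'   (\code{NA_real_} disables the filter).
#' @slot smoothPoints odd width of the accuracy moving average.
#' @slot windowMs window width in ms for time-averaged (cross-time) decoding.
#' @slot cost SVM regularization constant.
#' @slot baselineWindow ms interval for baseline correction
#'   (\code{c(NA, NA)} disables it).
#' @export
setClass("DecodeConfig",
  representation(
    nClasses = "integer",
    nFolds = "integer",
    nIterations = "integer",
    lowpassHz = "numeric",
    smoothPoints = "integer",
    windowMs = "numeric",
    cost = "numeric",
    baselineWindow = "numeric"
  ),
  prototype(
    nClasses = 4L, nFolds = 3L, nIterations = 10L, lowpassHz = 6,
    smoothPoints = 5L, windowMs = 100, cost = 1,
    baselineWindow = c(-500, 0)
  )
)

setValidity("DecodeConfig", function(object) {
  msg <- character(0)
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (object@smoothPoints < 1L || object@smoothPoints %% 2L == 0L)
    msg <- c(msg, "smoothPoints must be odd and >= 1")
  if (!is.na(object@lowpassHz) && object@lowpassHz <= 0)
    msg <- c(msg, "lowpassHz must be positive or NA")
  if (object@cost <= 0) msg <- c(msg, "cost must be positive")
  if (length(msg)) msg else TRUE
})

#' Synthetic study configuration
#'
#' Generative parameters for the synthetic EEG epoch generator. Defaults
#' emulate the study conditions: 22 participants, 640 analysis trials
#' balanced over the 16 identity x expression cells, 59 channels, 250 Hz,
#' epochs covering \code{[-500, 1500)} ms. Signal structure: per-class
#' unit-norm scalp topographies that change across pattern segments
#' (dynamic coding), an identity envelope that rises fast and decays to
#' zero, an expression envelope that rises more slowly and settles on a
#' sustained plateau, and an optional reactivation bump that re-injects the
#' previous trial's identity topography after stimulus onset. Noise is
#' AR(1) in time (independent across channels) plus a per-trial alpha-band
#' sinusoid with random frequency and phase.
#'
#' @slot nParticipants simulated sample size.
#' @slot nTrials analysis trials per participant (divisible by 16).
#' @slot nExtraPostTest extra trials flagged \code{is_post_test}, emulating
#'   the session bookkeeping in which trials following memory tests are
#'   recorded but excluded (80 on top of 640 reproduces the 720-trial
#'   session).
#' @slot nChannels electrode count.
#' @slot fs sampling rate, Hz.
#' @slot epochMs half-open epoch interval in ms.
#' @slot identityGain,expressionGain,reactivationGain peak signal amplitudes
#'   in microvolts (0 disables a component).
#' @slot idOnset,idPeak,idDecay identity envelope: onset ms, peak ms, and
#'   duration of the half-cosine decay back to \code{idPlateau}.
#' @slot idPlateau sustained identity level in [0,1] after the decay.
#' @slot exOnset,exPeak,exDecay,exPlateau same for the expression envelope.
#' @slot reactOnset,reactWidth raised-cosine reactivation bump: start ms
#'   (>= 0) and width ms.
#' @slot nSegments number of piecewise topography segments.
#' @slot segmentBoundaries post-onset ms at which each segment begins.
#' @slot noiseSd innovation standard deviation of the AR(1) noise, microvolts.
#' @slot arPhi AR(1) coefficient in [0, 1).
#' @slot alphaAmp amplitude of the per-trial alpha sinusoid, microvolts.
#' @slot behavMean,behavSd across-participant mean and sd of the true
#'   behavioral accuracy used to simulate the memory-test reports.
#' @export
setClass("SynthConfig",
  representation(
    nParticipants = "integer",
    nTrials = "integer",
    nExtraPostTest = "integer",
    nChannels = "integer",
    fs = "numeric",
    epochMs = "numeric",
    identityGain = "numeric",
    expressionGain = "numeric",
    reactivationGain = "numeric",
    idOnset = "numeric", idPeak = "numeric", idDecay = "numeric",
    idPlateau = "numeric",
    exOnset = "numeric", exPeak = "numeric", exDecay = "numeric",
    exPlateau = "numeric",
    reactOnset = "numeric", reactWidth = "numeric",
    nSegments = "integer",
    segmentBoundaries = "numeric",
    noiseSd = "numeric",
    arPhi = "numeric",
    alphaAmp = "numeric",
    behavMean = "numeric",
    behavSd = "numeric"
  ),
  prototype(
    nParticipants = 22L, nTrials = 640L, nExtraPostTest = 0L,
    nChannels = 59L, fs = 250, epochMs = c(-500, 1500),
    identityGain = 12, expressionGain = 4, reactivationGain = 0,
    idOnset = 60, idPeak = 160, idDecay = 560, idPlateau = 0,
    exOnset = 100, exPeak = 450, exDecay = 300, exPlateau = 0.5,
    reactOnset = 80, reactWidth = 400,
    nSegments = 3L, segmentBoundaries = c(0, 200, 500),
    noiseSd = 10, arPhi = 0.3, alphaAmp = 10,
    behavMean = 0.7, behavSd = 0.08
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character(0)
  if (object@nTrials %% 16L != 0L)
    msg <- c(msg, "nTrials must be divisible by 16 (balanced identity x expression cells)")
  gains <- c(object@identityGain, object@expressionGain, object@reactivationGain)
  if (any(gains < 0)) msg <- c(msg, "gains must be >= 0")
  if (object@arPhi < 0 || object@arPhi >= 1)
    msg <- c(msg, "arPhi must be in [0, 1)")
  if (object@nSegments < 1L) msg <- c(msg, "nSegments must be >= 1")
  if (length(object@segmentBoundaries) != object@nSegments)
    msg <- c(msg, "segmentBoundaries must have one entry per segment")
  if (object@nChannels < 2L) msg <- c(msg, "nChannels must be >= 2")
  if (length(object@epochMs) != 2L || diff(object@epochMs) <= 0)
    msg <- c(msg, "epochMs must be an increasing interval")
  if (object@reactOnset < 0) msg <- c(msg, "reactOnset must be >= 0")
  if (object@noiseSd < 0 || object@alphaAmp < 0)
    msg <- c(msg, "noise amplitudes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-class scalp topographies
#'
#' Unit-norm spatial vectors over channels for every class and pattern
#' segment, one array per face dimension (channels x classes x segments).
#'
#' @slot identity,expression numeric arrays, channels x classes x segments.
#' @export
setClass("TopographySet",
  representation(identity = "array", expression = "array")
)

setValidity("TopographySet", function(object) {
  for (nm in c("identity", "expression")) {
    a <- slot(object, nm)
    if (length(dim(a)) != 3L) return(sprintf("%s must be channels x classes x segments", nm))
    nrm <- sqrt(apply(a^2, c(2, 3), sum))
    if (any(abs(nrm - 1) > 1e-9)) return(sprintf("%s vectors must be unit norm", nm))
  }
  TRUE
})

#' Decoding accuracy time series
#'
#' @slot values accuracy per time point, proportion in [0, 1].
#' @slot times ms axis.
#' @slot nAttempts decoding attempts averaged per time point.
#' @export
setClass("AccuracySeries",
  representation(values = "numeric", times = "numeric", nAttempts = "integer")
)

setValidity("AccuracySeries", function(object) {
  if (length(object@values) != length(object@times))
    return("values and times must have equal length")
  if (any(object@values < -1e-12 | object@values > 1 + 1e-12))
    return("accuracy values must lie in [0, 1]")
  TRUE
})

#' Stored per-attempt predictions
#'
#' Retains, for every decoding attempt (iteration x fold x test row) and
#' every time point, the predicted class, together with the attempt's true
#' class. Accuracy and confusion matrices are recomputed from the store, and
#' permutation nulls relabel the store without retraining.
#'
#' @slot predicted integer matrix, attempts x time points.
#' @slot trueClass integer true class per attempt (constant across time).
#' @slot times ms axis.
#' @slot iteration,fold attempt bookkeeping vectors.
#' @export
setClass("PredictionStore",
  representation(
    predicted = "matrix", trueClass = "integer", times = "numeric",
    iteration = "integer", fold = "integer"
  )
)

setValidity("PredictionStore", function(object) {
  n <- nrow(object@predicted)
  if (length(object@trueClass) != n) return("trueClass length != attempt rows")
  if (ncol(object@predicted) != length(object@times))
    return("predicted columns != times length")
  if (length(object@iteration) != n || length(object@fold) != n)
    return("attempt bookkeeping must match attempt rows")
  TRUE
})

#' Balanced fold assignment
#'
#' @slot groups per class, a list of k equally sized index vectors.
#' @slot dropped per class, trial indices discarded to equalize group sizes.
#' @slot seed the seed the assignment was drawn with.
#' @export
setClass("FoldAssignment",
  representation(groups = "list", dropped = "list", seed = "integer")
)

setValidity("FoldAssignment", function(object) {
  for (cl in seq_along(object@groups)) {
    g <- object@groups[[cl]]
    sizes <- lengths(g)
    if (length(unique(sizes)) != 1L)
      return(sprintf("class %d groups are not equally sized", cl))
    all_idx <- c(unlist(g), object@dropped[[cl]])
    if (anyDuplicated(all_idx)) return(sprintf("class %d has overlapping groups", cl))
  }
  TRUE
})

#' Temporal generalization matrix
#'
#' @slot accuracy square matrix, train windows x test windows, entries in [0,1].
#' @slot windowTimes start of each window, ms.
#' @export
setClass("GenMatrix",
  representation(accuracy = "matrix", windowTimes = "numeric")
)

setValidity("GenMatrix", function(object) {
  a <- object@accuracy
  if (nrow(a) != ncol(a)) return("accuracy must be square")
  if (nrow(a) != length(object@windowTimes))
    return("windowTimes must match matrix side")
  if (any(a < -1e-12 | a > 1 + 1e-12)) return("entries must lie in [0, 1]")
  TRUE
})

#' Significant time-point clusters
#'
#' Maximal runs of contiguously significant time points with their summed
#' t mass and (after [clusterPvalues()]) permutation p-values.
#'
#' @slot clusters data.frame with columns \code{start}, \code{end} (time-point
#'   indices into the analyzed axis), \code{startTime}, \code{endTime} (ms),
#'   \code{mass}, and optionally \code{p} and \code{significant}.
#' @slot tail \code{"one"} or \code{"two"}.
#' @slot pointAlpha per-point threshold.
#' @slot clusterAlpha family threshold.
#' @slot df degrees of freedom of the point-wise t tests.
#' @export
setClass("ClusterSet",
  representation(
    clusters = "data.frame", tail = "character",
    pointAlpha = "numeric", clusterAlpha = "numeric", df = "numeric"
  ),
  prototype(tail = "one", pointAlpha = 0.05, clusterAlpha = 0.05)
)

setValidity("ClusterSet", function(object) {
  cl <- object@clusters
  if (!all(c("start", "end", "mass") %in% names(cl)))
    return("clusters needs start, end, mass columns")
  if (nrow(cl) > 1L) {
    if (is.unsorted(cl$start)) return("clusters must be ordered by start")
    if (any(cl$start[-1] <= cl$end[-nrow(cl)])) return("clusters must not overlap")
  }
  if (!object@tail %in% c("one", "two")) return("tail must be 'one' or 'two'")
  TRUE
})
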