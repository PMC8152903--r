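# Shared fixtures and small independent helpers for the test suite.

# A small EpochSet with hand-built labels; data optionally supplied.
makeTinyEpochs <- function(nTrials = 16, nChannels = 4, nTimes = 20,
                           fs = 250, tStart = -40, data = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(data)) data <- array(rnorm(nTrials * nChannels * nTimes),
                                   c(nTrials, nChannels, nTimes))
  labels <- data.frame(
    trial_index = seq_len(nTrials),
    identity = rep(rep(1:4, each = 4), length.out = nTrials),
    expression = rep(1:4, length.out = nTrials),
    is_post_test = FALSE,
    is_first = seq_len(nTrials) == 1
  )
  EpochSet(data, fs = fs, tStart = tStart, labels = labels)
}

# smoothed participants x time accuracy matrix from a list of stores
accMatrix <- function(stores, smoothPoints = 5L) {
  t(vapply(stores, function(st)
    erpdecode:::runningMean(colMeans(st@predicted == st@trueClass),
                            as.integer(smoothPoints)),
    numeric(ncol(stores[[1]]@predicted))))
}

# Simulate, preprocess and decode a whole group for one label dimension;
# returns the list of prediction stores.
decodeGroup <- function(synthCfg, decodeCfg, masterSeed, dimension = "identity",
                        previous = FALSE, crop = NULL) {
  n <- synthCfg@nParticipants
  seeds <- erpdecode:::deriveSeeds(masterSeed, 3L * n)
  lapply(seq_len(n), function(i) {
    topo <- makeTopographies(synthCfg, seeds[3 * i - 2])
    ep <- simulateParticipant(synthCfg, topo, seeds[3 * i - 1])
    if (!is.na(decodeCfg@lowpassHz))
      ep <- lowpassFilter(ep, decodeCfg@lowpassHz)
    bw <- decodeCfg@baselineWindow
    if (!anyNA(bw) && any(epochTimes(ep) >= bw[1] & epochTimes(ep) < bw[2]))
      ep <- baselineCorrect(ep, bw)
    if (!is.null(crop)) ep <- cropEpochs(ep, crop)
    lab <- trialLabels(ep)
    if (previous) {
      rel <- relabelPreviousTrial(lab, dimension)
      ep <- EpochSet(epochData(ep)[rel$keep, , , drop = FALSE], fs = ep@fs,
                     tStart = ep@tStart, channelNames = channelNames(ep),
                     participantId = participantId(ep),
                     labels = lab[rel$keep, , drop = FALSE])
      cls <- rel$classLabels
    } else cls <- collapseDimension(lab, dimension)
    decodeTimecourse(ep, cls, decodeCfg, seeds[3 * i])$store
  })
}

# Zero-signal generator configuration used by the null-calibration suites:
# short post-onset epochs, AR(1) noise only (the 6-Hz kernel does not fit a
# 100-sample epoch, and the autocorrelation under test is the AR structure).
nullStudyConfig <- function(nParticipants = 8, nTrials = 160, nChannels = 16,
                            arPhi = 0.5) {
  SynthConfig(nParticipants = nParticipants, nTrials = nTrials,
              nChannels = nChannels, epochMs = c(0, 400),
              identityGain = 0, expressionGain = 0, reactivationGain = 0,
              noiseSd = 1, arPhi = arPhi, alphaAmp = 0,
              nSegments = 1, segmentBoundaries = 0)
}

nullStudyDecodeConfig <- function(nIterations = 2)
  DecodeConfig(nIterations = nIterations, lowpassHz = NA,
               baselineWindow = c(NA, NA))
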