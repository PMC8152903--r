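#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @export
setGeneric("nTimes", function(x) standardGeneric("nTimes"))
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @export
setGeneric("accuracy", function(x, ...) standardGeneric("accuracy"))
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))
#' @export
setGeneric("nAttempts", function(x) standardGeneric("nAttempts"))
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @export
setGeneric("chanceLevel", function(x) standardGeneric("chanceLevel"))
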