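#' EEGRecording: a continuous multichannel EEG recording
#'
#' Holds a channels-by-samples potential matrix (microvolts) together with the
#' sampling rate, channel names, unit-sphere electrode positions and a
#' provenance log of the processing steps applied so far.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames character vector of unique channel names.
#' @slot channelPositions channels x 3 matrix of unit-norm electrode
#'   coordinates (x right, y anterior, z up).
#' @slot provenance list of processing-step records, in application order.
#' @exportClass EEGRecording
setClass("EEGRecording", representation(
  data = "matrix",
  samplingRate = "numeric",
  channelNames = "character",
  channelPositions = "matrix",
  provenance = "list"
))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!all(is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "rows of data must match channelNames")
  if (nrow(object@channelPositions) != nrow(object@data) ||
      ncol(object@channelPositions) != 3L)
    msg <- c(msg, "channelPositions must be channels x 3")
  else {
    nrm <- sqrt(rowSums(object@channelPositions^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "channel positions must be unit norm (within 1e-6)")
  }
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' EpochedData: fixed-length epochs cut from a cleaned recording
#'
#' @slot epochs list of channels x samples matrices, all the same shape.
#' @slot epochLength epoch length in seconds.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames channel names shared by all epochs.
#' @slot rejectedWindows two-column matrix (start, end in seconds) of spans
#'   removed by artifact rejection before epoching.
#' @exportClass EpochedData
setClass("EpochedData", representation(
  epochs = "list",
  epochLength = "numeric",
  samplingRate = "numeric",
  channelNames = "character",
  rejectedWindows = "matrix"
))

setValidity("EpochedData", function(object) {
  msg <- character()
  ns <- round(object@epochLength * object@samplingRate)
  if (abs(object@epochLength * object@samplingRate - ns) > 1e-9)
    msg <- c(msg, "epochLength x samplingRate must be integral")
  for (e in object@epochs) {
    if (!is.matrix(e) || nrow(e) != length(object@channelNames) ||
        ncol(e) != ns) {
      msg <- c(msg, "all epochs must be channels x (epochLength*samplingRate)")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' GfpSeries: global field power with detected peaks
#'
#' GFP(t) is the spatial standard deviation of the scalp map at sample t;
#' its local maxima are the moments of highest topographic signal-to-noise.
#'
#' @slot values list (one numeric vector per epoch) of GFP values, all >= 0.
#' @slot peaks list (one integer vector per epoch) of peak sample indices.
#' @slot samplingRate sampling rate in Hz.
#' @exportClass GfpSeries
setClass("GfpSeries", representation(
  values = "list", peaks = "list", samplingRate = "numeric"
))

setValidity("GfpSeries", function(object) {
  msg <- character()
  if (length(object@values) != length(object@peaks))
    msg <- c(msg, "values and peaks must have one entry per epoch")
  if (any(vapply(object@values, function(v) any(v < 0), logical(1))))
    msg <- c(msg, "GFP values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TemplateSet: K microstate template maps with labels and fit diagnostics
#'
#' @slot maps channels x K matrix of unit-norm, average-referenced templates.
#' @slot channelNames channel names (rows of maps).
#' @slot labels class labels, e.g. "A".."D", or "unassigned".
#' @slot gevTotal total global explained variance in [0,1] (NA if not fit).
#' @slot gevPerClass per-class GEV decomposition (sums to gevTotal).
#' @slot source identifier of the subject or group the set was derived from.
#' @exportClass TemplateSet
setClass("TemplateSet", representation(
  maps = "matrix",
  channelNames = "character",
  labels = "character",
  gevTotal = "numeric",
  gevPerClass = "numeric",
  source = "character"
))

setValidity("TemplateSet", function(object) {
  msg <- character()
  K <- ncol(object@maps)
  if (nrow(object@maps) != length(object@channelNames))
    msg <- c(msg, "rows of maps must match channelNames")
  if (length(object@labels) != K) msg <- c(msg, "one label per template")
  nrm <- sqrt(colSums(object@maps^2))
  if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "templates must be unit norm")
  if (!is.na(object@gevTotal)) {
    if (object@gevTotal < -1e-9 || object@gevTotal > 1 + 1e-9)
      msg <- c(msg, "gevTotal must lie in [0,1]")
    if (length(object@gevPerClass) == K &&
        abs(sum(object@gevPerClass) - object@gevTotal) > 1e-9)
      msg <- c(msg, "per-class GEV must sum to gevTotal")
  }
  if (length(msg)) msg else TRUE
})

#' MicrostateSegmentation: per-sample class labels for one subject
#'
#' @slot labels list (per epoch) of integer class labels in 1..K.
#' @slot corr list (per epoch) of |spatial correlation| with winning template.
#' @slot gfp list (per epoch) of GFP values.
#' @slot samplingRate sampling rate in Hz.
#' @slot K number of classes.
#' @slot classNames class names, length K.
#' @exportClass MicrostateSegmentation
setClass("MicrostateSegmentation", representation(
  labels = "list", corr = "list", gfp = "list",
  samplingRate = "numeric", K = "integer", classNames = "character"
))

setValidity("MicrostateSegmentation", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@corr) ||
      length(object@labels) != length(object@gfp))
    msg <- c(msg, "labels, corr and gfp must align per epoch")
  for (i in seq_along(object@labels)) {
    l <- object@labels[[i]]
    if (any(l < 1L | l > object@K)) { msg <- c(msg, "labels out of range"); break }
    if (length(l) != length(object@corr[[i]]) ||
        length(l) != length(object@gfp[[i]])) {
      msg <- c(msg, "per-epoch field lengths inconsistent"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' MicrostateParameters: temporal parameters for one subject
#'
#' Per class: mean duration (ms) of interior runs (NA when the class has no
#' interior run), occurrence rate (onsets per second), coverage (percent of
#' samples), and GEV.
#'
#' @slot durationMs named numeric, per-class mean duration in ms (NA allowed).
#' @slot occurrencePerS named numeric, per-class onsets per second.
#' @slot coveragePct named numeric, per-class time share in percent.
#' @slot gevPerClass named numeric, per-class GEV.
#' @slot gevTotal total GEV.
#' @exportClass MicrostateParameters
setClass("MicrostateParameters", representation(
  durationMs = "numeric", occurrencePerS = "numeric",
  coveragePct = "numeric", gevPerClass = "numeric", gevTotal = "numeric"
))

setValidity("MicrostateParameters", function(object) {
  msg <- character()
  if (abs(sum(object@coveragePct) - 100) > 1e-6)
    msg <- c(msg, "coverage must sum to 100")
  if (any(object@occurrencePerS < 0) || any(object@coveragePct < -1e-12))
    msg <- c(msg, "parameters must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TransitionTable: observed and expected microstate transition percentages
#'
#' Off-diagonal K x K percentages; both the observed and the expected matrix
#' sum to 100 over ordered pairs i != j. The expected matrix is the
#' independence null computed from segment-count fractions.
#'
#' @slot observedPct K x K matrix, zero diagonal.
#' @slot expectedPct K x K matrix, zero diagonal (NA matrix if not computed).
#' @slot segmentCounts named per-class segment counts.
#' @slot classNames class names.
#' @exportClass TransitionTable
setClass("TransitionTable", representation(
  observedPct = "matrix", expectedPct = "matrix",
  segmentCounts = "numeric", classNames = "character"
))

setValidity("TransitionTable", function(object) {
  msg <- character()
  chk <- function(m, nm) {
    if (all(is.na(m))) return(character())
    out <- character()
    if (any(abs(diag(m)) > 1e-12)) out <- c(out, paste(nm, "diagonal must be 0"))
    if (abs(sum(m) - 100) > 1e-6) out <- c(out, paste(nm, "must sum to 100"))
    out
  }
  msg <- c(msg, chk(object@observedPct, "observedPct"),
           chk(object@expectedPct, "expectedPct"))
  if (length(msg)) msg else TRUE
})

#' GeneratorConfig: parameters of the synthetic-EEG generator
#'
#' @slot nChannels number of channels.
#' @slot nStates number of embedded microstate classes (default 4).
#' @slot samplingRate sampling rate in Hz.
#' @slot duration recording length in seconds.
#' @slot meanSegmentMs mean microstate segment duration in ms (scalar or one
#'   value per state).
#' @slot transitionMatrix nStates x nStates row-stochastic matrix with zero
#'   diagonal governing successor states.
#' @slot envelopeFreq frequency (Hz) of the rectified-sinusoid GFP envelope.
#' @slot polarityFlipProb probability that a segment inverts polarity.
#' @slot noiseSigma sensor noise SD as a fraction of the (unit) map norm.
#' @slot seed integer seed.
#' @exportClass GeneratorConfig
setClass("GeneratorConfig", representation(
  nChannels = "integer", nStates = "integer", samplingRate = "numeric",
  duration = "numeric", meanSegmentMs = "numeric",
  transitionMatrix = "matrix", envelopeFreq = "numeric",
  polarityFlipProb = "numeric", noiseSigma = "numeric", seed = "integer"
))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  K <- object@nStates
  tm <- object@transitionMatrix
  if (nrow(tm) != K || ncol(tm) != K)
    msg <- c(msg, "transitionMatrix must be nStates x nStates")
  else {
    if (any(abs(diag(tm)) > 0)) msg <- c(msg, "transitionMatrix diagonal must be exactly 0")
    if (any(abs(rowSums(tm) - 1) > 1e-12))
      msg <- c(msg, "transitionMatrix rows must sum to 1 (within 1e-12)")
    if (any(tm < 0)) msg <- c(msg, "transition probabilities must be >= 0")
  }
  if (any(object@meanSegmentMs <= 0)) msg <- c(msg, "durations must be > 0")
  if (!length(object@meanSegmentMs) %in% c(1L, K))
    msg <- c(msg, "meanSegmentMs must be scalar or per-state")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@polarityFlipProb < 0 || object@polarityFlipProb > 1)
    msg <- c(msg, "polarityFlipProb must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: the embedded microstate structure of a synthetic recording
#'
#' @slot templates channels x nStates matrix of generating maps.
#' @slot labelSequence per-sample state index (1-based).
#' @slot segmentTable data.frame with columns state, start, end (sample
#'   indices, inclusive) and polarity (+1/-1); segments tile the sequence.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  templates = "matrix", labelSequence = "integer", segmentTable = "data.frame"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  st <- object@segmentTable
  n <- length(object@labelSequence)
  if (nrow(st)) {
    if (st$start[1] != 1L || st$end[nrow(st)] != n ||
        (nrow(st) > 1 && any(st$start[-1] != st$end[-nrow(st)] + 1L)))
      msg <- c(msg, "segments must tile the label sequence")
  }
  if (length(msg)) msg else TRUE
})
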