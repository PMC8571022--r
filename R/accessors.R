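#' Accessors for microstates S4 objects
#'
#' Small, read-only accessors; user code should use these instead of slots.
#'
#' @param object an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setMethod("eegData", "EEGRecording", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochedData", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "MicrostateSegmentation",
          function(object) object@samplingRate)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(object) object@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "EpochedData", function(object) object@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "TemplateSet", function(object) object@channelNames)

#' @rdname accessors
#' @export
setGeneric("channelPositions",
           function(object) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setMethod("channelPositions", "EEGRecording",
          function(object) object@channelPositions)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "EEGRecording", function(object) object@provenance)

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setMethod("nChannels", "EEGRecording", function(object) nrow(object@data))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setMethod("nSamples", "EEGRecording", function(object) ncol(object@data))

#' @rdname accessors
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))
#' @rdname accessors
#' @export
setMethod("epochs", "EpochedData", function(object) object@epochs)

#' @rdname accessors
#' @export
setGeneric("templateMaps", function(object) standardGeneric("templateMaps"))
#' @rdname accessors
#' @export
setMethod("templateMaps", "TemplateSet", function(object) object@maps)

#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setMethod("classLabels", "TemplateSet", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("gevTotal", function(object) standardGeneric("gevTotal"))
#' @rdname accessors
#' @export
setMethod("gevTotal", "TemplateSet", function(object) object@gevTotal)
#' @rdname accessors
#' @export
setMethod("gevTotal", "MicrostateParameters", function(object) object@gevTotal)

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setMethod("stateLabels", "MicrostateSegmentation",
          function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("stateLabels", "GroundTruth",
          function(object) object@labelSequence)

#' @rdname accessors
#' @export
setGeneric("durationMs", function(object) standardGeneric("durationMs"))
#' @rdname accessors
#' @export
setMethod("durationMs", "MicrostateParameters",
          function(object) object@durationMs)

#' @rdname accessors
#' @export
setGeneric("occurrencePerS", function(object) standardGeneric("occurrencePerS"))
#' @rdname accessors
#' @export
setMethod("occurrencePerS", "MicrostateParameters",
          function(object) object@occurrencePerS)

#' @rdname accessors
#' @export
setGeneric("coveragePct", function(object) standardGeneric("coveragePct"))
#' @rdname accessors
#' @export
setMethod("coveragePct", "MicrostateParameters",
          function(object) object@coveragePct)

#' @rdname accessors
#' @export
setGeneric("observedPct", function(object) standardGeneric("observedPct"))
#' @rdname accessors
#' @export
setMethod("observedPct", "TransitionTable", function(object) object@observedPct)

#' @rdname accessors
#' @export
setGeneric("expectedPct", function(object) standardGeneric("expectedPct"))
#' @rdname accessors
#' @export
setMethod("expectedPct", "TransitionTable", function(object) object@expectedPct)

#' @rdname accessors
#' @export
setGeneric("segmentCounts", function(object) standardGeneric("segmentCounts"))
#' @rdname accessors
#' @export
setMethod("segmentCounts", "TransitionTable",
          function(object) object@segmentCounts)

#' @rdname accessors
#' @export
setGeneric("segmentTable", function(object) standardGeneric("segmentTable"))
#' @rdname accessors
#' @export
setMethod("segmentTable", "GroundTruth", function(object) object@segmentTable)

#' @rdname accessors
#' @export
setGeneric("gfpValues", function(object) standardGeneric("gfpValues"))
#' @rdname accessors
#' @export
setMethod("gfpValues", "GfpSeries", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("gfpValues", "MicrostateSegmentation", function(object) object@gfp)

#' @rdname accessors
#' @export
setGeneric("gfpPeaks", function(object) standardGeneric("gfpPeaks"))
#' @rdname accessors
#' @export
setMethod("gfpPeaks", "GfpSeries", function(object) object@peaks)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
  cat(sprintf("  channels: %s%s\n",
              paste(utils::head(object@channelNames, 6), collapse = ", "),
              if (length(object@channelNames) > 6) ", ..." else ""))
  cat(sprintf("  provenance: %d step(s)\n", length(object@provenance)))
})

setMethod("show", "EpochedData", function(object) {
  cat(sprintf("EpochedData: %d epoch(s) of %g s @ %g Hz, %d channels\n",
              length(object@epochs), object@epochLength, object@samplingRate,
              length(object@channelNames)))
  if (nrow(object@rejectedWindows))
    cat(sprintf("  %d rejected window(s) upstream\n",
                nrow(object@rejectedWindows)))
})

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet '%s': %d templates on %d channels\n",
              object@source, ncol(object@maps), nrow(object@maps)))
  cat(sprintf("  labels: %s\n", paste(object@labels, collapse = " ")))
  if (!is.na(object@gevTotal))
    cat(sprintf("  GEV: %.3f\n", object@gevTotal))
})

setMethod("show", "MicrostateSegmentation", function(object) {
  n <- sum(vapply(object@labels, length, integer(1)))
  cat(sprintf("MicrostateSegmentation: %d epochs, %d samples, K=%d @ %g Hz\n",
              length(object@labels), n, object@K, object@samplingRate))
})

setMethod("show", "MicrostateParameters", function(object) {
  m <- rbind(duration_ms = object@durationMs,
             occurrence_s = object@occurrencePerS,
             coverage_pct = object@coveragePct,
             gev = object@gevPerClass)
  cat("MicrostateParameters:\n")
  print(round(m, 3))
  cat(sprintf("  total GEV: %.3f\n", object@gevTotal))
})

setMethod("show", "TransitionTable", function(object) {
  cat("TransitionTable (observed %):\n")
  print(round(object@observedPct, 2))
  if (!all(is.na(object@expectedPct))) {
    cat("expected % (independence null):\n")
    print(round(object@expectedPct, 2))
  }
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(paste0("GeneratorConfig: %d ch, %d states, %g Hz, %g s, ",
                     "mean segment %s ms, noise %.3g, seed %d\n"),
              object@nChannels, object@nStates, object@samplingRate,
              object@duration,
              paste(object@meanSegmentMs, collapse = "/"),
              object@noiseSigma, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d samples, %d segments, %d states\n",
              length(object@labelSequence), nrow(object@segmentTable),
              ncol(object@templates)))
})
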