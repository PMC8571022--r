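#' Build a synthetic-EEG generator configuration
#'
#' The generator emulates the data regime of a 64-channel, 5-minute,
#' 1000 Hz resting-state recording: a Markov chain over \code{nStates}
#' quasi-stable topographies with geometric segment lengths, a rectified
#' sinusoid amplitude envelope (GFP waxing/waning), per-segment polarity
#' inversions, and spatially white Gaussian sensor noise.
#'
#' @param nChannels number of channels.
#' @param nStates number of microstate classes (default 4).
#' @param samplingRate sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param meanSegmentMs mean segment duration in ms, scalar or one value per
#'   state (default 80 ms, the middle of the canonical 60-120 ms range).
#' @param transitionMatrix row-stochastic successor matrix with zero
#'   diagonal; default uniform over the other states.
#' @param envelopeFreq GFP envelope frequency in Hz (default 10, alpha-band).
#' @param polarityFlipProb probability that a new segment inverts polarity.
#' @param noiseSigma sensor-noise SD as a fraction of the (unit) map norm.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated \linkS4class{GeneratorConfig}.
#' @export
#' @examples
#' cfg <- generatorConfig(nChannels = 19, duration = 10, seed = 1)
#' cfg
generatorConfig <- function(nChannels = 64L, nStates = 4L,
                            samplingRate = 1000, duration = 300,
                            meanSegmentMs = 80,
                            transitionMatrix = NULL,
                            envelopeFreq = 10, polarityFlipProb = 0.5,
                            noiseSigma = 0.1, seed = 1L) {
  nStates <- as.integer(nStates)
  if (is.null(transitionMatrix)) {
    transitionMatrix <- matrix(1 / (nStates - 1), nStates, nStates)
    diag(transitionMatrix) <- 0
  }
  new("GeneratorConfig", nChannels = as.integer(nChannels),
      nStates = nStates, samplingRate = samplingRate, duration = duration,
      meanSegmentMs = as.numeric(meanSegmentMs),
      transitionMatrix = transitionMatrix, envelopeFreq = envelopeFreq,
      polarityFlipProb = polarityFlipProb, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

#' Generate well-separated smooth template maps
#'
#' Draws \code{nStates} average-referenced, unit-norm topographies as random
#' combinations of low-degree solid harmonics on the montage (spatially
#' smooth, like real scalp fields), resampling until every pair satisfies
#' |spatial correlation| <= 1 - \code{minSeparation}.
#'
#' @param nChannels number of channels.
#' @param nStates number of maps.
#' @param seed integer seed.
#' @param minSeparation required pairwise separation in [0, 1).
#' @param positions optional n x 3 electrode positions (defaults to
#'   \code{standardMontage(nChannels)}).
#' @param maxTries resampling attempts per map before failing.
#' @return channels x nStates matrix of maps (columns unit norm, zero mean).
#' @export
#' @examples
#' maps <- makeTemplateMaps(32, 4, seed = 1, minSeparation = 0.5)
#' round(crossprod(maps), 2)
makeTemplateMaps <- function(nChannels, nStates, seed = 1L,
                             minSeparation = 0.5, positions = NULL,
                             maxTries = 500L) {
  stopIfNot(nStates <= nChannels, "nStates must be <= nChannels")
  stopIfNot(minSeparation >= 0 && minSeparation < 1,
            "minSeparation must lie in [0, 1)")
  if (is.null(positions)) positions <- standardMontage(nChannels)$positions
  B <- harmonicBasis(positions)
  withSeed(seed, {
    maps <- matrix(0, nChannels, 0)
    tries <- 0L
    while (ncol(maps) < nStates) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("could not achieve requested map separation after ",
             maxTries, " attempts", call. = FALSE)
      v <- drop(B %*% rnorm(ncol(B)))
      v <- v - mean(v)
      if (sqrt(sum(v^2)) < 1e-8) next
      v <- unitNorm(v)
      if (ncol(maps)) {
        r <- abs(apply(maps, 2, function(u) stats::cor(u, v)))
        if (any(r > 1 - minSeparation)) next
      }
      maps <- cbind(maps, v)
      tries <- 0L
    }
    colnames(maps) <- paste0("S", seq_len(nStates))
    maps
  })
}

#' Sample a microstate label sequence
#'
#' Segment lengths are geometric at sample resolution with the configured
#' per-state mean; successors follow the transition matrix; polarity flips
#' between segments with the configured probability. The sequence is
#' truncated at \code{duration * samplingRate} samples.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return a \linkS4class{GroundTruth} (templates slot empty).
#' @export
sampleStateSequence <- function(config) {
  validObject(config)
  K <- config@nStates
  fs <- config@samplingRate
  n <- round(config@duration * fs)
  meanMs <- rep(config@meanSegmentMs, length.out = K)
  meanSamples <- meanMs / 1000 * fs
  stopIfNot(all(meanSamples >= 1), "mean segment shorter than one sample")
  p <- 1 / meanSamples
  withSeed(config@seed, {
    states <- integer(0); starts <- integer(0); ends <- integer(0)
    pols <- integer(0)
    cur <- sample.int(K, 1L)
    pol <- 1L
    total <- 0L
    while (total < n) {
      len <- rgeom(1L, p[cur]) + 1L
      states <- c(states, cur)
      starts <- c(starts, total + 1L)
      total <- min(total + len, n)
      ends <- c(ends, total)
      pols <- c(pols, pol)
      if (total < n) {
        cur <- if (K == 2L) (3L - cur) else
          sample.int(K, 1L, prob = config@transitionMatrix[cur, ])
        if (runif(1L) < config@polarityFlipProb) pol <- -pol
      }
    }
    seg <- data.frame(state = as.integer(states),
                      start = as.integer(starts),
                      end = as.integer(ends),
                      polarity = as.integer(pols))
    labels <- rep(states, ends - starts + 1L)
    new("GroundTruth", templates = matrix(0, 0, 0),
        labelSequence = as.integer(labels), segmentTable = seg)
  })
}

#' Synthesise a multichannel recording from templates and a label sequence
#'
#' Sample t equals polarity(segment) * envelope(t) * map[label(t)] plus
#' Gaussian sensor noise of SD \code{noiseSigma}. The envelope is
#' |sin(2 pi f t)| scaled to mean 1 (mean of |sin| is 2/pi), so GFP waxes
#' and wanes at twice the envelope frequency with true topography preserved
#' at every nonzero-envelope sample.
#'
#' @param templates channels x nStates matrix of generating maps.
#' @param groundTruth a \linkS4class{GroundTruth} from
#'   \code{\link{sampleStateSequence}}.
#' @param config the same \linkS4class{GeneratorConfig}.
#' @param positions optional electrode positions.
#' @return an \linkS4class{EEGRecording}.
#' @export
synthesizeRecording <- function(templates, groundTruth, config,
                                positions = NULL) {
  validObject(config)
  stopIfNot(nrow(templates) == config@nChannels,
            "templates do not match nChannels")
  stopIfNot(ncol(templates) >= max(groundTruth@labelSequence),
            "label sequence references missing template")
  mont <- standardMontage(config@nChannels)
  if (is.null(positions)) positions <- mont$positions
  fs <- config@samplingRate
  labels <- groundTruth@labelSequence
  n <- length(labels)
  tt <- (seq_len(n) - 1L) / fs
  env <- if (config@envelopeFreq > 0)
    abs(sin(2 * pi * config@envelopeFreq * tt)) * (pi / 2) else rep(1, n)
  seg <- groundTruth@segmentTable
  pol <- rep(seg$polarity, seg$end - seg$start + 1L)
  X <- templates[, labels, drop = FALSE] *
    matrix(env * pol, config@nChannels, n, byrow = TRUE)
  dimnames(X) <- NULL
  if (config@noiseSigma > 0) {
    X <- X + withSeed(deriveSeed(config@seed, 1000003L),
                      matrix(rnorm(config@nChannels * n, 0,
                                   config@noiseSigma), config@nChannels, n))
  }
  new("EEGRecording", data = X, samplingRate = fs,
      channelNames = mont$channelNames, channelPositions = positions,
      provenance = list(list(step = "synthesize",
                             nStates = config@nStates,
                             noiseSigma = config@noiseSigma,
                             seed = config@seed)))
}

#' Simulate a complete recording with ground truth
#'
#' Convenience wrapper: draws templates (unless given), samples the state
#' sequence and synthesises the recording.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param templates optional channels x nStates template matrix.
#' @param minSeparation pairwise map separation when drawing templates.
#' @return list with \code{recording} (\linkS4class{EEGRecording}) and
#'   \code{groundTruth} (\linkS4class{GroundTruth}, templates filled).
#' @export
#' @examples
#' sim <- simulateRecording(generatorConfig(nChannels = 19, samplingRate = 250,
#'                                          duration = 4, seed = 7))
#' sim$recording
simulateRecording <- function(config, templates = NULL, minSeparation = 0.5) {
  if (is.null(templates))
    templates <- makeTemplateMaps(config@nChannels, config@nStates,
                                  seed = deriveSeed(config@seed, 17L),
                                  minSeparation = minSeparation)
  gt <- sampleStateSequence(config)
  gt@templates <- templates
  rec <- synthesizeRecording(templates, gt, config)
  list(recording = rec, groundTruth = gt)
}

#' Inject controlled artifacts into a recording
#'
#' Supports three artifact families used to exercise the preprocessing
#' criteria: flatline spans (channel holds the value it had at span start),
#' noisy channels (replaced by independent Gaussian noise of matched
#' amplitude over the span), and high-amplitude bursts (windowed noise
#' transients added to all channels). All injections are logged in the
#' returned recording's provenance. With all specs empty the recording is
#' returned unchanged.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param flatChannels data.frame(channel, start, end) with times in seconds.
#' @param noisyChannels data.frame(channel) or (channel, start, end).
#' @param bursts data.frame(start) or (start, amplitude); each burst occupies
#'   a 0.5-s window from \code{start}; amplitude is a multiple of the median
#'   channel RMS (default 50).
#' @param seed integer seed for the injected noise.
#' @return the modified \linkS4class{EEGRecording}.
#' @export
injectArtifacts <- function(recording, flatChannels = NULL,
                            noisyChannels = NULL, bursts = NULL, seed = 1L) {
  if (is.null(flatChannels) && is.null(noisyChannels) && is.null(bursts))
    return(recording)
  X <- recording@data
  fs <- recording@samplingRate
  n <- ncol(X)
  log <- list()
  spans <- list() # per-channel injected spans, for overlap checking
  claim <- function(ch, a, b) {
    key <- as.character(ch)
    prev <- spans[[key]]
    if (!is.null(prev) &&
        any(a <= prev[, 2] & b >= prev[, 1]))
      stop("overlapping artifact specs on channel ", ch, call. = FALSE)
    spans[[key]] <<- rbind(prev, c(a, b))
  }
  chIndex <- function(ch) {
    i <- if (is.character(ch)) match(ch, recording@channelNames)
    else as.integer(ch)
    stopIfNot(!is.na(i) && i >= 1 && i <= nrow(X), paste("bad channel", ch))
    i
  }
  withSeed(seed, {
    if (!is.null(flatChannels)) for (r in seq_len(nrow(flatChannels))) {
      i <- chIndex(flatChannels$channel[r])
      a <- max(1L, round(flatChannels$start[r] * fs) + 1L)
      b <- min(n, round(flatChannels$end[r] * fs))
      claim(i, a, b)
      X[i, a:b] <- X[i, a]
      log[[length(log) + 1L]] <- list(type = "flat", channel = i,
                                      start = a, end = b)
    }
    if (!is.null(noisyChannels)) for (r in seq_len(nrow(noisyChannels))) {
      i <- chIndex(noisyChannels$channel[r])
      a <- if ("start" %in% names(noisyChannels))
        max(1L, round(noisyChannels$start[r] * fs) + 1L) else 1L
      b <- if ("end" %in% names(noisyChannels))
        min(n, round(noisyChannels$end[r] * fs)) else n
      claim(i, a, b)
      X[i, a:b] <- rnorm(b - a + 1L, 0, max(sd(X[i, ]), 1e-12))
      log[[length(log) + 1L]] <- list(type = "noisy", channel = i,
                                      start = a, end = b)
    }
    if (!is.null(bursts)) for (r in seq_len(nrow(bursts))) {
      a <- max(1L, round(bursts$start[r] * fs) + 1L)
      b <- min(n, a + round(0.5 * fs) - 1L)
      amp <- if ("amplitude" %in% names(bursts)) bursts$amplitude[r] else 50
      scale <- amp * median(apply(X, 1, function(ch) sqrt(mean(ch^2))))
      w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = b - a + 1L))
      X[, a:b] <- X[, a:b] +
        matrix(rnorm(nrow(X) * (b - a + 1L), 0, scale), nrow(X)) *
        matrix(w, nrow(X), b - a + 1L, byrow = TRUE)
      log[[length(log) + 1L]] <- list(type = "burst", start = a, end = b,
                                      amplitude = amp)
    }
  })
  new("EEGRecording", data = X, samplingRate = fs,
      channelNames = recording@channelNames,
      channelPositions = recording@channelPositions,
      provenance = c(recording@provenance,
                     list(list(step = "inject_artifacts", injections = log))))
}
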