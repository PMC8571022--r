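# Shared fixture builders. All randomness is seeded by the caller.

fixRecording <- function(X, fs = 250) {
  C <- nrow(X)
  m <- standardMontage(C)
  new("EEGRecording", data = X, samplingRate = fs,
      channelNames = m$channelNames, channelPositions = m$positions,
      provenance = list())
}

# Single-channel waveform replicated over nCh channels.
waveRecording <- function(x, fs = 250, nCh = 4) {
  fixRecording(matrix(rep(x, each = nCh), nCh), fs)
}

fixTemplateSet <- function(maps, labels = rep("unassigned", ncol(maps)),
                           source = "fix") {
  new("TemplateSet", maps = maps,
      channelNames = sprintf("E%02d", seq_len(nrow(maps))),
      labels = labels, gevTotal = NA_real_, gevPerClass = numeric(0),
      source = source)
}

# Orthonormal average-referenced maps (columns) on C channels.
orthoMaps <- function(C, K, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(C * K), C, K)
    M <- sweep(M, 2, colMeans(M))
    qr.Q(qr(M))[, seq_len(K), drop = FALSE]
  })
}

# Default small generator config for tests.
testConfig <- function(...) {
  args <- list(nChannels = 16L, nStates = 4L, samplingRate = 250,
               duration = 20, meanSegmentMs = 80, noiseSigma = 0.1,
               seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(generatorConfig, args)
}
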