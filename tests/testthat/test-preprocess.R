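test_that("polyphase resampling preserves in-band content exactly", {
  x <- sin(2 * pi * 5 * (0:4999) / 1000)
  rec <- waveRecording(x, fs = 1000)
  out <- resampleRecording(rec, 250)
  expect_identical(ncol(eegData(out)), 1250L)
  truth <- sin(2 * pi * 5 * (0:1249) / 250)
  expect_gte(cor(eegData(out)[1, ], truth), 0.999)
  # identity when the target equals the current rate
  expect_equal(eegData(resampleRecording(rec, 1000)), eegData(rec),
               tolerance = 1e-9)
  expect_error(resampleRecording(rec, -5), "positive")
})

test_that("band-pass and notch have the designed magnitude response", {
  fs <- 250
  tt <- (0:(120 * fs - 1)) / fs
  rms <- function(v) sqrt(mean(v^2))
  flt <- function(x) eegData(bandpassNotch(waveRecording(x, fs)))[1, ]
  s50 <- sin(2 * pi * 50 * tt + 0.7)
  expect_lte(rms(flt(s50)) / rms(s50), 0.05)
  s10 <- sin(2 * pi * 10 * tt + 0.3)
  expect_gte(rms(flt(s10)) / rms(s10), 0.90)
  dc <- rep(1, length(tt))
  expect_lte(rms(flt(dc)), 1e-6)
  expect_error(bandpassNotch(waveRecording(s10, fs), low = 30, high = 200),
               "invalid")
})

test_that("bad-channel detection flags planted faults and spares clean data", {
  cfg <- testConfig(nChannels = 64L, duration = 60, noiseSigma = 0.005,
                    envelopeFreq = 0, seed = 41)
  sim <- simulateRecording(cfg)
  expect_identical(nrow(detectBadChannels(sim$recording)), 0L)
  art <- injectArtifacts(sim$recording,
                         flatChannels = data.frame(channel = "E03",
                                                   start = 10, end = 16.5),
                         noisyChannels = data.frame(channel = "E07"),
                         seed = 141)
  bad <- detectBadChannels(art)
  expect_true(any(bad$channel == "E03" & grepl("flatline", bad$reasons)))
  expect_true(any(bad$channel == "E07" & grepl("correlation", bad$reasons)))
  expect_true(all(bad$channel %in% c("E03", "E07")))
})

test_that("detection refuses a recording with too few usable channels", {
  sim <- simulateRecording(testConfig(nChannels = 8L, duration = 10,
                                      noiseSigma = 0.005, envelopeFreq = 0,
                                      seed = 5))
  X <- eegData(sim$recording)
  X[1:6, ] <- 0 # six dead-flat channels
  expect_error(detectBadChannels(fixRecording(X)), "fewer than 4")
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  mont <- standardMontage(64)
  d <- c(0.3, 0.8, 0.52); d <- d / sqrt(sum(d^2))
  field <- as.numeric(mont$positions %*% d)
  amp <- withr::with_seed(7, runif(100, 0.5, 2))
  X <- outer(field, amp)
  rec <- fixRecording(X, fs = 100)
  out <- interpolateSpherical(rec, "E20")
  expect_lt(max(abs(eegData(out)[20, ] - X[20, ]) / abs(X[20, ])), 0.05)
  # good channels untouched; empty set is the identity
  expect_identical(eegData(out)[-20, ], X[-20, ])
  expect_identical(interpolateSpherical(rec, character(0)), rec)
  # the operator is linear and time-independent
  X2 <- X + outer(as.numeric(mont$positions %*% c(0, 0, 1)), rev(amp))
  o2 <- interpolateSpherical(fixRecording(X2, fs = 100), "E20")
  o12 <- interpolateSpherical(fixRecording(X + X2, fs = 100), "E20")
  expect_equal(eegData(o12)[20, ], eegData(out)[20, ] + eegData(o2)[20, ],
               tolerance = 1e-9)
  expect_error(interpolateSpherical(rec, mont$channelNames), "all")
})

test_that("average referencing zeroes column means and is idempotent", {
  X <- withr::with_seed(3, matrix(rnorm(8 * 100), 8) + 10)
  rec <- fixRecording(X)
  out <- rereferenceAverage(rec)
  expect_equal(colSums(eegData(out)), rep(0, 100), tolerance = 1e-9)
  out2 <- rereferenceAverage(out)
  expect_equal(eegData(out2), eegData(out), tolerance = 1e-9)
})

test_that("window rejection excises exactly the planted burst windows", {
  for (s in 1:5) {
    sim <- simulateRecording(testConfig(duration = 30, seed = s))
    art <- injectArtifacts(sim$recording,
                           bursts = data.frame(start = 10, amplitude = 100),
                           seed = s + 50)
    rej <- rejectArtifactWindows(art)
    expect_equal(unname(rej$mask), matrix(c(10, 10.5), 1), tolerance = 1e-9)
  }
  # clean data: empty mask; infinite cut: identity
  sim <- simulateRecording(testConfig(duration = 30, seed = 7))
  expect_identical(nrow(rejectArtifactWindows(sim$recording)$mask), 0L)
  ident <- rejectArtifactWindows(sim$recording, sdCut = Inf)
  expect_identical(eegData(ident$recording), eegData(sim$recording))
  # mostly-artifact recordings are refused
  art2 <- injectArtifacts(sim$recording,
                          bursts = data.frame(start = seq(0, 29, by = 0.5)[1:40],
                                              amplitude = 100),
                          seed = 9)
  expect_error(rejectArtifactWindows(art2), "unusable")
})

test_that("epoching respects length arithmetic and rejection boundaries", {
  sim <- simulateRecording(testConfig(duration = 300, seed = 2))
  ep <- epochRecording(sim$recording, 2)
  expect_length(epochs(ep), 150)
  expect_identical(dim(epochs(ep)[[1]]), c(16L, 500L))
  short <- simulateRecording(testConfig(duration = 5.5, seed = 2))
  expect_length(epochs(epochRecording(short$recording, 2)), 2)
  # an epoch can never span an excised window
  sim10 <- simulateRecording(testConfig(duration = 10, seed = 3))
  art <- injectArtifacts(sim10$recording,
                         bursts = data.frame(start = 3.0, amplitude = 100),
                         seed = 4)
  rej <- rejectArtifactWindows(art)
  ep2 <- epochRecording(rej$recording, 2)
  # chunks [0, 3.0] and [3.5, 10] give 1 + 3 epochs
  expect_length(epochs(ep2), 4)
  expect_error(epochRecording(simulateRecording(
    testConfig(duration = 1, seed = 1))$recording, 2), "no epochs")
})

test_that("the full chain is signal-preserving at moderate noise", {
  cfg <- testConfig(nChannels = 32L, duration = 60, noiseSigma = 0.1,
                    seed = 9)
  sim <- simulateRecording(cfg)
  pp <- preprocessRecording(sim$recording, targetRate = 250)
  expect_gt(length(epochs(pp$epochs)), 20)
  # per-sample maps still point at the generating template (in-band noise
  # caps the per-sample correlation; the bulk must stay high)...
  lab <- stateLabels(sim$groundTruth)
  X <- do.call(cbind, epochs(pp$epochs))
  g <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  hi <- which(g > median(g))
  cors <- vapply(hi, function(t)
    abs(cor(X[, t], sim$groundTruth@templates[, lab[t]])), 0)
  expect_gte(median(cors), 0.9)
  # ...so that templates recovered after the chain match the generators
  ts <- subjectTemplates(pp$epochs)
  R <- abs(cor(templateMaps(ts), sim$groundTruth@templates))
  expect_gte(min(apply(R, 2, max)), 0.95)
})
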