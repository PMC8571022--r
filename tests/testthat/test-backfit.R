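test_that("noise-free backfit reproduces the ground-truth labels", {
  sim <- simulateRecording(testConfig(noiseSigma = 0, duration = 20,
                                      seed = 22))
  X <- eegData(sim$recording)
  Tm <- sim$groundTruth@templates
  seg <- backfit(X, Tm, samplingRate = 250)
  g <- gfpValues(seg)[[1]]
  nz <- g > 1e-9
  expect_identical(seg@labels[[1]][nz], stateLabels(sim$groundTruth)[nz])
  # polarity invariance: sign-flipped data give identical labels
  segF <- backfit(-X, Tm, samplingRate = 250)
  expect_identical(segF@labels, seg@labels)
})

test_that("random data covers orthogonal templates uniformly", {
  Tm <- orthoMaps(16, 4, seed = 1)
  covs <- sapply(1:5, function(s) {
    X <- withr::with_seed(s, matrix(rnorm(16 * 5000), 16))
    seg <- backfit(X, Tm, samplingRate = 250)
    computeParameters(seg)@coveragePct
  })
  expect_equal(unname(rowMeans(covs)), rep(25, 4), tolerance = 0.1)
})

test_that("label smoothing absorbs short segments without shrinking survivors", {
  Tm <- orthoMaps(8, 2, seed = 3)
  lab <- c(rep(1L, 10), 2L, rep(1L, 10))
  X <- Tm[, lab]
  seg <- backfit(X, Tm, samplingRate = 250)
  expect_identical(seg@labels[[1]], lab)
  expect_identical(smoothLabels(seg), seg) # threshold 0 is the identity
  sm <- smoothLabels(seg, minSegmentMs = 8, epochs = list(X),
                     templates = Tm)
  expect_identical(sm@labels[[1]], rep(1L, 21))
  # property: smoothing never decreases a surviving class's mean duration
  for (s in 1:5) {
    lab2 <- withr::with_seed(s, sample(1:2, 200, replace = TRUE))
    X2 <- Tm[, lab2] + withr::with_seed(s + 9,
                                        matrix(rnorm(8 * 200, 0, 0.05), 8))
    sg <- backfit(X2, Tm, samplingRate = 250)
    sm2 <- smoothLabels(sg, minSegmentMs = 12, epochs = list(X2),
                        templates = Tm)
    d0 <- computeParameters(sg)@durationMs
    d1 <- computeParameters(sm2)@durationMs
    ok <- !is.na(d0) & !is.na(d1)
    expect_true(all(d1[ok] >= d0[ok] - 1e-9))
  }
})

test_that("parameters follow their definitions on hand-built labellings", {
  seg <- segmentationFromLabels(c(rep(1L, 250), rep(2L, 250)), K = 4,
                                samplingRate = 250)
  p <- computeParameters(seg)
  expect_equal(unname(coveragePct(p)), c(50, 50, 0, 0))
  expect_true(all(is.na(durationMs(p)[1:2]))) # both runs touch a boundary
  expect_equal(unname(occurrencePerS(p)[1:2]), c(0.5, 0.5))
  seg2 <- segmentationFromLabels(c(rep(1L, 100), rep(2L, 50), rep(1L, 100),
                                   rep(3L, 250)), K = 3,
                                 samplingRate = 250)
  p2 <- computeParameters(seg2)
  expect_equal(unname(durationMs(p2)[2]), 200)
  expect_equal(unname(coveragePct(p2)), c(40, 10, 50))
  # coverage always sums to 100 exactly
  expect_equal(sum(coveragePct(p2)), 100, tolerance = 1e-12)
})

test_that("parameter estimates recover generator ground truth", {
  cfg <- testConfig(noiseSigma = 0, duration = 120, seed = 23)
  sim <- simulateRecording(cfg)
  seg <- backfit(eegData(sim$recording), sim$groundTruth@templates,
                 samplingRate = 250)
  p <- computeParameters(seg)
  st <- segmentTable(sim$groundTruth)
  inner <- st[-c(1, nrow(st)), ]
  truthDur <- as.numeric(tapply(inner$end - inner$start + 1,
                                inner$state, mean)) * 4
  expect_equal(unname(durationMs(p)), truthDur, tolerance = 0.1)
  truthCov <- 100 * tabulate(stateLabels(sim$groundTruth), 4) /
    length(stateLabels(sim$groundTruth))
  expect_true(all(abs(coveragePct(p) - truthCov) < 2))
})

test_that("transition counting stays within epochs and matches the chain", {
  lab <- rep(rep(c(1L, 2L), length.out = 11), each = 10) # 10 transitions
  tt <- transitionMatrix(segmentationFromLabels(lab, K = 2,
                                                samplingRate = 250))
  expect_equal(observedPct(tt)[1, 2], 50)
  expect_equal(observedPct(tt)[2, 1], 50)
  expect_error(transitionMatrix(segmentationFromLabels(rep(1L, 100), K = 2,
                                                       samplingRate = 250)),
               "no transitions")
  # long Markov sequence: conditional frequencies approach the chain
  tm <- matrix(c(0, 0.6, 0.4,
                 0.2, 0, 0.8,
                 0.5, 0.5, 0), 3, 3, byrow = TRUE)
  cfg <- testConfig(nStates = 3L, transitionMatrix = tm, duration = 300,
                    noiseSigma = 0, seed = 31)
  gt <- sampleStateSequence(cfg)
  seg <- segmentationFromLabels(stateLabels(gt), K = 3, samplingRate = 250)
  obs <- observedPct(transitionMatrix(seg))
  cond <- obs / rowSums(obs)
  expect_true(all(abs(cond - tm)[tm > 0] < 0.05))
})

test_that("expected transitions implement the independence null", {
  e <- expectedTransitions(c(A = 10, B = 10, C = 10, D = 10))
  off <- expectedPct(e)[row(expectedPct(e)) != col(expectedPct(e))]
  expect_equal(off, rep(100 / 12, 12), tolerance = 1e-12)
  e2 <- expectedTransitions(c(A = 5, B = 5))
  expect_equal(expectedPct(e2)[1, 2], 50)
  expect_error(expectedTransitions(c(A = 5, B = 0)), "two classes")
  # label-independent successors: observed converges to expected
  cfg <- testConfig(duration = 600, noiseSigma = 0, seed = 33)
  gt <- sampleStateSequence(cfg)
  tt <- expectedTransitions(transitionMatrix(
    segmentationFromLabels(stateLabels(gt), K = 4, samplingRate = 250)))
  expect_true(all(abs(observedPct(tt) - expectedPct(tt)) < 1.5))
})

test_that("coverage is consistent with occurrence times duration", {
  cfg <- testConfig(duration = 300, noiseSigma = 0, seed = 35)
  sim <- simulateRecording(cfg)
  seg <- backfit(eegData(sim$recording), sim$groundTruth@templates,
                 samplingRate = 250)
  p <- computeParameters(seg)
  pred <- occurrencePerS(p) * durationMs(p) / 1000 * 100
  expect_true(all(abs(pred - coveragePct(p)) <= 2))
})

test_that("backfit is the GEV-optimal per-sample labelling", {
  Tm <- orthoMaps(6, 2, seed = 8)
  X <- withr::with_seed(9, matrix(rnorm(6 * 10), 6, 10))
  seg <- backfit(X, Tm, samplingRate = 250)
  best <- gevFit(X, seg@labels[[1]], Tm)$total
  grid <- as.matrix(expand.grid(rep(list(1:2), 10)))
  all_gev <- apply(grid, 1, function(l) gevFit(X, l, Tm)$total)
  expect_lte(max(all_gev), best + 1e-12)
})
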