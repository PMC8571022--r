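test_that("GFP matches its closed forms", {
  expect_equal(gfpValues(gfp(matrix(c(1, -1), 2, 1), 250))[[1]], 1)
  expect_equal(gfpValues(gfp(matrix(5, 4, 1), 250))[[1]], 0)
  expect_equal(gfpValues(gfp(matrix(c(2, 0, -2, 0), 4, 1), 250))[[1]],
               sqrt(2))
  expect_error(gfp(matrix(1, 1, 10), 250), "single-channel")
})

test_that("GFP peak detection enforces strictness, spacing and tie rule", {
  mkg <- function(v, fs = 250) new("GfpSeries", values = list(v),
                                   peaks = list(integer(0)),
                                   samplingRate = fs)
  expect_length(findGfpPeaks(mkg(seq_len(100)))@peaks[[1]], 0)
  # rectified 10 Hz sinusoid at 250 Hz: ~20 peaks per second
  tt <- (0:(250 * 4 - 1)) / 250
  env <- abs(sin(2 * pi * 10 * tt))
  np <- length(findGfpPeaks(mkg(env))@peaks[[1]])
  expect_true(abs(np / 4 - 20) <= 1)
  # equal maxima 4 ms apart at 1000 Hz: earlier index wins
  v <- c(0, 1, 0.5, 0.5, 0.5, 1, 0)
  pk <- findGfpPeaks(mkg(v, fs = 1000), minDistanceMs = 10)@peaks[[1]]
  expect_identical(pk, 2L)
  # epoch boundaries are never peaks
  expect_false(1L %in% findGfpPeaks(mkg(c(2, 1, 2, 1, 2)))@peaks[[1]])
})

test_that("spatial correlation is polarity-invariant Pearson", {
  u <- c(1, -1, 0, 0); v <- c(0, 0, 1, -1)
  expect_equal(spatialCorrelation(u, u), 1)
  expect_equal(spatialCorrelation(u, -u), 1)
  expect_equal(spatialCorrelation(u, -u, ignorePolarity = FALSE), -1)
  expect_equal(spatialCorrelation(u, v), 0)
  expect_error(spatialCorrelation(u, rep(1, 4)), "zero-variance")
})

test_that("AAHC separates noise-free groups and is scale/sign invariant", {
  G <- orthoMaps(8, 2, seed = 2)
  V <- cbind(G[, 1] * 2, -G[, 1], G[, 1] * 0.5,
             G[, 2], -3 * G[, 2], G[, 2] * 1.5)
  res <- aahcCluster(V, 2)
  expect_true(samePartition(res$assignment, c(1, 1, 1, 2, 2, 2)))
  R <- abs(cor(templateMaps(res$templates), G))
  expect_equal(apply(R, 2, max), c(1, 1), tolerance = 1e-9)
  # per-map sign flips and a common scale leave the partition unchanged
  # (per-map scaling legitimately reweights GEV contributions)
  V2 <- -1.3 * V %*% diag(c(-1, 1, 1, -1, 1, -1))
  expect_true(samePartition(aahcCluster(V2, 2)$assignment, res$assignment))
  # k = n: every map its own cluster, GEV = 1
  resN <- aahcCluster(V, ncol(V))
  expect_identical(sort(unique(resN$assignment)), 1:6)
  expect_equal(gevTotal(resN$templates), 1, tolerance = 1e-9)
})

test_that("AAHC agrees with an independently written naive implementation", {
  for (s in 1:10) {
    n <- withr::with_seed(s, sample(10:40, 1))
    V <- withr::with_seed(100 + s, matrix(rnorm(8 * n), 8, n))
    expect_true(samePartition(aahcCluster(V, 3)$assignment,
                              naiveAAHC(V, 3)),
                label = paste("seed", s))
  }
})

test_that("GEV never decreases as k grows on one peak set", {
  V <- withr::with_seed(5, matrix(rnorm(8 * 30), 8, 30))
  gevs <- vapply(2:6, function(k) gevTotal(aahcCluster(V, k)$templates), 0)
  expect_true(all(diff(gevs) >= -1e-9))
})

test_that("GEV identities hold for exact and orthogonal labellings", {
  Tm <- orthoMaps(8, 3, seed = 4)
  lab <- withr::with_seed(6, sample(1:3, 40, replace = TRUE))
  sc <- withr::with_seed(7, runif(40, 0.5, 2) * sample(c(-1, 1), 40,
                                                       replace = TRUE))
  V <- Tm[, lab] %*% diag(sc)
  expect_equal(gevFit(V, lab, Tm)$total, 1, tolerance = 1e-9)
  # orthogonal (wrong) labels explain nothing
  wrong <- (lab %% 3) + 1L
  expect_equal(gevFit(V, wrong, Tm)$total, 0, tolerance = 1e-9)
  # per-class decomposition sums to the total
  fit <- gevFit(V, lab, Tm)
  expect_equal(sum(fit$perClass), fit$total, tolerance = 1e-12)
})

test_that("random labels never beat the backfit-optimal labelling", {
  sim <- simulateRecording(testConfig(duration = 10, seed = 13))
  X <- eegData(rereferenceAverage(sim$recording))
  Tm <- sim$groundTruth@templates
  seg <- backfit(X, Tm, samplingRate = 250)
  best <- gevFit(X, seg@labels[[1]], Tm)$total
  for (s in 1:5) {
    rnd <- withr::with_seed(s, sample(1:4, ncol(X), replace = TRUE))
    expect_lt(gevFit(X, rnd, Tm)$total, best)
  }
})

test_that("subject alignment recovers shuffles and signs; single subject is identity", {
  maps <- makeTemplateMaps(16, 4, seed = 3)
  sets <- list(fixTemplateSet(maps),
               fixTemplateSet(maps[, c(3, 1, 4, 2)] %*% diag(c(-1, 1, -1, 1))),
               fixTemplateSet(maps[, c(4, 3, 2, 1)] %*% diag(c(1, -1, 1, -1))))
  al <- alignSubjectMaps(sets)
  gm <- groupMeanTemplates(al)
  for (s in seq_along(al))
    expect_equal(unname(abs(diag(cor(templateMaps(gm),
                                     templateMaps(al[[s]]))))),
                 rep(1, 4), tolerance = 1e-9)
  one <- alignSubjectMaps(sets[1])
  expect_identical(templateMaps(one[[1]]), maps)
  # noisy subjects converge with group mean close to every subject
  noisySets <- lapply(1:6, function(s) {
    pert <- withr::with_seed(s, maps + matrix(rnorm(64, 0, 0.12), 16, 4))
    pert <- apply(pert, 2, function(v) v - mean(v))
    pert <- apply(pert, 2, function(v) v / sqrt(sum(v^2)))
    perm <- withr::with_seed(s + 50, sample(4))
    fixTemplateSet(pert[, perm] %*% diag(sample(c(-1, 1), 4, TRUE)))
  })
  alN <- alignSubjectMaps(noisySets)
  gmN <- groupMeanTemplates(alN)
  for (s in seq_along(alN))
    expect_gt(min(abs(diag(cor(templateMaps(gmN), templateMaps(alN[[s]]))))),
              0.85)
})

test_that("canonical labelling recovers planted permutations under sign flips", {
  mont <- standardMontage(32)
  arch <- canonicalArchetypes(mont$positions)
  lc0 <- labelCanonical(fixTemplateSet(templateMaps(arch)), arch)
  expect_identical(classLabels(lc0$templates), c("A", "B", "C", "D"))
  expect_equal(unname(lc0$correlations), rep(1, 4), tolerance = 1e-9)
  for (s in 1:8) {
    perm <- withr::with_seed(s, sample(4))
    signs <- withr::with_seed(s + 10, sample(c(-1, 1), 4, TRUE))
    shuf <- fixTemplateSet(templateMaps(arch)[, perm] %*% diag(signs))
    lc <- labelCanonical(shuf, arch)
    # brute-force expectation: class of template j is the archetype it was
    # copied from, i.e. reordering restores A,B,C,D with |corr| 1
    expect_equal(unname(lc$correlations), rep(1, 4), tolerance = 1e-9)
    expect_equal(unname(abs(diag(cor(templateMaps(lc$templates),
                                     templateMaps(arch))))), rep(1, 4),
                 tolerance = 1e-9)
  }
})

test_that("templates are recovered from noisy synthetic recordings", {
  cfg <- testConfig(nChannels = 32L, duration = 60, noiseSigma = 0.2,
                    seed = 17)
  sim <- simulateRecording(cfg)
  ep <- epochRecording(rereferenceAverage(sim$recording), 2)
  ts <- subjectTemplates(ep)
  R <- abs(cor(templateMaps(ts), sim$groundTruth@templates))
  expect_gte(min(apply(R, 2, max)), 0.95)
})
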