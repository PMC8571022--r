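test_that("the normality gate routes to the right test", {
  x <- withr::with_seed(1, rnorm(20))
  same <- normalityGatedCompare(x, x)
  expect_match(same$test, "t")
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  skewed <- withr::with_seed(2, exp(rnorm(40, 0, 1.5)))
  g <- normalityGatedCompare(skewed, withr::with_seed(3, exp(rnorm(40, 0, 1.5))))
  expect_identical(g$test, "Mann-Whitney U")
  expect_identical(g$gate, "non-normal")
  const <- normalityGatedCompare(rep(1, 5), withr::with_seed(4, rnorm(5)))
  expect_identical(const$gate, "constant-sample")
})

test_that("test statistics match closed-form oracles", {
  for (s in 1:10) {
    x <- withr::with_seed(s, rnorm(46, 0, 1))
    y <- withr::with_seed(s + 100, rnorm(22, 0.4, 1.2))
    got <- normalityGatedCompare(x, y)
    if (grepl("^t", got$test)) {
      o <- oracleT(x, y)
      expect_equal(got$statistic, o$t, tolerance = 1e-10)
      expect_equal(got$p_value, o$p, tolerance = 1e-10)
    } else {
      expect_equal(got$statistic, oracleU(x, y), tolerance = 1e-10)
    }
    pr <- pearsonWithP(x[1:22], y)
    o2 <- oraclePearson(x[1:22], y)
    expect_equal(pr$r, o2$r, tolerance = 1e-10)
    expect_equal(pr$p_value, o2$p, tolerance = 1e-10)
    sr <- simpleRegression(y, x[1:22])
    o3 <- oracleSlope(y, x[1:22])
    expect_equal(sr$beta, o3$beta, tolerance = 1e-10)
    expect_equal(sr$p_value, o3$p, tolerance = 1e-10)
  }
  # the frozen hand-computed example
  expect_equal(pearsonWithP(c(1, 2, 3), c(1, 2, 4))$r, 0.98198,
               tolerance = 1e-5)
  expect_equal(pearsonWithP(1:10, 2 * (1:10) + 1)$r, 1)
})

test_that("regression handles exact fits and degenerate designs", {
  x <- 1:10
  fit <- simpleRegression(3 * x, x)
  expect_equal(fit$beta, 3, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-12)
  expect_error(simpleRegression(rnorm(5), rep(2, 5)), "degenerate")
})

test_that("regression confidence intervals have nominal coverage", {
  hits <- 0
  for (s in 1:60) {
    x <- withr::with_seed(s, runif(22, 0, 10))
    y <- withr::with_seed(s + 500, -1.5 * x + rnorm(22, 0, 3))
    fit <- simpleRegression(y, x)
    ci <- fit$beta + c(-1, 1) * stats::qt(0.975, 20) * fit$se
    if (ci[1] <= -1.5 && -1.5 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 54) # >= 90% at nominal 95%
})

test_that("ANCOVA detects slope differences and holds its type-I error", {
  g <- rep(c("a", "b"), c(22, 46))
  expect_error(ancovaGroupInteraction(
    withr::with_seed(1, rnorm(68)),
    c(rep(1, 22), withr::with_seed(2, rnorm(46))), g))
  hits <- 0
  for (s in 1:40) {
    x <- withr::with_seed(s, runif(68, 0, 10))
    y <- withr::with_seed(s + 900,
                          ifelse(g == "a", -1.5 * x, 0) + rnorm(68, 0, 4))
    if (ancovaGroupInteraction(y, x, g)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.8)
  rej <- 0
  for (s in 1:400) {
    x <- withr::with_seed(2000 + s, runif(68, 0, 10))
    y <- withr::with_seed(3000 + s, 0.7 * x + rnorm(68, 0, 4))
    if (ancovaGroupInteraction(y, x, g)$p_value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 400, 0.03)
  expect_lte(rej / 400, 0.07)
})

test_that("Cohen's d follows its closed form and sign convention", {
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohensD(c(0, 1), c(1, 2)), -sqrt(2), tolerance = 1e-12)
  x <- withr::with_seed(5, rnorm(10)); y <- withr::with_seed(6, rnorm(12))
  expect_equal(cohensD(x, y), -cohensD(y, x))
  expect_error(cohensD(rep(1, 4), rep(2, 4)), "pooled")
})

test_that("p-value adjustment matches hand-computed step-down", {
  expect_equal(adjustPvalues(0.03), 0.03)
  expect_equal(adjustPvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjustPvalues(p, "holm"), c(0.04, 0.06, 0.06, 0.06))
  for (s in 1:5) {
    q <- withr::with_seed(s, runif(12))
    adj <- adjustPvalues(q, "holm")
    expect_equal(adj, oracleHolm(q))
    expect_true(all(adj >= q))
    expect_true(all(diff(adj[order(q)]) >= -1e-12))
  }
})

test_that("observed-vs-expected transition tests behave at the extremes", {
  mkTab <- function(obs, ex) {
    K <- 2
    new("TransitionTable",
        observedPct = matrix(c(0, obs, 100 - obs, 0), 2, 2),
        expectedPct = matrix(c(0, ex, 100 - ex, 0), 2, 2),
        segmentCounts = c(A = 10, B = 10), classNames = c("A", "B"))
  }
  vals <- withr::with_seed(8, runif(6, 40, 60))
  same <- compareObservedExpectedTransitions(
    lapply(vals, function(v) mkTab(v, v)))
  expect_equal(same$t, rep(0, 2), tolerance = 1e-12)
  expect_equal(same$p_value, rep(1, 2), tolerance = 1e-12)
  # planted coupling: B->C and C->B excess is flagged with positive d
  tabs <- lapply(1:20, function(s) {
    tm <- matrix(1 / 3, 4, 4); diag(tm) <- 0
    tm[2, 3] <- 0.7; tm[2, -c(2, 3)] <- 0.15
    tm[3, 2] <- 0.7; tm[3, -c(2, 3)] <- 0.15
    cfg <- testConfig(transitionMatrix = tm, duration = 60, noiseSigma = 0,
                      seed = 600 + s)
    expectedTransitions(transitionMatrix(segmentationFromLabels(
      stateLabels(sampleStateSequence(cfg)), K = 4, samplingRate = 250,
      classNames = c("A", "B", "C", "D"))))
  })
  res <- compareObservedExpectedTransitions(tabs)
  bc <- res[(res$from == "B" & res$to == "C") |
              (res$from == "C" & res$to == "B"), ]
  expect_true(all(bc$p_adjusted < 0.05))
  expect_true(all(bc$d > 0))
})

test_that("the full report reproduces a planted group difference pattern", {
  cohorts <- lapply(1:3, function(rep) {
    meta <- withr::with_seed(400 + rep, data.frame(
      subject_id = sprintf("S%02d", 1:30),
      group = rep(c("RBD", "HC"), c(12, 18)),
      rbdqhk_score = c(sample(17:80, 12, TRUE),
                       sample(0:12, 18, TRUE))))
    pars <- lapply(seq_len(30), function(s) {
      msm <- c(80, 80, 80, 80)
      if (meta$group[s] == "RBD") msm <- c(80, 96, 80, 66)
      cfg <- testConfig(meanSegmentMs = msm, duration = 60, noiseSigma = 0,
                        seed = 5000 + rep * 100 + s)
      computeParameters(segmentationFromLabels(
        stateLabels(sampleStateSequence(cfg)), K = 4, samplingRate = 250))
    })
    trans <- lapply(seq_len(30), function(s) {
      cfg <- testConfig(duration = 60, noiseSigma = 0,
                        seed = 7000 + rep * 100 + s)
      expectedTransitions(transitionMatrix(segmentationFromLabels(
        stateLabels(sampleStateSequence(cfg)), K = 4, samplingRate = 250)))
    })
    list(subjects = meta, parameters = pars, transitions = trans)
  })
  hits <- 0
  for (co in cohorts) {
    rep <- groupComparisonReport(co)
    pd <- rep$parameters
    dD <- pd[pd$cell == "duration_D", ]
    cB <- pd[pd$cell == "coverage_B", ]
    if (dD$mean_rbd < dD$mean_hc && dD$p_value < 0.05 &&
        cB$mean_rbd > cB$mean_hc && cB$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 2)
  expect_error(groupComparisonReport(list(
    subjects = data.frame(subject_id = "a", group = "HC", rbdqhk_score = 1),
    parameters = list(), transitions = list())), "both groups")
})
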