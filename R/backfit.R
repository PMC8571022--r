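#' Backfit templates to every sample
#'
#' Assigns each sample the template of maximal absolute spatial correlation
#' (polarity ignored). Ties go to the lowest class index. Samples with GFP
#' below 1e-12 inherit the previous label (the first sample of an epoch
#' falls back to class 1) so envelope zeros cannot create spurious
#' segments.
#'
#' @param x an \linkS4class{EpochedData} (average-referenced), a channels x
#'   samples matrix or a list of matrices.
#' @param templates a \linkS4class{TemplateSet} (or channels x K matrix).
#' @param samplingRate required when \code{x} is not EpochedData.
#' @return a \linkS4class{MicrostateSegmentation}.
#' @export
backfit <- function(x, templates, samplingRate = NULL) {
  if (is(templates, "TemplateSet")) {
    Tm <- templates@maps
    classNames <- templates@labels
  } else {
    Tm <- templates
    classNames <- colnames(Tm) %||% paste0("T", seq_len(ncol(Tm)))
  }
  if (is(x, "EpochedData")) {
    eps <- x@epochs
    fs <- x@samplingRate
    stopIfNot(length(x@channelNames) == nrow(Tm), "channel mismatch")
  } else if (is.matrix(x)) {
    eps <- list(x); fs <- samplingRate %||% NA_real_
  } else {
    eps <- x; fs <- samplingRate %||% NA_real_
  }
  K <- ncol(Tm)
  Tc <- apply(Tm, 2, function(u) unitNorm(u - mean(u)))
  labs <- vector("list", length(eps))
  cors <- vector("list", length(eps))
  gfps <- vector("list", length(eps))
  for (e in seq_along(eps)) {
    V <- centerChannels(eps[[e]])
    stopIfNot(nrow(V) == nrow(Tc), "channel mismatch")
    C <- nrow(V)
    g <- sqrt(colMeans(V^2))
    # |corr(v_t, T_k)| = |v_t . T_k| / (sqrt(C) * GFP_t)
    proj <- abs(crossprod(Tc, V)) # K x S
    lab <- integer(ncol(V))
    bestc <- numeric(ncol(V))
    best <- proj[1, ]
    lab[] <- 1L
    if (K > 1) for (kk in 2:K) {
      better <- proj[kk, ] > best
      lab[better] <- kk
      best[better] <- proj[kk, better]
    }
    ok <- g >= 1e-12
    bestc[ok] <- best[ok] / (sqrt(C) * g[ok])
    # carry the previous label through near-zero-GFP samples
    if (any(!ok)) {
      idx <- which(!ok)
      for (t in idx) lab[t] <- if (t == 1L) 1L else lab[t - 1L]
      bestc[idx] <- 0
    }
    labs[[e]] <- lab
    cors[[e]] <- pmin(1, bestc)
    gfps[[e]] <- g
  }
  new("MicrostateSegmentation", labels = labs, corr = cors, gfp = gfps,
      samplingRate = fs, K = as.integer(K), classNames = classNames)
}

# Runs of constant label within one epoch: data.frame(state, start, end).
labelRuns <- function(lab) {
  r <- rle(lab)
  end <- cumsum(r$lengths)
  data.frame(state = r$values, start = end - r$lengths + 1L, end = end)
}

#' Absorb segments shorter than a minimum duration
#'
#' Each sample of a segment shorter than \code{minSegmentMs} is reassigned
#' to the neighbouring segment whose template correlates better with it
#' (absolute spatial correlation), iterating until no short segment
#' remains. With the default threshold of 0 the segmentation is returned
#' unchanged (no temporal smoothing, the package default).
#'
#' @param segmentation a \linkS4class{MicrostateSegmentation}.
#' @param minSegmentMs minimum segment duration in ms.
#' @param epochs the \linkS4class{EpochedData} (or list of matrices) the
#'   segmentation came from; required when \code{minSegmentMs > 0}.
#' @param templates the \linkS4class{TemplateSet} used for backfitting;
#'   required when \code{minSegmentMs > 0}.
#' @return the smoothed \linkS4class{MicrostateSegmentation}.
#' @export
smoothLabels <- function(segmentation, minSegmentMs = 0, epochs = NULL,
                         templates = NULL) {
  stopIfNot(minSegmentMs >= 0, "minSegmentMs must be >= 0")
  if (minSegmentMs == 0) return(segmentation)
  stopIfNot(!is.null(epochs) && !is.null(templates),
            "epochs and templates are required for smoothing")
  eps <- if (is(epochs, "EpochedData")) epochs@epochs else epochs
  Tm <- if (is(templates, "TemplateSet")) templates@maps else templates
  Tc <- apply(Tm, 2, function(u) unitNorm(u - mean(u)))
  fs <- segmentation@samplingRate
  L <- round(minSegmentMs / 1000 * fs)
  for (e in seq_along(segmentation@labels)) {
    lab <- segmentation@labels[[e]]
    stopIfNot(L <= length(lab), "threshold longer than epoch")
    V <- centerChannels(eps[[e]])
    proj <- abs(crossprod(Tc, V)) # K x S
    for (iter in seq_len(200L)) {
      runs <- labelRuns(lab)
      short <- which(runs$end - runs$start + 1L < L)
      if (!length(short) || nrow(runs) == 1L) break
      r <- short[which.min(runs$end[short] - runs$start[short])]
      left <- if (r > 1L) runs$state[r - 1L] else NA_integer_
      right <- if (r < nrow(runs)) runs$state[r + 1L] else NA_integer_
      for (t in runs$start[r]:runs$end[r]) {
        lab[t] <- if (is.na(left)) right
        else if (is.na(right)) left
        else if (proj[left, t] >= proj[right, t]) left else right
      }
    }
    segmentation@labels[[e]] <- lab
    C <- nrow(V)
    g <- segmentation@gfp[[e]]
    ok <- g >= 1e-12
    cr <- numeric(length(lab))
    cr[ok] <- proj[cbind(lab[ok], which(ok))] / (sqrt(C) * g[ok])
    segmentation@corr[[e]] <- pmin(1, cr)
  }
  segmentation
}

#' Temporal microstate parameters of one subject
#'
#' Segments are maximal constant-label runs within each epoch. Mean
#' duration (ms) averages interior runs only (runs touching an epoch
#' boundary are truncated and would bias durations downward); occurrence
#' (1/s) counts all runs, boundary-truncated included, over the retained
#' time; coverage (\%) is the labelled sample share. Per-class GEV comes
#' from the stored per-sample GFP and assignment correlations.
#'
#' @param segmentation a \linkS4class{MicrostateSegmentation}.
#' @return a \linkS4class{MicrostateParameters}; classes with no interior
#'   run have NA duration.
#' @export
computeParameters <- function(segmentation) {
  K <- segmentation@K
  fs <- segmentation@samplingRate
  stopIfNot(length(segmentation@labels) > 0, "empty segmentation")
  nSamp <- 0L
  covN <- numeric(K)
  runCount <- numeric(K)
  durSum <- numeric(K); durN <- numeric(K)
  gevNum <- numeric(K); gevDen <- 0
  for (e in seq_along(segmentation@labels)) {
    lab <- segmentation@labels[[e]]
    n <- length(lab)
    nSamp <- nSamp + n
    covN <- covN + tabulate(lab, K)
    runs <- labelRuns(lab)
    runCount <- runCount + tabulate(runs$state, K)
    interior <- runs$start > 1L & runs$end < n
    if (any(interior)) {
      len <- runs$end[interior] - runs$start[interior] + 1L
      st <- runs$state[interior]
      for (kk in unique(st)) {
        sel <- st == kk
        durSum[kk] <- durSum[kk] + sum(len[sel])
        durN[kk] <- durN[kk] + sum(sel)
      }
    }
    g <- segmentation@gfp[[e]]
    cr <- segmentation@corr[[e]]
    gc2 <- (g * cr)^2
    for (kk in seq_len(K)) gevNum[kk] <- gevNum[kk] + sum(gc2[lab == kk])
    gevDen <- gevDen + sum(g^2)
  }
  secs <- nSamp / fs
  dur <- ifelse(durN > 0, durSum / durN * 1000 / fs, NA_real_)
  occ <- runCount / secs
  cov <- 100 * covN / nSamp
  gevK <- if (gevDen > 0) gevNum / gevDen else rep(NA_real_, K)
  nm <- segmentation@classNames
  names(dur) <- names(occ) <- names(cov) <- names(gevK) <- nm
  new("MicrostateParameters", durationMs = dur, occurrencePerS = occ,
      coveragePct = cov, gevPerClass = gevK, gevTotal = sum(gevK))
}

#' Observed microstate transition percentages
#'
#' Counts ordered pairs of consecutive segments (i to j, i != j) within
#' epochs - never across epoch boundaries - and normalises to percentages.
#'
#' @param segmentation a \linkS4class{MicrostateSegmentation} with at least
#'   one transition.
#' @return a \linkS4class{TransitionTable} (expected part NA; fill with
#'   \code{\link{expectedTransitions}}).
#' @export
transitionMatrix <- function(segmentation) {
  K <- segmentation@K
  counts <- matrix(0, K, K)
  segCounts <- numeric(K)
  for (e in seq_along(segmentation@labels)) {
    runs <- labelRuns(segmentation@labels[[e]])
    segCounts <- segCounts + tabulate(runs$state, K)
    if (nrow(runs) >= 2L) {
      from <- runs$state[-nrow(runs)]
      to <- runs$state[-1L]
      for (i in seq_along(from))
        counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
    }
  }
  stopIfNot(sum(counts) > 0, "no transitions in the segmentation")
  nm <- segmentation@classNames
  obs <- 100 * counts / sum(counts)
  dimnames(obs) <- list(from = nm, to = nm)
  names(segCounts) <- nm
  new("TransitionTable", observedPct = obs,
      expectedPct = matrix(NA_real_, K, K, dimnames = dimnames(obs)),
      segmentCounts = segCounts, classNames = nm)
}

#' Expected transition percentages under segment-label independence
#'
#' With q_k the segment-count fraction of class k, the independence null
#' predicts expected(i to j) = 100 * q_i q_j / sum over a != b of q_a q_b.
#' An alternative coverage-weighted null (q from coverage) is available.
#'
#' @param x a \linkS4class{TransitionTable} (its segment counts are used and
#'   the expected part filled in) or a named per-class count vector.
#' @param weights "segments" (default) or "coverage"; the latter requires
#'   \code{coverage}.
#' @param coverage per-class coverage percentages for the alternative null.
#' @return a \linkS4class{TransitionTable} with \code{expectedPct} filled.
#' @export
expectedTransitions <- function(x, weights = c("segments", "coverage"),
                                coverage = NULL) {
  weights <- match.arg(weights)
  if (is(x, "TransitionTable")) {
    tab <- x
    q <- x@segmentCounts
  } else {
    q <- x
    K <- length(q)
    nm <- names(q) %||% paste0("T", seq_len(K))
    tab <- new("TransitionTable",
               observedPct = matrix(NA_real_, K, K,
                                    dimnames = list(from = nm, to = nm)),
               expectedPct = matrix(NA_real_, K, K,
                                    dimnames = list(from = nm, to = nm)),
               segmentCounts = q, classNames = nm)
  }
  if (weights == "coverage") {
    stopIfNot(!is.null(coverage), "coverage weights need coverage values")
    q <- coverage
  }
  stopIfNot(sum(q > 0) >= 2, "need at least two classes with segments")
  q <- q / sum(q)
  E <- outer(q, q)
  diag(E) <- 0
  E <- 100 * E / sum(E)
  dimnames(E) <- dimnames(tab@expectedPct)
  tab@expectedPct <- E
  tab
}
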