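# --- Global field power and peak extraction -------------------------------

gfpVector <- function(X) {
  stopIfNot(nrow(X) >= 2, "GFP undefined for single-channel data")
  Xc <- centerChannels(X)
  sqrt(colMeans(Xc^2))
}

#' Global field power
#'
#' GFP(t) = sqrt(mean over channels of (v_c(t) - mean_c v(t))^2), the
#' spatial standard deviation of the instantaneous map, computed per sample
#' within each epoch.
#'
#' @param x an \linkS4class{EpochedData}, a channels x samples matrix, or a
#'   list of such matrices.
#' @param samplingRate required when \code{x} is a matrix or list.
#' @return a \linkS4class{GfpSeries} (peaks not yet detected).
#' @export
#' @examples
#' gfp(matrix(c(2, 0, -2, 0), 4, 1), samplingRate = 250)
gfp <- function(x, samplingRate = NULL) {
  if (is(x, "EpochedData")) {
    vals <- lapply(x@epochs, gfpVector)
    fs <- x@samplingRate
  } else if (is.matrix(x)) {
    vals <- list(gfpVector(x))
    fs <- samplingRate %||% NA_real_
  } else {
    vals <- lapply(x, gfpVector)
    fs <- samplingRate %||% NA_real_
  }
  new("GfpSeries", values = vals,
      peaks = rep(list(integer(0)), length(vals)), samplingRate = fs)
}

#' Detect GFP peaks
#'
#' Strict local maxima of the GFP series within each epoch, at least
#' \code{minDistanceMs} apart; epoch-boundary samples are never peaks. When
#' two candidates of equal height fall within the minimum distance, the
#' earlier sample is kept.
#'
#' @param gfpSeries a \linkS4class{GfpSeries}.
#' @param minDistanceMs minimum peak spacing in ms.
#' @return the \linkS4class{GfpSeries} with the \code{peaks} slot filled.
#' @export
findGfpPeaks <- function(gfpSeries, minDistanceMs = 10) {
  fs <- gfpSeries@samplingRate
  minDist <- max(1L, round(minDistanceMs / 1000 * fs))
  gfpSeries@peaks <- lapply(gfpSeries@values, function(v) {
    n <- length(v)
    if (n < 3L) return(integer(0))
    i <- 2:(n - 1L)
    cand <- i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
    if (!length(cand)) return(integer(0))
    # greedy by descending height, earlier index wins ties
    ord <- cand[order(-v[cand], cand)]
    kept <- integer(0)
    for (p in ord)
      if (!length(kept) || all(abs(kept - p) >= minDist))
        kept <- c(kept, p)
    sort(kept)
  })
  gfpSeries
}

#' Polarity-invariant spatial correlation of two maps
#'
#' Pearson correlation across channels; the absolute value is taken when
#' polarity is ignored (the microstate convention).
#'
#' @param u,v numeric per-channel map vectors on the same channel set.
#' @param ignorePolarity take |r| (default TRUE).
#' @return correlation in [0,1] (or [-1,1] when polarity is respected).
#' @export
spatialCorrelation <- function(u, v, ignorePolarity = TRUE) {
  stopIfNot(length(u) == length(v), "maps must share the channel set")
  stopIfNot(sd(u) > 0 && sd(v) > 0, "zero-variance map")
  r <- cor(u, v)
  if (ignorePolarity) abs(r) else r
}

# Extract GFP-peak maps from epoched data: channels x nPeaks matrix.
collectPeakMaps <- function(epochedData, minDistanceMs = 10,
                            maxPeaks = Inf) {
  g <- findGfpPeaks(gfp(epochedData), minDistanceMs)
  cols <- list()
  for (e in seq_along(epochedData@epochs)) {
    p <- g@peaks[[e]]
    if (length(p))
      cols[[length(cols) + 1L]] <- epochedData@epochs[[e]][, p, drop = FALSE]
  }
  stopIfNot(length(cols) > 0, "no GFP peaks found")
  V <- do.call(cbind, cols)
  if (is.finite(maxPeaks) && ncol(V) > maxPeaks) {
    keep <- round(seq(1L, ncol(V), length.out = maxPeaks))
    V <- V[, keep, drop = FALSE]
  }
  V
}

# --- AAHC ----------------------------------------------------------------

#' Atomize and Agglomerate Hierarchical Clustering of topographic maps
#'
#' Polarity-invariant AAHC: every map starts as a singleton cluster; the
#' cluster contributing least global explained variance is repeatedly
#' dissolved ("atomized") and each orphaned member reassigned to the
#' surviving cluster whose template it correlates best with (absolute
#' spatial correlation); affected templates are then recomputed; the
#' procedure stops at \code{k} clusters. A cluster's template is the first
#' principal direction of its member maps, which is invariant to member
#' sign and scale. Exact GEV ties atomize the lowest cluster index first;
#' assignment ties go to the lowest cluster index.
#'
#' @param peakMaps channels x n matrix of maps (typically GFP-peak maps).
#' @param k target number of clusters.
#' @param source identifier stored in the returned template set.
#' @return list with \code{templates} (a \linkS4class{TemplateSet}, labels
#'   "unassigned", GEV diagnostics filled) and \code{assignment} (integer
#'   cluster index per input map).
#' @export
aahcCluster <- function(peakMaps, k = 4L, source = "subject") {
  V <- centerChannels(as.matrix(peakMaps))
  C <- nrow(V); n <- ncol(V)
  stopIfNot(k >= 1, "k must be >= 1")
  stopIfNot(k <= n, "k exceeds the number of maps")
  # cluster state: scatter matrices, templates (unit, centered), lambda =
  # leading eigenvalue = C * (GEV numerator contribution of the cluster)
  members <- lapply(seq_len(n), function(i) i)
  scat <- vector("list", n)
  tmpl <- matrix(0, C, n)
  lam <- numeric(n)
  for (i in seq_len(n)) {
    v <- V[, i]
    scat[[i]] <- tcrossprod(v)
    tmpl[, i] <- unitNorm(v)
    lam[i] <- sum(v^2)
  }
  alive <- rep(TRUE, n)
  principal <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    list(vec = e$vectors[, 1], val = e$values[1])
  }
  while (sum(alive) > k) {
    idxAlive <- which(alive)
    worst <- idxAlive[which.min(lam[idxAlive])]
    alive[worst] <- FALSE
    rest <- which(alive)
    orphans <- members[[worst]]
    # assignment with templates frozen at their pre-atomization state
    corrs <- abs(crossprod(tmpl[, rest, drop = FALSE],
                           V[, orphans, drop = FALSE]))
    dest <- rest[apply(corrs, 2, which.max)]
    touched <- unique(dest)
    for (j in seq_along(orphans)) {
      d <- dest[j]; o <- orphans[j]
      members[[d]] <- c(members[[d]], o)
      scat[[d]] <- scat[[d]] + tcrossprod(V[, o])
    }
    for (d in touched) {
      pr <- principal(scat[[d]])
      tmpl[, d] <- unitNorm(pr$vec)
      lam[d] <- pr$val
    }
    members[[worst]] <- integer(0)
  }
  keep <- which(alive)
  assignment <- integer(n)
  for (j in seq_along(keep)) assignment[members[[keep[j]]]] <- j
  maps <- tmpl[, keep, drop = FALSE]
  colnames(maps) <- paste0("T", seq_along(keep))
  fit <- gevFit(V, assignment, maps)
  ts <- new("TemplateSet", maps = maps,
            channelNames = rownames(peakMaps) %||%
              sprintf("E%02d", seq_len(C)),
            labels = rep("unassigned", length(keep)),
            gevTotal = fit$total, gevPerClass = fit$perClass,
            source = source)
  list(templates = ts, assignment = assignment)
}

#' Global explained variance of a labelling
#'
#' GEV = sum_t (GFP(t) * corr(v_t, T_label(t)))^2 / sum_t GFP(t)^2, with
#' polarity-invariant correlation; also returns the per-class decomposition
#' (which sums to the total).
#'
#' @param maps channels x n matrix of maps.
#' @param labels integer template index per map (1..K).
#' @param templates channels x K matrix of unit-norm templates (or a
#'   \linkS4class{TemplateSet}).
#' @return list with \code{total} and \code{perClass}.
#' @export
gevFit <- function(maps, labels, templates) {
  if (is(templates, "TemplateSet")) templates <- templates@maps
  V <- centerChannels(as.matrix(maps))
  C <- nrow(V)
  K <- ncol(templates)
  stopIfNot(all(labels >= 1 & labels <= K), "labels out of template range")
  g2 <- colSums(V^2) / C           # GFP^2
  den <- sum(g2)
  stopIfNot(den > 0, "all-zero GFP")
  Tc <- apply(templates, 2, function(u) unitNorm(u - mean(u)))
  num <- numeric(K)
  for (kk in seq_len(K)) {
    sel <- which(labels == kk)
    if (length(sel))
      # GFP * corr = (v . T) / sqrt(C) for centered v and unit centered T
      num[kk] <- sum((crossprod(Tc[, kk], V[, sel, drop = FALSE]))^2) / C
  }
  list(total = sum(num) / den, perClass = num / den)
}

# --- Group aggregation ----------------------------------------------------

# Best permutation and signs aligning maps (C x K) to a reference (C x K),
# maximizing sum of squared spatial correlations; exhaustive over K!.
bestPermutation <- function(maps, ref) {
  K <- ncol(ref)
  R <- matrix(0, K, K) # R[i, j] = corr(ref_i, map_j)
  for (i in seq_len(K)) for (j in seq_len(K))
    R[i, j] <- cor(ref[, i], maps[, j])
  perms <- allPermutations(K)
  sc <- apply(perms, 1, function(p) sum(R[cbind(seq_len(K), p)]^2))
  best <- perms[which.max(sc), ]
  signs <- sign(R[cbind(seq_len(K), best)])
  signs[signs == 0] <- 1
  list(perm = best, signs = signs, score = max(sc))
}

#' Align subject template sets by permutation and polarity
#'
#' Iteratively aligns each subject's K maps to the running group mean: the
#' permutation (exhaustive over K!) and per-map signs maximizing the summed
#' squared spatial correlation are applied, the mean is recomputed from the
#' aligned maps, and the loop repeats until the mean changes by less than
#' 1e-6 (or 100 iterations).
#'
#' @param templateSets list of \linkS4class{TemplateSet}s with identical K
#'   and channel sets.
#' @return list of aligned \linkS4class{TemplateSet}s (same order).
#' @export
alignSubjectMaps <- function(templateSets) {
  stopIfNot(length(templateSets) >= 1, "empty group")
  K <- ncol(templateSets[[1]]@maps)
  ch <- templateSets[[1]]@channelNames
  for (ts in templateSets)
    stopIfNot(identical(ts@channelNames, ch) && ncol(ts@maps) == K,
              "inconsistent channel sets or K across subjects")
  if (length(templateSets) == 1L) return(templateSets)
  mapsList <- lapply(templateSets, function(ts) ts@maps)
  ref <- mapsList[[1]]
  for (iter in seq_len(100L)) {
    aligned <- lapply(mapsList, function(M) {
      b <- bestPermutation(M, ref)
      M[, b$perm, drop = FALSE] %*% diag(b$signs, K)
    })
    newRef <- Reduce(`+`, aligned) / length(aligned)
    newRef <- apply(newRef, 2, function(v) unitNorm(v - mean(v)))
    if (max(abs(newRef - ref)) < 1e-6) { ref <- newRef; break }
    ref <- newRef
  }
  out <- vector("list", length(templateSets))
  for (s in seq_along(templateSets)) {
    b <- bestPermutation(mapsList[[s]], ref)
    ts <- templateSets[[s]]
    ts@maps <- mapsList[[s]][, b$perm, drop = FALSE] %*% diag(b$signs, K)
    colnames(ts@maps) <- colnames(templateSets[[s]]@maps)
    ts@labels <- ts@labels[b$perm]
    if (length(ts@gevPerClass) == K) ts@gevPerClass <- ts@gevPerClass[b$perm]
    out[[s]] <- ts
  }
  out
}

#' Group mean templates from aligned subject sets
#'
#' Per class, averages the polarity-reconciled subject maps (signs matched
#' to the first subject) and renormalises to unit norm.
#'
#' @param alignedSets list of aligned \linkS4class{TemplateSet}s (from
#'   \code{\link{alignSubjectMaps}}).
#' @param source identifier for the resulting set.
#' @return a \linkS4class{TemplateSet} (GEV slots NA; fill by backfitting).
#' @export
groupMeanTemplates <- function(alignedSets, source = "group") {
  stopIfNot(length(alignedSets) >= 1, "empty group")
  K <- ncol(alignedSets[[1]]@maps)
  anchor <- alignedSets[[1]]@maps
  acc <- matrix(0, nrow(anchor), K)
  for (ts in alignedSets) {
    M <- ts@maps
    for (kk in seq_len(K)) {
      s <- sign(sum(M[, kk] * anchor[, kk]))
      if (s == 0) s <- 1
      acc[, kk] <- acc[, kk] + s * M[, kk]
    }
  }
  acc <- acc / length(alignedSets)
  maps <- apply(acc, 2, function(v) unitNorm(v - mean(v)))
  colnames(maps) <- colnames(anchor)
  new("TemplateSet", maps = maps,
      channelNames = alignedSets[[1]]@channelNames,
      labels = rep("unassigned", K), gevTotal = NA_real_,
      gevPerClass = numeric(0), source = source)
}

#' Label templates against the canonical A-D archetypes
#'
#' Finds the one-to-one assignment of the four templates to the archetype
#' classes maximizing the total absolute spatial correlation (exhaustive
#' over the 24 permutations), reorders the templates to A, B, C, D and
#' reports the per-class correlations.
#'
#' @param templates a \linkS4class{TemplateSet} with K = 4.
#' @param archetypes a \linkS4class{TemplateSet} of archetype maps (e.g.
#'   \code{\link{canonicalArchetypes}}); labels define the class names.
#' @return list with \code{templates} (relabelled, reordered
#'   \linkS4class{TemplateSet}) and \code{correlations} (named |r| per
#'   class).
#' @export
labelCanonical <- function(templates, archetypes) {
  A <- archetypes@maps
  M <- templates@maps
  K <- ncol(A)
  stopIfNot(ncol(M) == K, "template count must match archetypes")
  R <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    R[i, j] <- abs(cor(A[, i], M[, j]))
  perms <- allPermutations(K)
  sc <- apply(perms, 1, function(p) sum(R[cbind(seq_len(K), p)]))
  best <- perms[which.max(sc), ] # best[i] = template assigned to class i
  ts <- templates
  ts@maps <- M[, best, drop = FALSE]
  colnames(ts@maps) <- archetypes@labels
  ts@labels <- archetypes@labels
  if (length(ts@gevPerClass) == K) ts@gevPerClass <- ts@gevPerClass[best]
  corrs <- R[cbind(seq_len(K), best)]
  names(corrs) <- archetypes@labels
  list(templates = ts, correlations = corrs)
}

#' Derive a subject's template set from epoched data
#'
#' Convenience wrapper: collects GFP-peak maps and runs AAHC.
#'
#' @param epochedData an \linkS4class{EpochedData}.
#' @param k number of clusters (default 4).
#' @param minDistanceMs GFP-peak spacing in ms.
#' @param maxPeaks optional cap on the number of peak maps (evenly
#'   subsampled); \code{Inf} uses all peaks.
#' @param source identifier for the set.
#' @return a \linkS4class{TemplateSet}.
#' @export
subjectTemplates <- function(epochedData, k = 4L, minDistanceMs = 10,
                             maxPeaks = Inf, source = "subject") {
  V <- collectPeakMaps(epochedData, minDistanceMs, maxPeaks)
  rownames(V) <- epochedData@channelNames
  aahcCluster(V, k = k, source = source)$templates
}
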