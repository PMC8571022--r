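# --- FIR design and zero-phase application -------------------------------
#
# All filtering uses linear-phase windowed-sinc FIR kernels applied by
# convolution with reflection padding and exact group-delay compensation,
# i.e. zero-phase overall. Kernel length follows the Hamming-window rule
# taps ~ 3.3 * fs / transition_bandwidth.

# Lowpass windowed-sinc kernel, cutoff fc in Hz, unity DC gain, odd length.
firLowpass <- function(fc, fs, taps, window = c("hamming", "kaiser"),
                       beta = 5) {
  window <- match.arg(window)
  if (taps %% 2L == 0L) taps <- taps + 1L
  m <- (taps - 1L) / 2L
  n <- seq(-m, m)
  h <- 2 * fc / fs * sinc(2 * fc / fs * n)
  w <- if (window == "hamming") 0.54 + 0.46 * cos(pi * n / m)
  else besselI0(beta * sqrt(pmax(0, 1 - (n / m)^2))) / besselI0(beta)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

besselI0 <- function(x) besselI(x, 0)

# Zero-phase FIR filtering of each row of X with an odd symmetric kernel:
# reflection padding, FFT convolution, exact delay trim.
applyFirZeroPhase <- function(X, h) {
  if (is.null(dim(X))) X <- matrix(X, 1L)
  m <- (length(h) - 1L) / 2L
  S <- ncol(X)
  pad <- min(m, S - 1L)
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[S] - x[S - (1:pad)])
    y <- fftConvolve(xp, h)
    out[i, ] <- y[(m + pad + 1L):(m + pad + S)]
  }
  out
}

# Linear convolution via FFT; returns full length(x)+length(h)-1 result.
fftConvolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                     stats::fft(c(h, numeric(nf - length(h)))),
                     inverse = TRUE)) / nf
  y[seq_len(n)]
}

appendProv <- function(recording, entry) {
  recording@provenance <- c(recording@provenance, list(entry))
  recording
}

# --- Operations -----------------------------------------------------------

#' Polyphase anti-aliased resampling
#'
#' Resamples to \code{targetRate} by rational-factor polyphase filtering
#' (upsample by p, Kaiser-windowed-sinc lowpass, downsample by q). The new
#' sample count is \code{floor(n * targetRate / samplingRate)}.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param targetRate new sampling rate in Hz; must not exceed the current
#'   rate.
#' @return the resampled \linkS4class{EEGRecording}.
#' @export
resampleRecording <- function(recording, targetRate) {
  fs <- recording@samplingRate
  stopIfNot(targetRate > 0, "target rate must be positive")
  stopIfNot(targetRate <= fs, "upsampling is not supported")
  if (abs(targetRate - fs) < 1e-12) return(recording)
  scale <- 1e3
  a <- round(targetRate * scale); b <- round(fs * scale)
  g <- gcdInt(a, b)
  p <- a %/% g; q <- b %/% g
  S <- ncol(recording@data)
  nOut <- floor(S * targetRate / fs)
  half <- 10L * max(p, q)
  # cutoff min(fs/2, target/2), designed at the upsampled rate fs*p
  h <- firLowpass(fc = fs * min(p, q) / (2 * q), fs = fs * p,
                  taps = 2L * half + 1L, window = "kaiser", beta = 5) * p
  m <- half
  pad <- ceiling(m / p) + 1L
  X <- recording@data
  out <- matrix(0, nrow(X), nOut)
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[S] - x[S - (1:pad)])
    up <- numeric(length(xp) * p)
    up[seq(1L, length(up), by = p)] <- xp
    y <- fftConvolve(up, h)
    # sample j of output sits at upsampled index (j-1)*q + 1 relative to x[1]
    base <- m + pad * p
    idx <- base + (seq_len(nOut) - 1L) * q + 1L
    out[i, ] <- y[idx]
  }
  rec <- new("EEGRecording", data = out, samplingRate = targetRate,
             channelNames = recording@channelNames,
             channelPositions = recording@channelPositions,
             provenance = recording@provenance)
  appendProv(rec, list(step = "resample", from = fs, to = targetRate))
}

gcdInt <- function(a, b) if (b == 0) a else gcdInt(b, a %% b)

#' Band-pass plus notch filtering
#'
#' Zero-phase FIR band-pass (difference of two unity-gain windowed-sinc
#' lowpass kernels, so DC is removed exactly) followed by a band-stop notch
#' (spectral inversion of a band-pass around the line frequency).
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param low,high band-pass edges in Hz.
#' @param notch line frequency in Hz (NULL to skip).
#' @param transWidth transition bandwidth in Hz at the low edge.
#' @param notchWidth full notch width in Hz.
#' @return the filtered \linkS4class{EEGRecording}.
#' @export
bandpassNotch <- function(recording, low = 1, high = 40, notch = 50,
                          transWidth = 1, notchWidth = 2) {
  fs <- recording@samplingRate
  stopIfNot(low < high && high < fs / 2, "band invalid for sampling rate")
  taps <- ceiling(3.3 * fs / transWidth)
  if (taps %% 2L == 0L) taps <- taps + 1L
  hLow <- firLowpass(high, fs, taps)
  hHigh <- firLowpass(low, fs, taps)
  hBand <- hLow - hHigh # exact zero DC gain: both kernels sum to 1
  X <- applyFirZeroPhase(recording@data, hBand)
  if (!is.null(notch) && notch < fs / 2) {
    tapsN <- ceiling(3.3 * fs / (notchWidth / 2))
    if (tapsN %% 2L == 0L) tapsN <- tapsN + 1L
    hN <- firLowpass(notch + notchWidth / 2, fs, tapsN) -
      firLowpass(notch - notchWidth / 2, fs, tapsN)
    hStop <- -hN
    hStop[(tapsN + 1L) / 2L] <- hStop[(tapsN + 1L) / 2L] + 1
    X <- applyFirZeroPhase(X, hStop)
  }
  rec <- new("EEGRecording", data = X, samplingRate = fs,
             channelNames = recording@channelNames,
             channelPositions = recording@channelPositions,
             provenance = recording@provenance)
  appendProv(rec, list(step = "bandpass_notch", low = low, high = high,
                       notch = notch))
}

#' Detect bad channels
#'
#' Flags channels by three criteria, mirroring common automated raw-data
#' cleaning: (i) \emph{flatline} - any constant run (successive differences
#' below 1e-10 uV) lasting at least \code{flatlineS} seconds; (ii)
#' \emph{noise} - robust z-score of the channel's high-frequency noise level
#' (scaled MAD of the second difference) across channels above
#' \code{noiseSD}, with the cross-channel scale floored at 5\% of the median
#' level so near-identical channels cannot produce spurious outliers; (iii)
#' \emph{correlation} - the channel's Pearson correlation with its
#' leave-one-out spherical-spline prediction from the remaining channels
#' falls below \code{minCorr} in the majority of 1-s windows (a channel
#' carrying signal unrelated to the rest of the montage cannot be
#' reconstructed from it).
#'
#' @param recording an \linkS4class{EEGRecording}, at least \code{flatlineS}
#'   seconds long.
#' @param flatlineS maximum tolerated flatline duration in seconds.
#' @param noiseSD robust z threshold for the noise criterion.
#' @param minCorr minimum acceptable correlation with the spatial
#'   prediction.
#' @return data.frame with columns \code{channel} and \code{reasons}
#'   (comma-separated); zero rows when the recording is clean.
#' @export
detectBadChannels <- function(recording, flatlineS = 5, noiseSD = 4,
                              minCorr = 0.8) {
  X <- recording@data
  fs <- recording@samplingRate
  C <- nrow(X); S <- ncol(X)
  stopIfNot(S >= flatlineS * fs, "recording shorter than flatline criterion")
  reasons <- vector("list", C)
  # flatline
  minRun <- flatlineS * fs
  for (i in seq_len(C)) {
    flat <- abs(diff(X[i, ])) < 1e-10
    if (any(flat)) {
      r <- rle(flat)
      if (any(r$values & (r$lengths + 1L) >= minRun))
        reasons[[i]] <- c(reasons[[i]], "flatline")
    }
  }
  # noise: robust per-channel noise level as the scaled MAD of the second
  # difference (quasi-stable topographic signal is piecewise smooth, so its
  # second difference is sparse and the MAD sees mostly sensor noise),
  # z-scored across channels with the scale floored at 5% of the median
  # level so near-identical channels cannot produce spurious outliers
  nl <- apply(X, 1, function(x) mad(diff(x, differences = 2L)))
  scale <- max(mad(nl), 0.05 * median(nl), 1e-24)
  z <- (nl - median(nl)) / scale
  for (i in which(z > noiseSD)) reasons[[i]] <- c(reasons[[i]], "noise")
  # correlation with leave-one-out spherical-spline prediction, 1-s windows;
  # a second pass drops first-pass bad channels from the predictor set so a
  # single bad channel cannot drag its neighbours below the criterion
  corrBad <- function(predictors) {
    W <- looSplineWeights(recording@channelPositions,
                          predictors = predictors)
    pred <- W %*% X
    nw <- floor(S / fs)
    below <- matrix(FALSE, C, nw)
    for (w in seq_len(nw)) {
      idx <- ((w - 1L) * fs + 1L):(w * fs)
      for (i in seq_len(C)) {
        sx <- sd(X[i, idx]); sp <- sd(pred[i, idx])
        r <- if (sx < 1e-12 || sp < 1e-12) 0
        else cor(X[i, idx], pred[i, idx])
        below[i, w] <- r < minCorr
      }
    }
    rowMeans(below) > 0.5
  }
  cb <- corrBad(seq_len(C))
  bad1 <- unique(c(which(lengths(reasons) > 0), which(cb)))
  if (length(bad1) && C - length(bad1) >= 4L)
    cb <- corrBad(setdiff(seq_len(C), bad1))
  for (i in which(cb)) reasons[[i]] <- c(reasons[[i]], "correlation")
  bad <- which(lengths(reasons) > 0)
  if (C - length(bad) < 4L)
    stop("fewer than 4 good channels remain: unusable recording",
         call. = FALSE)
  data.frame(channel = recording@channelNames[bad],
             reasons = vapply(reasons[bad], paste, "", collapse = ","),
             stringsAsFactors = FALSE)
}

# Leave-one-out spherical-spline prediction weights: row i reconstructs
# channel i from the remaining channels in `predictors`.
looSplineWeights <- function(positions, m = 4, reg = 1e-5, nmax = 50,
                             predictors = seq_len(nrow(positions))) {
  C <- nrow(positions)
  W <- matrix(0, C, C)
  for (i in seq_len(C)) {
    g <- setdiff(predictors, i)
    ng <- length(g)
    Ggg <- sphericalG(tcrossprod(positions[g, , drop = FALSE]), m, nmax)
    Gbg <- sphericalG(positions[i, , drop = FALSE] %*%
                        t(positions[g, , drop = FALSE]), m, nmax)
    A <- rbind(cbind(Ggg + diag(reg, ng), rep(1, ng)),
               c(rep(1, ng), 0))
    Wt <- cbind(Gbg, 1) %*% solve(A)
    W[i, g] <- Wt[1, seq_len(ng)]
  }
  W
}

# Legendre polynomials P_1..P_nmax at x (vector), by recurrence.
legendreTable <- function(x, nmax) {
  P <- matrix(0, length(x), nmax)
  P[, 1] <- x
  if (nmax >= 2) P[, 2] <- 0.5 * (3 * x^2 - 1)
  if (nmax >= 3) for (n in 3:nmax)
    P[, n] <- ((2 * n - 1) * x * P[, n - 1] - (n - 1) * P[, n - 2]) / n
  P
}

# Spherical-spline kernel g_m(cos angle) (Perrin et al. style), stiffness m.
sphericalG <- function(cosang, m = 4, nmax = 50) {
  P <- legendreTable(pmin(1, pmax(-1, as.numeric(cosang))), nmax)
  n <- seq_len(nmax)
  coef <- (2 * n + 1) / (n * (n + 1))^m
  matrix(P %*% coef / (4 * pi), nrow = nrow(as.matrix(cosang)))
}

#' Spherical-spline interpolation of bad channels
#'
#' Rebuilds the flagged channels from the good ones with spherical-spline
#' interpolation (stiffness m = 4, Legendre expansion to order 50,
#' regularisation 1e-5). Good channels are untouched; each interpolated
#' channel is a fixed linear combination of the good channels.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param badChannels character vector of channel names (or the data.frame
#'   from \code{\link{detectBadChannels}}); may be empty.
#' @param m spline stiffness.
#' @param reg diagonal regularisation.
#' @param nLegendre expansion order.
#' @return the repaired \linkS4class{EEGRecording}.
#' @export
interpolateSpherical <- function(recording, badChannels, m = 4, reg = 1e-5,
                                 nLegendre = 50) {
  if (is.data.frame(badChannels)) badChannels <- badChannels$channel
  if (length(badChannels) == 0L) return(recording)
  bad <- match(badChannels, recording@channelNames)
  stopIfNot(!anyNA(bad), "unknown bad channel name")
  good <- setdiff(seq_len(nrow(recording@data)), bad)
  stopIfNot(length(good) > 0, "all channels bad")
  P <- recording@channelPositions
  Ggg <- sphericalG(tcrossprod(P[good, , drop = FALSE]), m, nLegendre)
  Gbg <- sphericalG(P[bad, , drop = FALSE] %*% t(P[good, , drop = FALSE]),
                    m, nLegendre)
  g <- length(good)
  A <- rbind(cbind(Ggg + diag(reg, g), rep(1, g)), c(rep(1, g), 0))
  Ainv <- solve(A)
  Wfull <- cbind(Gbg, rep(1, length(bad))) %*% Ainv
  # columns 1..g of Ainv map the data part of the RHS; the constraint RHS is 0
  Wt <- Wfull[, seq_len(g), drop = FALSE]
  X <- recording@data
  X[bad, ] <- Wt %*% X[good, , drop = FALSE]
  rec <- new("EEGRecording", data = X, samplingRate = recording@samplingRate,
             channelNames = recording@channelNames, channelPositions = P,
             provenance = recording@provenance)
  appendProv(rec, list(step = "interpolate_spherical",
                       channels = recording@channelNames[bad]))
}

#' Average referencing
#'
#' Subtracts the cross-channel mean from every sample, so each column of the
#' data sums to zero. Idempotent.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @return the re-referenced \linkS4class{EEGRecording}.
#' @export
rereferenceAverage <- function(recording) {
  rec <- new("EEGRecording", data = centerChannels(recording@data),
             samplingRate = recording@samplingRate,
             channelNames = recording@channelNames,
             channelPositions = recording@channelPositions,
             provenance = recording@provenance)
  appendProv(rec, list(step = "rereference_average"))
}

#' Reject high-amplitude windows
#'
#' Splits the recording into consecutive \code{windowS}-second windows,
#' calibrates per-channel robust RMS statistics (median and MAD) on the
#' cleanest quartile of windows (ranked by worst-channel RMS), and excises
#' every window whose worst channel exceeds median + \code{sdCut} robust
#' SDs. Remaining data are concatenated; the cut positions are recorded so
#' later epoching never spans a discontinuity.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param windowS window length in seconds.
#' @param sdCut rejection threshold in robust SDs; \code{Inf} disables
#'   rejection.
#' @return list with \code{recording} (trimmed, provenance carries the break
#'   positions) and \code{mask} (matrix of removed start/end times in
#'   seconds, zero rows when clean).
#' @export
rejectArtifactWindows <- function(recording, windowS = 0.5, sdCut = 20) {
  X <- recording@data
  fs <- recording@samplingRate
  S <- ncol(X)
  w <- round(windowS * fs)
  stopIfNot(S >= w, "recording shorter than one window")
  nw <- floor(S / w)
  rms <- matrix(0, nrow(X), nw)
  for (j in seq_len(nw)) {
    idx <- ((j - 1L) * w + 1L):(j * w)
    rms[, j] <- sqrt(rowMeans(X[, idx, drop = FALSE]^2))
  }
  keepWin <- rep(TRUE, nw)
  if (is.finite(sdCut)) {
    worst <- apply(rms, 2, max)
    calib <- which(worst <= quantile(worst, 0.25))
    med <- apply(rms[, calib, drop = FALSE], 1, median)
    sc <- pmax(apply(rms[, calib, drop = FALSE], 1, mad), 0.01 * med, 1e-12)
    bad <- colSums(rms > med + sdCut * sc) > 0
    keepWin <- !bad
  }
  if (mean(keepWin) < 0.5)
    stop("more than half of all windows rejected: unusable recording",
         call. = FALSE)
  if (all(keepWin)) {
    mask <- matrix(numeric(0), 0, 2,
                   dimnames = list(NULL, c("start", "end")))
    rec <- appendProv(recording, list(step = "reject_windows",
                                      windowS = windowS, sdCut = sdCut,
                                      breaks = integer(0), mask = mask))
    return(list(recording = rec, mask = mask))
  }
  keepIdx <- unlist(lapply(which(keepWin), function(j)
    ((j - 1L) * w + 1L):(j * w)))
  tail <- if (nw * w < S) (nw * w + 1L):S else integer(0)
  keepIdx <- c(keepIdx, tail)
  drop <- which(!keepWin)
  mask <- cbind(start = (drop - 1L) * w / fs, end = drop * w / fs)
  # breaks: positions (in the new index) after which a cut occurred
  kept <- sort(keepIdx)
  gap <- which(diff(kept) > 1L)
  rec <- new("EEGRecording", data = X[, kept, drop = FALSE],
             samplingRate = fs, channelNames = recording@channelNames,
             channelPositions = recording@channelPositions,
             provenance = recording@provenance)
  rec <- appendProv(rec, list(step = "reject_windows", windowS = windowS,
                              sdCut = sdCut, breaks = gap, mask = mask))
  list(recording = rec, mask = mask)
}

#' Cut a recording into fixed-length epochs
#'
#' Non-overlapping consecutive epochs of \code{epochS} seconds. Epochs never
#' span a rejection cut (the recording is split into continuous chunks at
#' the break positions recorded by \code{\link{rejectArtifactWindows}});
#' remainders shorter than one epoch are discarded.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param epochS epoch length in seconds.
#' @return an \linkS4class{EpochedData}; it is an error if no epoch fits.
#' @export
epochRecording <- function(recording, epochS = 2) {
  fs <- recording@samplingRate
  ns <- round(epochS * fs)
  S <- ncol(recording@data)
  breaks <- integer(0)
  mask <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  for (pr in recording@provenance) {
    if (identical(pr$step, "reject_windows")) {
      breaks <- pr$breaks
      mask <- pr$mask
    }
  }
  bounds <- c(0L, breaks, S)
  eps <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k] + 1L; b <- bounds[k + 1L]
    nE <- (b - a + 1L) %/% ns
    for (e in seq_len(nE)) {
      idx <- (a + (e - 1L) * ns):(a + e * ns - 1L)
      eps[[length(eps) + 1L]] <- recording@data[, idx, drop = FALSE]
    }
  }
  stopIfNot(length(eps) > 0, "no epochs produced")
  new("EpochedData", epochs = eps, epochLength = epochS, samplingRate = fs,
      channelNames = recording@channelNames, rejectedWindows = mask)
}

#' Full preprocessing chain
#'
#' Runs the fixed pipeline order: resample, band-pass + notch, bad-channel
#' detection and spherical interpolation, average reference, window
#' rejection, optional plug-in cleaner, epoching.
#'
#' @param recording raw \linkS4class{EEGRecording}.
#' @param targetRate,low,high,notch,flatlineS,noiseSD,minCorr,windowS,sdCut,epochS
#'   stage thresholds (defaults: 250 Hz; 1-40 Hz; 50 Hz; 5 s; 4 SD; 0.8;
#'   0.5 s; 20 SD; 2 s).
#' @param cleaner optional function \code{EEGRecording -> EEGRecording}
#'   applied between window rejection and epoching (hook for external
#'   artifact removal such as ICA).
#' @return list with \code{epochs} (\linkS4class{EpochedData}),
#'   \code{badChannels}, \code{mask} and \code{log} (per-stage summary,
#'   including the proportion of interpolated channels).
#' @export
preprocessRecording <- function(recording, targetRate = 250, low = 1,
                                high = 40, notch = 50, flatlineS = 5,
                                noiseSD = 4, minCorr = 0.8, windowS = 0.5,
                                sdCut = 20, epochS = 2, cleaner = NULL) {
  rec <- resampleRecording(recording, targetRate)
  rec <- bandpassNotch(rec, low, high, notch)
  bad <- detectBadChannels(rec, flatlineS, noiseSD, minCorr)
  rec <- interpolateSpherical(rec, bad)
  rec <- rereferenceAverage(rec)
  rej <- rejectArtifactWindows(rec, windowS, sdCut)
  rec <- rej$recording
  if (!is.null(cleaner)) rec <- cleaner(rec)
  ep <- epochRecording(rec, epochS)
  list(epochs = ep, badChannels = bad, mask = rej$mask,
       log = list(nBadChannels = nrow(bad),
                  propBadChannels = 100 * nrow(bad) / nrow(recording@data),
                  nRejectedWindows = nrow(rej$mask),
                  nEpochs = length(ep@epochs)))
}
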