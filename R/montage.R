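#' Quasi-uniform electrode cap layout
#'
#' Returns a deterministic electrode montage: \code{n} unit-sphere positions
#' distributed quasi-uniformly (Fibonacci spiral) over a spherical cap
#' extending 105 degrees from the vertex, the area covered by an extended
#' 10/20-style EEG cap. Coordinates are x (right), y (anterior), z (up).
#' Every routine that needs sensor geometry (spherical-spline interpolation,
#' neighbour prediction, smooth synthetic topographies) accepts explicit
#' positions, so a real digitised montage can be substituted.
#'
#' @param n number of electrodes.
#' @return list with \code{channelNames} (character) and \code{positions}
#'   (n x 3 unit-norm matrix).
#' @export
#' @examples
#' m <- standardMontage(19)
#' range(sqrt(rowSums(m$positions^2)))
standardMontage <- function(n) {
  stopIfNot(n >= 1, "n must be >= 1")
  thetaMax <- 105 * pi / 180
  i <- seq_len(n)
  z <- 1 - (1 - cos(thetaMax)) * (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  az <- i * golden
  pos <- cbind(x = r * cos(az), y = r * sin(az), z = z)
  rownames(pos) <- NULL
  list(channelNames = sprintf("E%02d", i), positions = pos)
}

# k nearest neighbours by great-circle distance; returns for each channel the
# neighbour indices and 1/distance weights (normalised to sum 1).
nearestNeighbours <- function(positions, k = 6L) {
  n <- nrow(positions)
  k <- min(k, n - 1L)
  cosang <- tcrossprod(positions)
  cosang[] <- pmin(1, pmax(-1, cosang))
  d <- acos(cosang)
  lapply(seq_len(n), function(i) {
    ord <- order(d[i, -i])[seq_len(k)]
    idx <- setdiff(seq_len(n), i)[ord]
    w <- 1 / pmax(d[i, idx], 1e-6)
    list(index = idx, weight = w / sum(w))
  })
}

# Smooth spatial basis: low-degree solid harmonics evaluated at electrode
# positions. Real scalp topographies are spatially smooth; restricting maps
# to this basis gives neighbouring electrodes correlated values.
harmonicBasis <- function(positions) {
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  cbind(x, y, z, x * y, x * z, y * z, x^2 - y^2, 3 * z^2 - 1)
}

#' Canonical microstate archetype maps
#'
#' Builds the four idealised class archetypes used to label templates A-D:
#' A and B are the two mirrored diagonal gradients (left-posterior to
#' right-anterior and its mirror image), C is an anterior-posterior gradient,
#' and D a fronto-central focal extreme. All maps are synthesised as smooth
#' fields on the given montage, average-referenced and unit-normalised.
#'
#' @param positions n x 3 unit-norm electrode positions.
#' @param channelNames channel names (defaults to E01..).
#' @return a \linkS4class{TemplateSet} labelled A, B, C, D.
#' @export
canonicalArchetypes <- function(positions,
                                channelNames = sprintf("E%02d",
                                                       seq_len(nrow(positions)))) {
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  a <- (x + y) / sqrt(2)          # right-anterior vs left-posterior diagonal
  b <- (-x + y) / sqrt(2)         # mirrored diagonal
  cc <- y                         # anterior-posterior axis
  fc <- c(0, 0.45, 0.893)        # fronto-central point (unit norm)
  fc <- fc / sqrt(sum(fc^2))
  d <- exp(-rowSums(sweep(positions, 2, fc)^2) / (2 * 0.5^2))
  maps <- apply(cbind(a, b, cc, d), 2, function(v) unitNorm(v - mean(v)))
  colnames(maps) <- c("A", "B", "C", "D")
  new("TemplateSet", maps = maps, channelNames = channelNames,
      labels = c("A", "B", "C", "D"), gevTotal = NA_real_,
      gevPerClass = numeric(0), source = "canonical")
}
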