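#' @importFrom methods new validObject is slot slotNames show
#' @importFrom stats median mad sd cor rnorm runif rgeom quantile
NULL

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. All randomness in the package funnels through
# this so that a seed in a config reproduces results exactly.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-subject seed from a master seed; keeps values < 2^31.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + index * 7919) %% 2147483647L)
}

# Center a vector (or each column of a matrix) across channels.
centerChannels <- function(x) {
  if (is.matrix(x)) sweep(x, 2L, colMeans(x), "-") else x - mean(x)
}

# Unit L2 norm; leaves exact-zero vectors untouched.
unitNorm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n > 0) v / n else v
}

stopIfNot <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# All permutations of 1..n (n small; n = 4 -> 24 rows).
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}
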