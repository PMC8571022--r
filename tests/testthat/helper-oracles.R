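# Independent oracles, written as direct transcriptions of the definitions
# and kept free of the package's internal helpers.

# Naive AAHC: recomputes every template and every GEV contribution from
# scratch each round, straight from the definitions.
naiveAAHC <- function(V, k) {
  V <- sweep(V, 2, colMeans(V))
  clusters <- lapply(seq_len(ncol(V)), function(i) i)
  templateOf <- function(members) {
    M <- V[, members, drop = FALSE]
    svd(M)$u[, 1]
  }
  while (length(clusters) > k) {
    tmpl <- lapply(clusters, templateOf)
    contrib <- vapply(seq_along(clusters), function(j) {
      sum(vapply(clusters[[j]], function(t) {
        v <- V[, t]
        gfp <- sqrt(mean((v - mean(v))^2))
        (gfp * abs(cor(v, tmpl[[j]])))^2
      }, 0))
    }, 0)
    worst <- which.min(contrib)
    orphans <- clusters[[worst]]
    clusters <- clusters[-worst]
    tmpl <- tmpl[-worst]
    for (o in orphans) {
      rs <- vapply(tmpl, function(tj) abs(cor(V[, o], tj)), 0)
      d <- which.max(rs)
      clusters[[d]] <- c(clusters[[d]], o)
    }
  }
  assignment <- integer(ncol(V))
  for (j in seq_along(clusters)) assignment[clusters[[j]]] <- j
  assignment
}

samePartition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 0))]),
            unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 0))]))
}

# Closed-form two-sample pooled t.
oracleT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * stats::pt(-abs(t), nx + ny - 2))
}

# Closed-form Pearson r with t-based p.
oraclePearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Closed-form OLS slope with t-based p.
oracleSlope <- function(y, x) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  t <- b / se
  list(beta = b, se = se, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

# Mann-Whitney U of x by direct pair counting.
oracleU <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# Holm step-down by hand.
oracleHolm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}
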