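# Independent oracles used to cross-check the implementation.

# all-pairs weighted shortest paths, Floyd-Warshall, edge length = 1/weight
fwDistances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracleGlobalEfficiency <- function(w) {
  n <- nrow(w)
  if (n < 2 || all(w == 0)) return(0)
  d <- fwDistances(w)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

# exhaustive simple-path enumeration: shortest path by trying every
# intermediate-node ordering (feasible for <= 6 nodes)
enumShortestPath <- function(w, i, j) {
  n <- nrow(w)
  best <- Inf
  visit <- function(node, seen, len) {
    if (len >= best) return(invisible())
    if (node == j) { best <<- len; return(invisible()) }
    for (nxt in seq_len(n)) {
      if (!seen[nxt] && w[node, nxt] > 0)
        visit(nxt, `[<-`(seen, nxt, TRUE), len + 1 / w[node, nxt])
    }
  }
  visit(i, `[<-`(rep(FALSE, n), i, TRUE), 0)
  best
}

oracleGlobalEfficiencyEnum <- function(w) {
  n <- nrow(w)
  if (n < 2 || all(w == 0)) return(0)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      d <- enumShortestPath(w, i, j)
      tot <- tot + if (is.finite(d)) 1 / d else 0
    }
  tot / (n * (n - 1) / 2)
}

oracleLocalEfficiency <- function(w) {
  n <- nrow(w)
  if (n == 0) return(0)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracleGlobalEfficiency(w[nb, nb, drop = FALSE])
  }, 1.0))
}

randomWeightedGraph <- function(n, pEdge = 0.6) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[runif(length(up)) < pEdge]
  w[on] <- runif(length(on), 0.05, 1)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w
}

# two-hemisphere toy network definitions for cohort simulations
toyNetworks <- function(nA = 10, nB = 8) {
  mk <- function(name, n) {
    half <- n / 2
    NetworkDefinition(name, data.frame(
      id = sprintf("%s_%s%d", name, rep(c("L", "R"), each = half),
                   rep(seq_len(half), 2)),
      hemisphere = rep(c("L", "R"), each = half),
      region = name))
  }
  list(mk("netA", nA), mk("netB", nB))
}

# textbook formula oracles for the classical tests
oraclePairedT <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

oracleTwoSampleT <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

oracleChiSquare <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chisq = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE))
}

# partial correlation via the inverse of the full correlation matrix
oraclePartialCorrelation <- function(x, y, covariates) {
  m <- cbind(x, y, covariates)
  p <- solve(cor(m))
  -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
}

# sinusoid amplitude via projection onto sin/cos at the known frequency
toneAmplitude <- function(x, freqHz, tr) {
  t <- (seq_along(x) - 1) * tr
  s <- sin(2 * pi * freqHz * t); c <- cos(2 * pi * freqHz * t)
  2 * sqrt(mean(x * s)^2 + mean(x * c)^2)
}
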