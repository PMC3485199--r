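withr_tempfile <- function() {
  withr::local_tempfile(.local_envir = parent.frame())
}

# Independent brute-force oracles. These deliberately re-derive each
# quantity along a different code path (explicit loops, stats::lm, manual
# set arithmetic) from the implementation they check.

# Brute-force tricube weighted-least-squares local-linear smooth: same
# neighbourhood contract (q = ceiling(span * n), min 2, distance ties broken
# by earlier time), fitted with stats::lm at every evaluation point.
oracleLoess <- function(times, values, span = 0.5) {
  obs <- which(!is.na(values))
  n <- length(obs)
  out <- rep(NA_real_, length(values))
  if (n < 4 || span * n < 2) return(out)
  q <- max(2, ceiling(span * n))
  for (i in obs) {
    d <- abs(times[obs] - times[i])
    ord <- order(d, times[obs])
    sel <- ord[1:q]
    dmax <- max(d[sel])
    w <- (1 - (d[sel] / dmax)^3)^3
    df <- data.frame(x = times[obs][sel] - times[i], y = values[obs][sel])
    fit <- stats::lm(y ~ x, data = df, weights = w)
    out[i] <- unname(stats::predict(fit, newdata = data.frame(x = 0)))
  }
  out
}

# Brute-force permutation p-value for the cosinor r^2, using stats::lm per
# permutation and the same seeded shuffle stream the implementation draws.
oraclePermP <- function(times, values, period, nPerm, seed) {
  keep <- !is.na(values)
  t <- times[keep]; y <- values[keep]
  r2of <- function(yy) {
    fit <- stats::lm(yy ~ cos(2 * pi * t / period) +
                       sin(2 * pi * t / period))
    tss <- sum((yy - mean(yy))^2)
    if (tss < 1e-12) 0 else max(0, 1 - sum(residuals(fit)^2) / tss)
  }
  obs <- r2of(y)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  hits <- 0
  for (k in seq_len(nPerm)) {
    if (r2of(y[sample.int(length(y))]) >= obs) hits <- hits + 1
  }
  (1 + hits) / (1 + nPerm)
}

# Plain breadth-first search returning all nodes within `steps` of `from`
# on an edge list (two-column character matrix).
oracleBfsNodes <- function(edges, from, steps) {
  frontier <- from
  seen <- from
  for (s in seq_len(steps)) {
    nxt <- character(0)
    for (v in frontier) {
      nxt <- c(nxt, edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
    }
    frontier <- setdiff(unique(nxt), seen)
    seen <- union(seen, frontier)
  }
  sort(seen)
}

# random ExpressionTimeCourse fixture
randomCourse <- function(nGenes, times, seed, experimentId = "exp",
                         missingFrac = 0) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
      globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    v <- matrix(rnorm(nGenes * length(times)), nGenes,
                dimnames = list(sprintf("G%03d", seq_len(nGenes)), NULL))
    if (missingFrac > 0)
      v[runif(length(v)) < missingFrac] <- NA
    expressionTimeCourse(v, times, experimentId)
  })
}

# random simple undirected graph fixture as an edge matrix
randomEdges <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- runif(nrow(idx)) < p
  cbind(nodes[idx[pick, 1]], nodes[idx[pick, 2]])
}
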