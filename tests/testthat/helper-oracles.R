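# Independent oracles and small fixtures, kept deliberately naive: straight
# loops and closed forms, no reuse of package internals.

# brute-force frame rule: scan all frames against the extremes
bruteForcePhase <- function(g, band = 0.30) {
  gmin <- min(g)
  gmax <- max(g)
  r <- gmax - gmin
  out <- character(length(g))
  for (t in seq_along(g)) {
    if (g[t] <= gmin + band * r) {
      out[t] <- "expiratory"
    } else if (g[t] >= gmax - band * r) {
      out[t] <- "inspiratory"
    } else {
      out[t] <- "excluded"
    }
  }
  out
}

# brute-force fixed-bin histogram: per-value loop over bins
bruteForceHistogram <- function(values, edges) {
  counts <- numeric(length(edges) - 1)
  out <- 0L
  for (v in values) {
    placed <- FALSE
    for (b in seq_len(length(counts))) {
      last <- b == length(counts)
      if (v >= edges[b] && (v < edges[b + 1] || (last && v <= edges[b + 1]))) {
        counts[b] <- counts[b] + 1
        placed <- TRUE
        break
      }
    }
    if (!placed) out <- out + 1L
  }
  list(weights = if (sum(counts) > 0) counts / sum(counts) else counts,
       outOfRange = out)
}

# closed-form simple least squares
olsOracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  yhat <- mean(y) + b * (x - mean(x))
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = b, r2 = r2)
}

# n uniform points on the 3-simplex
randomSimplex <- function(n) {
  e <- matrix(stats::rexp(3 * n), nrow = 3)
  sweep(e, 2, colSums(e), "/")
}

# compact phantom spec for fast tests
tinySpec <- function(...) {
  args <- utils::modifyList(list(dim = c(24L, 32L, 6L), seed = 11L), list(...))
  do.call(PhantomSpec, args)
}

# FractionMaps from raw arrays (test-side constructor)
makeFractions <- function(gas, tissue, blood, mask = array(TRUE, dim(gas)),
                          spacing = c(0.5, 0.5, 5)) {
  new("FractionMaps", gas = gas, tissue = tissue, blood = blood,
      mask = mask, residual = array(0, dim(gas)), spacing = spacing,
      projected = TRUE)
}
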