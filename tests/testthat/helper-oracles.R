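# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths (and the stats shortcuts they call).

# Upper-tail hypergeometric probability by exhaustive enumeration: draw every
# size-n subset of 1..N, mark 1..K, count draws with >= k marked.
enum_hypergeom_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)
  mean(marked >= k)
}

# KS enrichment by materializing the full running-sum curve over all n
# positions, rather than the closed-form extrema over the t hit positions.
brute_ks <- function(V, n) {
  t <- length(V)
  hit <- seq_len(n) %in% V
  Fi <- cumsum(hit) / t                # F(i), i = 1..n
  F_prev <- c(0, Fi[-n])               # F(i-1)
  i <- seq_len(n)
  a <- max(Fi - i / n)
  b <- max(i / n - F_prev)
  if (a > b) a else -b
}

# UPGMA by direct recursion on a distance matrix: repeatedly merge the
# closest pair at height = their distance, recomputing cluster distances as
# size-weighted averages. Returns the sorted merge heights.
brute_upgma_heights <- function(d) {
  d <- as.matrix(d)
  sizes <- rep(1L, nrow(d))
  active <- seq_len(nrow(d))
  heights <- numeric(0)
  while (length(active) > 1L) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    i <- active[ij[1L]]; j <- active[ij[2L]]
    heights <- c(heights, d[i, j])
    # merged cluster reuses slot i with weighted-average distances
    for (m in setdiff(active, c(i, j))) {
      d[i, m] <- d[m, i] <-
        (sizes[i] * d[i, m] + sizes[j] * d[j, m]) / (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# minimum / maximum attainable PWM window score over all 4^L sequences
brute_pwm_extrema <- function(log_odds) {
  L <- ncol(log_odds)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- apply(grid, 1, function(b) sum(log_odds[cbind(b, seq_len(L))]))
  c(min = min(scores), max = max(scores))
}
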