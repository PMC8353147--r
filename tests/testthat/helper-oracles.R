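# Independent reference implementations ("oracles") used to check the
# package's own code paths. These stay definitional and slow on purpose.

# Two-sided Pearson t-test p-value by numeric integration of the t density.
pvalue_integrate_oracle <- function(r, n) {
  if (r == 0) return(1)
  t <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::integrate(function(x) stats::dt(x, df = n - 2), t, Inf,
                       rel.tol = 1e-13, abs.tol = 0)$value
}

# Literal step-up Benjamini-Hochberg: sort ascending, q_(i) = min_{j>=i}
# p_(j) * m / j capped at 1, mapped back by explicit loops.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    qs[i] <- min(1, best)
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

# Definitional UPGMA: recompute every mean inter-cluster distance from the
# ORIGINAL matrix at each step; same tie-break rule as the implementation
# (lowest original index first).
upgma_oracle <- function(D) {
  key_less <- function(k1, k2) {
    if (k1[1] < k2[1] - 1e-12) return(TRUE)
    if (k1[1] > k2[1] + 1e-12) return(FALSE)
    if (k1[2] != k2[2]) return(k1[2] < k2[2])
    k1[3] < k2[3]
  }
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  codes <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      h <- mean(D[clusters[[a]], clusters[[b]]])
      ma <- min(clusters[[a]]); mb <- min(clusters[[b]])
      key <- c(h, min(ma, mb), max(ma, mb))
      if (is.null(best) || key_less(key, best$key))
        best <- list(a = a, b = b, h = h, key = key)
    }
    a <- best$a; b <- best$b
    if (min(clusters[[b]]) < min(clusters[[a]])) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(codes[a], codes[b])
    height[step] <- best$h
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    codes[a] <- step
    clusters[[b]] <- NULL
    codes <- codes[-b]
  }
  list(merge = merge, height = height)
}

random_dist_matrix <- function(k) {
  d <- matrix(0, k, k)
  d[upper.tri(d)] <- runif(k * (k - 1) / 2, 0.05, 2)
  d + t(d)
}
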