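# Independent brute-force oracles used to validate the implementations.

# two-sided Fisher exact p by full enumeration over the hypergeometric
# support of 2x2 tables with fixed margins
fisher_p_enumeration <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# O(n^3) topological overlap from an adjacency matrix
tom_bruteforce <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  dimnames(tom) <- dimnames(a)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# mutual ranks recomputed directly from a correlation matrix
mr_bruteforce <- function(cc) {
  n <- nrow(cc)
  mr <- matrix(NA_real_, n, n, dimnames = dimnames(cc))
  rank_of <- function(i, j) {
    others <- setdiff(seq_len(n), i)
    vals <- cc[i, others]
    rank(-vals)[match(j, others)]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) mr[i, j] <- sqrt(rank_of(i, j) * rank_of(j, i))
    }
  }
  mr
}

# Holm step-down adjustment from first principles
holm_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[ord])
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# adjusted Rand index between two partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- sa * sb / n2
  (sij - exp_idx) / ((sa + sb) / 2 - exp_idx)
}
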