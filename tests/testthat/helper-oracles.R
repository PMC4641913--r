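# Independent oracle implementations used to check the package's
# computations. These deliberately take the slow, direct route (explicit
# summation, brute force) and share no code with the implementation.

# Two-sided exact p-value by direct summation of the conditional
# distribution: given the total n = x + y, the count in library 2 follows
# Binomial(n, N2/(N1+N2)) under the null. Probabilities are accumulated
# from individual log-space pmf terms.
oracle_exact_pvalue <- function(x, y, N1, N2) {
  n <- x + y
  pr <- N2 / (N1 + N2)
  j <- 0:n
  logpmf <- lchoose(n, j) + j * log(pr) + (n - j) * log1p(-pr)
  pmf <- exp(logpmf)
  lower <- sum(pmf[j <= y])
  upper <- sum(pmf[j >= y])
  min(1, 2 * min(lower, upper))
}

# Brute-force Benjamini-Hochberg step-up: literal minimum over j >= i of
# p_(j) * n / j, evaluated with an explicit double loop.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    m <- Inf
    for (j in i:n) m <- min(m, ps[j] * n / j)
    q[i] <- min(1, m)
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Hypergeometric upper tail P(X >= k) by explicit summation of the pmf
# choose(K, j) choose(N-K, n-j) / choose(N, n).
oracle_hyper_upper <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Pearson correlation straight from the covariance formula.
oracle_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Adjusted Rand index from the contingency-table formula.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}

# Transitive ancestors by brute-force repeated expansion of the edge list.
oracle_ancestors <- function(term, edges) {
  anc <- character(0)
  frontier <- term
  repeat {
    parents <- unique(edges$parent[edges$child %in% frontier])
    new <- setdiff(parents, anc)
    if (length(new) == 0) break
    anc <- c(anc, new)
    frontier <- new
  }
  sort(anc)
}
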