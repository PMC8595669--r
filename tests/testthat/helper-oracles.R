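# Shared fixtures and independent oracles used across the suite.

# adjusted Rand index (closed form on the contingency table)
ari <- function(a, b) {
  t <- table(a, b)
  n <- sum(t)
  sij <- sum(choose(t, 2))
  si <- sum(choose(rowSums(t), 2))
  sj <- sum(choose(colSums(t), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# brute-force O/E: divide every entry by the mean of its own diagonal,
# computed pair by pair
oracle_oe <- function(counts, mask = integer()) {
  n <- nrow(counts)
  un <- setdiff(seq_len(n), mask)
  out <- matrix(0, n, n)
  for (i in un) for (j in un) {
    d <- abs(i - j)
    vals <- c()
    for (k in un) if ((k + d) <= n && (k + d) %in% un)
      vals <- c(vals, counts[k, k + d])
    e <- mean(vals)
    out[i, j] <- if (e > 0) counts[i, j] / e else 0
  }
  out
}

# elementwise Pearson correlation by the direct formula
oracle_pearson <- function(X) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- X[i, ]; y <- X[j, ]
    out[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
  }
  out
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# assignments of the pooled ranks to group 1 (no ties assumed)
oracle_wilcoxon <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- rank(c(x, y))
  w_obs <- sum(pooled[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2L, function(ix) sum(seq_len(nx + ny)[ix]) -
                nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

# symmetric positive random matrix
random_symmetric <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n, 1, 10), n, n)
  (A + t(A)) / 2
}

# decay-law matrix counts = c * d^(-a), diagonal = c
decay_matrix <- function(n, a = 1, c = 100) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  c * pmax(d, 1)^(-a)
}
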