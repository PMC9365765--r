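# Independent brute-force oracles, kept free of the package's own code paths.

# all set partitions of n elements as integer label vectors (restricted growth)
set_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_id) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (c in seq_len(next_id)) rec(c(labels, c), max(next_id, c + 1L))
  }
  rec(integer(0), 1L)
  out
}

# cell-by-cell Pearson chi-squared, plain double loop
chi2_oracle <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      total <- total + (tab[i, j] - e)^2 / e
    }
  }
  total
}

cramers_v_oracle <- function(tab) {
  tab <- as.matrix(tab)
  sqrt((chi2_oracle(tab) / sum(tab)) / (min(dim(tab)) - 1))
}

# exact two-sided Mann-Whitney p-value by enumerating all group assignments
mw_exact_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_of <- function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, (m / i) * p[ord[i]])
    q_sorted[i] <- running
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# exact upper-tail hypergeometric probability from binomial coefficients
hyper_oracle <- function(N, B, n, b) {
  ks <- b:min(B, n)
  sum(choose(B, ks) * choose(N - B, n - ks)) / choose(N, n)
}

# Welch t statistic and Welch-Satterthwaite df from the textbook formulas
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t_stat, df = df)
}

# adjusted Rand index between two label vectors, from the pair-counting form
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(sum(tab), 2)
  maxi <- (sum_i + sum_j) / 2
  (sum_ij - expected) / (maxi - expected)
}
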