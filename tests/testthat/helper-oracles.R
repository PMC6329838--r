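# Independent brute-force oracles used to validate the implementation.

# BH step-up rule applied literally: adj_(i) = min_{j >= i} m * p_(j) / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# upper-tail hypergeometric by direct summation of the pmf
hyper_upper_brute <- function(q, m, t, k) {
  j <- q:min(m, k)
  if (q > min(m, k)) return(0)
  sum(choose(m, j) * choose(t - m, k - j)) / choose(t, k)
}

# TOM by the defining triple loop
tom_brute <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exact conditional NB test by exhaustive enumeration of all t + 1 splits
nb_exact_brute <- function(sum_a, sum_b, n_a, n_b, phi) {
  t <- sum_a + sum_b
  if (t == 0) return(1)
  y <- 0:t
  mu_a <- t * n_a / (n_a + n_b)
  mu_b <- t - mu_a
  pr <- if (phi < 1e-12) {
    dpois(y, mu_a) * dpois(t - y, mu_b)
  } else {
    dnbinom(y, size = n_a / phi, mu = mu_a) *
      dnbinom(t - y, size = n_b / phi, mu = mu_b)
  }
  pr <- pr / sum(pr)
  p_obs <- pr[sum_a + 1]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# longest ORF by walking codons from every ATG occurrence
orf_brute <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- 0L
  for (i in seq_len(max(0, n - 2))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i
    while (j + 2 <= n) {
      cod <- substr(s, j, j + 2)
      if (j > i && cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2 - i + 1)
        break
      }
      j <- j + 3
    }
  }
  as.integer(best)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
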