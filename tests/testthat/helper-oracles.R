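# Independent brute-force oracles: literal term-by-term transcriptions of the
# published metric formulas, written with explicit loops and no shared code
# with the package implementation. They exist so every metric can be checked
# against a second, naive derivation on small repertoires.

o_mean_freq <- function(p) {
  s <- 0
  for (pi in p) s <- s + pi
  s / length(p)
}

o_geo_mean_freq <- function(p) {
  prod <- 1
  for (pi in p) prod <- prod * pi
  prod^(1 / length(p))
}

o_mean_len <- function(len, p) {
  s <- 0
  for (i in seq_along(p)) s <- s + len[i] * p[i]
  s
}

o_convergence <- function(nt, aa) {
  total <- 0
  for (a in unique(aa)) total <- total + length(unique(nt[aa == a]))
  total / length(unique(aa))
}

o_spectratype <- function(len, p) {
  out <- numeric(0)
  for (L in sort(unique(len))) out[as.character(L)] <- sum(p[len == L])
  out
}

o_pielou_clonality <- function(p) {
  n <- length(p)
  if (n == 1) return(1)
  s <- 0
  for (pi in p) s <- s + pi * log(pi)
  1 + s / log(n)
}

o_clonal_proportion <- function(p, percent) {
  p <- sort(p, decreasing = TRUE)
  cum <- 0
  for (k in seq_along(p)) {
    cum <- cum + p[k]
    if (cum >= percent / 100 - 1e-12) return(k)
  }
  length(p)
}

o_shannon_wiener <- function(p) {
  H <- 0
  for (pi in p) H <- H - pi * log(pi)
  exp(H)
}

o_norm_shannon_wiener <- function(p) o_shannon_wiener(p) / log(length(p))

o_simpson_D <- function(p) {
  D <- 0
  for (pi in p) D <- D + pi^2
  D
}

o_d50 <- function(counts) {
  counts <- sort(counts, decreasing = TRUE)
  total <- sum(counts)
  cum <- 0
  for (k in seq_along(counts)) {
    cum <- cum + counts[k]
    if (cum >= total / 2) return(100 * k / length(counts))
  }
}

o_chao1 <- function(counts) {
  S <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  est <- S + f1 * (f1 - 1) / (2 * (f2 + 1))
  v <- if (f2 > 0)
    f2 * (0.5 * (f1 / f2)^2 + (f1 / f2)^3 + 0.25 * (f1 / f2)^4)
  else NA_real_
  c(est, v)
}

o_gini_coefficient <- function(p) {
  p <- sort(p)
  n <- length(p)
  lorenz_x <- (0:n) / n
  lorenz_y <- c(0, cumsum(p))
  area <- 0
  for (i in 1:n)
    area <- area + (lorenz_x[i + 1] - lorenz_x[i]) *
      (lorenz_y[i] + lorenz_y[i + 1]) / 2
  (0.5 - area) / 0.5
}

o_usage <- function(labels, p, weighted) {
  out <- numeric(0)
  for (g in sort(unique(labels))) {
    out[g] <- if (weighted) sum(p[labels == g]) else
      sum(labels == g) / length(labels)
  }
  out
}

# Naive quadratic-scan overlap: compares every row of a with every row of b
# on the key fields.
o_overlap <- function(a, b, key_fields, alpha = 0.5, beta = 0.5) {
  same_key <- function(i, k) {
    for (f in key_fields) if (a[[f]][i] != b[[f]][k]) return(FALSE)
    TRUE
  }
  shared_a <- integer(0); shared_b <- integer(0)
  for (i in seq_len(nrow(a))) {
    for (k in seq_len(nrow(b))) {
      if (same_key(i, k)) {
        shared_a <- c(shared_a, i)
        shared_b <- c(shared_b, k)
      }
    }
  }
  d_i <- nrow(a); d_j <- nrow(b); d_ij <- length(shared_a)
  X <- sum(a$count); Y <- sum(b$count)
  x <- a$count[shared_a]; y <- b$count[shared_b]
  fx <- a$freq[shared_a]; fy <- b$freq[shared_b]
  mh <- if (d_ij == 0) 0 else
    2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
  cosine <- if (d_ij == 0) 0 else
    sum(fx * fy) / (sqrt(sum(fx^2)) * sqrt(sum(fy^2)))
  pearson <- if (d_ij < 2 || sd(fx) == 0 || sd(fy) == 0) NA_real_ else
    cor(fx, fy)
  list(
    morisita_horn = mh,
    jaccard = d_ij / (d_i + d_j - d_ij),
    overlap_coeff = d_ij / min(d_i, d_j),
    tversky = d_ij / (alpha * (d_i - d_ij) + beta * (d_j - d_ij) + d_ij),
    cosine = cosine,
    pearson = pearson,
    rel_overlap_div = d_ij / (d_i * d_j),
    geo_mean_overlap_freq = sqrt(sum(fx) * sum(fy)),
    clonewise_geo_sum = sum(sqrt(fx * fy))
  )
}

o_jsd <- function(P, Q) {
  M <- (P + Q) / 2
  kl <- function(p, m) {
    s <- 0
    for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log2(p[i] / m[i])
    s
  }
  0.5 * kl(P, M) + 0.5 * kl(Q, M)
}

o_kmers <- function(seqs, k, weights = rep(1, length(seqs))) {
  out <- numeric(0)
  for (s in seq_along(seqs)) {
    seq <- seqs[s]
    if (nchar(seq) < k) next
    for (start in 1:(nchar(seq) - k + 1)) {
      kmer <- substr(seq, start, start + k - 1)
      out[kmer] <- (if (is.na(out[kmer])) 0 else out[kmer]) + weights[s]
    }
  }
  out
}
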