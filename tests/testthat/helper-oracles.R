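# Independently coded brute-force oracles. These re-derive each quantity
# from first principles (direct summation, enumeration, textbook formulas)
# and deliberately share no code with the package implementations.

# Audic-Claverie conditional mass p(y | x) summed term by term in log space,
# with the same larger-normalized-count conditioning convention as the
# package's two-sided test.
oracle_ac_mass <- function(yy, x, n1, n2) {
  r <- n2 / n1
  exp(yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
        (x + yy + 1) * log(1 + r))
}

oracle_ac <- function(x, y, n1, n2) {
  if (x / n1 < y / n2) {
    tmp <- x; x <- y; y <- tmp
    tmp <- n1; n1 <- n2; n2 <- tmp
  }
  lower <- sum(oracle_ac_mass(0:y, x, n1, n2))
  # upper tail: sum upward from y until terms vanish
  upper <- 0
  yy <- y
  repeat {
    term <- oracle_ac_mass(yy, x, n1, n2)
    upper <- upper + term
    yy <- yy + 1
    if (term < upper * 1e-17 && yy > y + 10) break
    if (yy > y + 1e6) break
  }
  min(1, 2 * min(lower, upper))
}

# Textbook Benjamini-Hochberg step-up: monotonized m * p_(i) / i from the
# largest p downward.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  prev <- 1
  for (idx in seq_along(o)) {
    i <- o[idx]
    rank_i <- m - idx + 1
    prev <- min(prev, m * p[i] / rank_i)
    q[i] <- prev
  }
  q
}

# Hypergeometric upper tail by direct enumeration of the mass function.
oracle_hyper <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Pearson correlation from the covariance / standard deviation formula.
oracle_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Mid-ranks (ties averaged) computed by definition, then Pearson on ranks.
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# Venn region counts by looping over every non-empty tissue subset and
# counting genes whose presence pattern matches it exactly.
oracle_venn <- function(calls) {
  tissues <- colnames(calls)
  T <- length(tissues)
  out <- integer(0)
  for (code in 1:(2^T - 1)) {
    members <- as.logical(bitwAnd(code, 2^(seq_len(T) - 1)))
    n <- 0
    for (g in seq_len(nrow(calls)))
      if (all(calls[g, ] == members)) n <- n + 1
    out[paste(tissues[members], collapse = "&")] <- n
  }
  out
}
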