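# Independent reference implementations used to cross-check the package.
# Deliberately share no code with the package: permutations come from
# index-tuple filtering, Fisher from explicit hypergeometric tail sums,
# KS from an ECDF sweep, BH from the literal step-up construction.

all_perms_oracle <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  ok <- rep(TRUE, nrow(grid))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- ok & grid[, i] != grid[, j]
    }
  }
  grid[ok, , drop = FALSE]
}

rho_d2_oracle <- function(x, y) {          # tie-free classical formula
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

spearman_exact_p_oracle <- function(x, y) {
  P <- all_perms_oracle(length(x))
  obs <- rho_d2_oracle(x, y)
  rho_all <- vapply(seq_len(nrow(P)), function(i) {
    rho_d2_oracle(x, y[P[i, ]])
  }, numeric(1))
  mean(abs(rho_all) >= abs(obs) - 1e-12)
}

step_up_oracle <- function(p, m) {
  o <- order(p)
  q <- p[o] * m / seq_along(p)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

fisher_oracle <- function(a, b, c, d) {
  # two-sided Fisher: sum of probabilities of all tables with the same
  # margins whose probability does not exceed the observed table's
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  pr <- vapply(support, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  sum(pr[pr <= pr[support == a] * (1 + 1e-7)])
}

ks_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g),
                 numeric(1))))
}

overlap_oracle <- function(sites, track) {
  sum(vapply(seq_len(nrow(sites)), function(i) {
    s <- sites$pos[i]; e <- s + 2L
    any(track$chrom == sites$chrom[i] & track$start < e & track$end > s)
  }, logical(1)))
}
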