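# Independent brute-force oracles, written with different machinery than the
# package: permutations filtered out of the full n^n index grid (Spearman)
# and direct combn scans computing rank sums from scratch (Mann-Whitney).

# every permutation of 1..n as the rows of expand.grid(n^n tuples) that
# visit each index once -- brute force, independent of the package machinery
grid_permutations <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  perms <- grid_permutations(length(y))
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

brute_mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  stat <- function(idx) {
    ua <- sum(r[idx]) - n1 * (n1 + 1) / 2
    min(ua, n1 * n2 - ua)
  }
  obs <- stat(seq_len(n1))
  all_u <- apply(combn(n1 + n2, n1), 2, stat)
  list(U = obs, p = mean(all_u <= obs + 1e-12))
}
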