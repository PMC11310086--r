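# Independent oracles used across the suite. These deliberately re-derive
# quantities with plain loops / direct summation, not via the package code.

# adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  s <- function(x) sum(choose(x, 2))
  expected <- s(rowSums(tab)) * s(colSums(tab)) / choose(n, 2)
  (s(tab) - expected) / ((s(rowSums(tab)) + s(colSums(tab))) / 2 - expected)
}

# brute-force TMM: same published rule, coded independently with loops
oracle_tmm <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  prop <- sweep(counts, 2, lib, "/")
  f75 <- apply(prop, 2, quantile, 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    if (s == ref) { f[s] <- 1; next }
    m <- a <- w <- c()
    for (g in seq_len(nrow(counts))) {
      if (counts[g, s] > 0 && counts[g, ref] > 0) {
        po <- counts[g, s] / lib[s]; pr <- counts[g, ref] / lib[ref]
        m <- c(m, log2(po / pr))
        a <- c(a, 0.5 * log2(po * pr))
        w <- c(w, (lib[s] - counts[g, s]) / (lib[s] * counts[g, s]) +
                 (lib[ref] - counts[g, ref]) / (lib[ref] * counts[g, ref]))
      }
    }
    if (!length(m) || max(abs(m)) < 1e-6) { f[s] <- 1; next }
    n <- length(m)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * abs_trim) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    f[s] <- 2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f / exp(mean(log(f)))
}

# exact hypergeometric tails by direct summation of point masses
oracle_hyper_enrich <- function(k, K, n, M) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(M - K, n - xs)) / choose(M, n)
}
oracle_hyper_deplete <- function(k, K, n, M) {
  xs <- max(0, n + K - M):k
  sum(choose(K, xs) * choose(M - K, n - xs)) / choose(M, n)
}

# exact upper binomial tail by direct summation
oracle_binom_tail <- function(k, n, p) {
  xs <- k:n
  sum(choose(n, xs) * p^xs * (1 - p)^(n - xs))
}

# textbook Benjamini-Hochberg step-up adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# all permutations of a vector (n small)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# hard truth assignment for one species of a simulated time course
truth_hard <- function(sim, sp) {
  tr <- sim$truth$gene_clusters
  tr <- tr[tr$species == sp, ]
  setNames(paste0("C", tr$cluster), tr$gene_id)
}
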