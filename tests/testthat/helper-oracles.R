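# Independent oracles and small fixtures used across the suite. Each oracle
# is a deliberately naive implementation (brute force, enumeration, direct
# formula) kept separate from the package's computation path.

# Brute-force Poisson threshold: scan v upward until the exact tail sum
# drops below alpha.
brute_poisson_threshold <- function(lambda, alpha = 0.05) {
  v <- 1
  repeat {
    tail <- 1 - sum(stats::dpois(0:(v - 1), lambda))
    if (tail < alpha) return(v)
    v <- v + 1
  }
}

# Exhaustive modularity search: enumerate every set partition of the nodes
# (restricted growth strings) and return the maximal Q.
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (c in seq_len(k + 1)) rec(c(assign, c), max(k, c))
  }
  rec(integer(0), 0)
  out
}

# Naive Q evaluated straight from the definition over ordered node pairs.
naive_q <- function(adj, memb) {
  v <- sum(adj)
  if (v == 0) return(0)
  k <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) q <- q + adj[i, j] / v - k[i] * k[j] / v^2
    }
  }
  unname(q)
}

exhaustive_best_q <- function(adj) {
  parts <- all_set_partitions(nrow(adj))
  max(vapply(parts, function(p) naive_q(adj, p), 0))
}

# Rank-then-Pearson Spearman oracle: average ranks computed by hand, then
# the Pearson product-moment formula evaluated directly.
oracle_spearman <- function(x, y) {
  rk <- function(v) {
    # average ranks without calling rank(): position-based with tie groups
    ord <- order(v)
    r <- numeric(length(v))
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[ord[j + 1]] == v[ord[i]]) j <- j + 1
      r[ord[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  rx <- rk(x)
  ry <- rk(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Named adjacency helpers.
named_adj <- function(m) {
  labels <- sprintf("n%02d", seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  m
}

complete_graph <- function(n) {
  m <- matrix(1, n, n)
  diag(m) <- 0
  named_adj(m)
}

two_cliques <- function(k = 3, bridge = FALSE) {
  n <- 2 * k
  m <- matrix(0, n, n)
  m[1:k, 1:k] <- 1
  m[(k + 1):n, (k + 1):n] <- 1
  diag(m) <- 0
  if (bridge) m[k, k + 1] <- m[k + 1, k] <- 1
  named_adj(m)
}

ring_lattice <- function(n = 20, k = 4) {
  m <- matrix(0, n, n)
  for (d in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      m[i, j] <- m[j, i] <- 1
    }
  }
  named_adj(m)
}

er_graph <- function(n, p, seed) {
  m <- matrix(0, n, n)
  set.seed(seed)
  ut <- upper.tri(m)
  m[ut] <- (runif(sum(ut)) < p) + 0
  m <- m + t(m)
  named_adj(m)
}

# Small planted design reused by several files.
tiny_design <- function(seed = 11, ts_length = 64, ...) {
  planted_design(roi_set = 12,
                 true_partition = balanced_partition(roi_set(12), 3),
                 n_subjects = 8, ts_length = ts_length, seed = seed, ...)
}
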