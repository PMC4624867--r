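# independent brute-force oracles used to cross-check the implementation

# weighted clustering coefficient of node i by explicit triple loop
brute_clustering <- function(w, i) {
  n <- nrow(w)
  num <- 0
  den <- 0
  for (k in seq_len(n)) {
    if (k == i) next
    for (l in seq_len(n)) {
      if (l == i || l == k) next
      num <- num + w[i, k] * w[i, l] * w[k, l]
      den <- den + w[i, k] * w[i, l]
    }
  }
  if (den == 0) 0 else num / den
}

# all-pairs shortest path lengths over 1/w edges by enumerating every
# simple path (feasible for n <= 6)
brute_shortest_paths <- function(w) {
  n <- nrow(w)
  len <- function(path) {
    s <- 0
    for (k in seq_len(length(path) - 1)) {
      wij <- w[path[k], path[k + 1]]
      if (wij == 0) return(Inf)
      s <- s + 1 / wij
    }
    s
  }
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  extend <- function(path) {
    i <- path[1]
    j <- path[length(path)]
    best[i, j] <<- min(best[i, j], len(path))
    for (nxt in setdiff(seq_len(n), path)) extend(c(path, nxt))
  }
  for (i in seq_len(n)) extend(i)
  pmin(best, t(best))
}

# exact two-tailed Mann-Whitney p by enumerating all group assignments
perm_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  nm <- n_a * length(b)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n_a * (n_a + 1) / 2
  }
  u_obs <- min(u_stat(seq_len(n_a)), nm - u_stat(seq_len(n_a)))
  combos <- utils::combn(length(pooled), n_a)
  hits <- apply(combos, 2, function(idx) {
    u <- u_stat(idx)
    min(u, nm - u) <= u_obs
  })
  mean(hits)
}

# seeded symmetric all-weighted random graph, weights in [0.05, 1]
make_random_w <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2, 0.05, 1)
  w <- w + t(w)
  rownames(w) <- colnames(w) <- paste0("n", seq_len(n))
  w
}

# pure-tone recording helper
tone_recording <- function(freqs, fs = 250, duration = 10, phases = 0,
                           labels = NULL) {
  t <- seq_len(duration * fs) / fs
  phases <- rep_len(phases, length(freqs))
  m <- t(mapply(function(f, p) cos(2 * pi * f * t + p), freqs, phases))
  if (is.null(labels)) labels <- paste0("ch", seq_along(freqs))
  eeg_recording(m, labels, fs)
}
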