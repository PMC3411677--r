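# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (adjacency hashes, BFS, sparse matrix
# tricks) so they can serve as cross-checks.

# Literal sequential weighted sampling without replacement: draw a pair with
# probability proportional to current weight, zero it, renormalise, repeat.
sequential_draw_oracle <- function(w, l) {
  picked <- integer(l)
  for (t in seq_len(l)) {
    i <- sample.int(length(w), 1L, prob = w)
    picked[t] <- i
    w[i] <- 0
  }
  picked
}

# Local clustering by explicit neighbour-pair enumeration.
clustering_oracle <- function(n, edges, isolates = "zero") {
  adj <- lapply(seq_len(n), function(v)
    sort(unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))))
  has <- function(i, j) any(edges[, 1] == min(i, j) & edges[, 2] == max(i, j))
  ci <- vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(NA_real_)
    cnt <- 0
    for (p in seq_len(k - 1)) for (q in (p + 1):k)
      if (has(nb[p], nb[q])) cnt <- cnt + 1
    cnt / (k * (k - 1) / 2)
  }, numeric(1))
  if (isolates == "zero") mean(ifelse(is.na(ci), 0, ci)) else mean(ci, na.rm = TRUE)
}

# Assortativity straight from the definition: Pearson correlation over the
# 2m ordered edge endpoints.
assortativity_oracle <- function(n, edges) {
  if (nrow(edges) == 0) return(NA_real_)
  k <- tabulate(edges, nbins = n)
  x <- c(k[edges[, 1]], k[edges[, 2]])
  y <- c(k[edges[, 2]], k[edges[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  suppressWarnings(stats::cor(x, y))
}

# Fragmentation by explicit reachability: boolean matrix closure.
fragmentation_oracle <- function(n, edges) {
  reach <- diag(TRUE, n)
  for (e in seq_len(nrow(edges))) {
    reach[edges[e, 1], edges[e, 2]] <- TRUE
    reach[edges[e, 2], edges[e, 1]] <- TRUE
  }
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  1 - (sum(reach) - n) / (n * (n - 1))
}

# Uniform simple random graph on n nodes with m edges (for oracle sweeps).
random_graph <- function(n, m) {
  all_pairs <- t(combn(n, 2))
  all_pairs[sample.int(nrow(all_pairs), m), , drop = FALSE]
}

# Measures of many replicates at one parameter combination.
replicate_measures <- function(reps, seed0, ...) {
  do.call(rbind, lapply(seq_len(reps), function(r)
    network_measures(specnet(..., seed = seed0 + r))))
}
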