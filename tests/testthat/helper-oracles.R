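# Brute-force graph oracles, deliberately independent of igraph: triangle
# enumeration for clustering, BFS level expansion for distances and
# shortest-path counts, and direct pair-by-pair path-fraction sums for
# betweenness. Only feasible for small graphs; used to certify the fast
# implementations exactly.

oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) {
      return(0)
    }
    pairs <- utils::combn(nb, 2)
    mean(a[cbind(pairs[1, ], pairs[2, ])] == 1)
  }, numeric(1))
}

# All-pairs shortest-path distances by breadth-first search from each node.
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- setdiff(which(colSums(a[frontier, , drop = FALSE] == 1) > 0), which(is.finite(d[s, ])))
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

oracle_path_length <- function(a) {
  d <- oracle_distances(a)
  du <- d[upper.tri(d)]
  list(mean = mean(du[is.finite(du)]), n_disconnected_pairs = sum(!is.finite(du)))
}

# Number of shortest paths between every pair, by dynamic programming over
# BFS distance levels.
oracle_nsp <- function(a, d) {
  n <- nrow(a)
  nsp <- matrix(0, n, n)
  diag(nsp) <- 1
  for (s in seq_len(n)) {
    for (dist in seq_len(max(d[s, ][is.finite(d[s, ])]))) {
      for (v in which(d[s, ] == dist)) {
        pred <- which(a[, v] == 1 & d[s, ] == dist - 1)
        nsp[s, v] <- sum(nsp[s, pred])
      }
    }
  }
  nsp
}

oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  nsp <- oracle_nsp(a, d)
  bc <- numeric(n)
  for (j in seq_len(n - 1)) {
    for (k in seq(j + 1, n)) {
      if (!is.finite(d[j, k]) || nsp[j, k] == 0) next
      for (i in seq_len(n)) {
        if (i == j || i == k) next
        if (is.finite(d[j, i]) && is.finite(d[i, k]) && d[j, i] + d[i, k] == d[j, k]) {
          bc[i] <- bc[i] + nsp[j, i] * nsp[i, k] / nsp[j, k]
        }
      }
    }
  }
  bc
}

# Small named graph builders.
path_adj <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  a
}

star_adj <- function(n_leaves) {
  a <- matrix(0L, n_leaves + 1, n_leaves + 1)
  a[1, -1] <- a[-1, 1] <- 1L
  a
}

complete_adj <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}

rand_adj <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# A small residualized-looking morphometry table built from a scenario.
make_test_table <- function(scenario = "planted", seed = 1, n = 35, ...) {
  sc <- morph_scenario(scenario, seed = seed, n_subjects = n, ...)
  residualize(generate_morphometry(sc$high, sc$low, seed = seed))
}
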