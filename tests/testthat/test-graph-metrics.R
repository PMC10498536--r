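test_that("clustering coefficient matches exhaustive neighbor-pair counts", {
  expect_equal(clustering_coefficient(complete_adj(4))$node, rep(1, 4))
  expect_equal(clustering_coefficient(complete_adj(4))$mean, 1)
  expect_equal(clustering_coefficient(star_adj(4))$node, rep(0, 5))

  # triangle A-B-C with pendant D attached to A
  a <- matrix(0L, 4, 4)
  a[1, 2] <- a[2, 1] <- a[1, 3] <- a[3, 1] <- a[2, 3] <- a[3, 2] <- a[1, 4] <- a[4, 1] <- 1L
  cc <- clustering_coefficient(a)
  expect_equal(cc$node, c(1 / 3, 1, 1, 0))
  expect_equal(cc$mean, 7 / 12)
})

test_that("characteristic path length averages finite BFS distances", {
  expect_equal(characteristic_path_length(complete_adj(6))$mean, 1)
  expect_equal(characteristic_path_length(complete_adj(6))$n_disconnected_pairs, 0)
  expect_equal(characteristic_path_length(path_adj(4))$mean, 10 / 6)

  two_triangles <- rbind(
    cbind(complete_adj(3), matrix(0L, 3, 3)),
    cbind(matrix(0L, 3, 3), complete_adj(3))
  )
  lp <- characteristic_path_length(two_triangles)
  expect_equal(lp$mean, 1)
  expect_equal(lp$n_disconnected_pairs, 9)

  expect_error(characteristic_path_length(matrix(0L, 4, 4)), "edgeless")
})

test_that("betweenness counts unordered-pair path fractions through each node", {
  expect_equal(unname(betweenness_centrality(complete_adj(5))), rep(0, 5))
  expect_equal(unname(betweenness_centrality(star_adj(4))), c(6, 0, 0, 0, 0))
  expect_equal(unname(betweenness_centrality(path_adj(5))), c(0, 3, 4, 3, 0))
})

test_that("adjacency validation rejects malformed input", {
  bad <- matrix(0L, 3, 3)
  bad[1, 2] <- 1L
  expect_error(clustering_coefficient(bad), "symmetric")
  loop <- complete_adj(3)
  diag(loop) <- 1L
  expect_error(betweenness_centrality(loop), "diagonal")
})

test_that("fast metrics agree exactly with brute-force oracles on random graphs", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    a <- rand_adj(n, runif(1, 0.2, 0.7))
    expect_equal(clustering_coefficient(a)$node, oracle_clustering(a), tolerance = 1e-12)
    if (sum(a) > 0) {
      o <- oracle_path_length(a)
      l <- characteristic_path_length(a)
      expect_equal(l$mean, o$mean, tolerance = 1e-12)
      expect_equal(l$n_disconnected_pairs, o$n_disconnected_pairs)
    }
    bc <- unname(betweenness_centrality(a))
    obc <- oracle_betweenness(a)
    expect_equal(bc, obc, tolerance = 1e-9)
    # conservation: total betweenness equals the pairwise interior mass
    expect_equal(sum(bc), sum(obc), tolerance = 1e-9)
  }
})

test_that("degree-preserving nulls conserve the degree sequence and reproduce under a seed", {
  tab <- make_test_table(seed = 3, n = 20)
  net <- binarize_at_sparsity(zero_negatives(covariance_matrix(tab, "low")), 0.25)
  a <- net$adjacency
  nulls <- random_networks(a, 5, seed = 7)
  for (r in nulls) {
    expect_equal(sort(rowSums(r)), sort(rowSums(a)))
    expect_equal(sum(r) / 2, sum(a) / 2)
    expect_equal(diag(r), rep(0, nrow(a)), ignore_attr = TRUE)
  }
  expect_identical(random_networks(a, 3, seed = 7)[[3]], nulls[[3]])
  expect_false(identical(nulls[[1]], a)) # swaps actually happened

  expect_warning(k5 <- random_networks(complete_adj(5), 3, seed = 1), "complete")
  expect_equal(k5[[2]], complete_adj(5))
})

test_that("small-worldness is gamma over lambda and sigma > 1 on a Watts-Strogatz ring", {
  set.seed(52)
  ws <- igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 90, 5, 0.1),
    sparse = FALSE
  )
  sw <- small_world(ws, n_random = 50, seed = 53)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)
  # identity against the equivalent cross-ratio form
  expect_equal(
    sw$sigma,
    (sw$clustering * sw$lp_random_mean) / (sw$cp_random_mean * sw$path_length),
    tolerance = 1e-12
  )
  expect_gt(sw$sigma, 1)
})

test_that("an already-random graph has sigma near 1", {
  set.seed(54)
  er <- igraph::as_adjacency_matrix(igraph::sample_gnm(90, 1001), sparse = FALSE)
  sw <- small_world(er, n_random = 50, seed = 55)
  expect_lt(abs(sw$sigma - 1), 0.1)
})

test_that("sigma rises then falls along the ring-lattice rewiring sweep", {
  # a larger ring, so the lattice end has genuinely long paths (lambda >> 1)
  sig_at <- function(p, seed) {
    set.seed(seed)
    a <- igraph::as_adjacency_matrix(igraph::sample_smallworld(1, 300, 5, p), sparse = FALSE)
    small_world(a, n_random = 20, seed = seed + 1)$sigma
  }
  s_low <- sig_at(0.001, 61)
  s_mid <- sig_at(0.05, 62)
  s_high <- sig_at(1.00, 63)
  expect_gt(s_mid, s_low)
  expect_gt(s_mid, s_high)
})

test_that("normalized betweenness has mean one and flags dispersed hubs", {
  expect_equal(normalize_bc(c(2, 2, 2)), c(1, 1, 1))
  star_norm <- normalize_bc(c(6, 0, 0, 0, 0))
  expect_equal(star_norm, c(5, 0, 0, 0, 0))
  set.seed(56)
  x <- runif(30, 0, 10)
  expect_equal(mean(normalize_bc(x)), 1, tolerance = 1e-12)
  expect_error(normalize_bc(rep(0, 4)), "undefined")

  # star: SD = sqrt(5) ~ 2.236, threshold ~ 3.236 -> only the center
  expect_equal(unname(identify_hubs(star_norm)), 1L)
  expect_length(identify_hubs(rep(1, 10)), 0)
  vals <- c(1, 1, 1, 1, 1, 1, 4)
  expect_equal(unname(identify_hubs(vals / mean(vals))), 7L)
})
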