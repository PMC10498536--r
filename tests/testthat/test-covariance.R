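make_tab <- function(vol, cov, group = NULL) morph_table(vol, cov, group)

test_that("residualization orthogonalizes volumes against the covariates", {
  set.seed(41)
  n <- 40
  cov <- data.frame(
    subject_id = paste0("s", 1:n), age = rnorm(n, 22, 3),
    sex = rbinom(n, 1, 0.5), education = rnorm(n, 15, 1.4),
    tiv = rnorm(n, 1550, 150)
  )
  vol <- 0.002 * cov$tiv + matrix(rnorm(n * 6), n, 6) # exact TIV effect + noise
  tab <- residualize(make_tab(vol, cov))
  expect_true(tab$residualized)
  for (j in 1:6) {
    expect_lt(abs(mean(tab$volumes[, j])), 1e-10)
    expect_lt(abs(cor(tab$volumes[, j], cov$tiv)), 1e-10)
    expect_lt(abs(cor(tab$volumes[, j], cov$age)), 1e-10)
  }
})

test_that("residualization is idempotent and invariant to covariate recoding", {
  set.seed(42)
  n <- 30
  cov <- data.frame(
    subject_id = paste0("s", 1:n), age = rnorm(n, 22, 3),
    sex = rbinom(n, 1, 0.5), education = rnorm(n, 15, 1.4),
    tiv = rnorm(n, 1550, 150)
  )
  vol <- matrix(rnorm(n * 5), n, 5) + 0.1 * cov$age
  once <- residualize(make_tab(vol, cov))
  twice <- residualize(once)
  expect_equal(once$volumes, twice$volumes, tolerance = 1e-12)

  cov2 <- cov
  cov2$sex <- cov$sex + 1 # 1/2 coding instead of 0/1
  expect_equal(residualize(make_tab(vol, cov2))$volumes, once$volumes, tolerance = 1e-10)
})

test_that("a collinear covariate design is rejected by name", {
  n <- 20
  cov <- data.frame(
    subject_id = paste0("s", 1:n), age = rnorm(n), sex = 1, # constant: aliased with intercept
    education = rnorm(n), tiv = rnorm(n)
  )
  expect_error(residualize(make_tab(matrix(rnorm(n * 3), n, 3), cov)), "sex")
})

test_that("covariance matrix matches hand-computed Pearson correlations", {
  # 6 subjects x 4 regions, correlations computed by the textbook formula
  set.seed(43)
  vol <- matrix(rnorm(24), 6, 4)
  cov <- data.frame(subject_id = paste0("s", 1:6), age = rnorm(6), sex = rbinom(6, 1, 0.5), education = rnorm(6), tiv = rnorm(6))
  tab <- make_tab(vol, cov)
  tab$residualized <- TRUE # correlate raw columns for this arithmetic check
  net <- covariance_matrix(tab)
  hand_r <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_lt(abs(net$weights[i, j] - hand_r(vol[, i], vol[, j])), 1e-12)
    }
  }
  expect_equal(diag(net$weights), rep(0, 4), ignore_attr = TRUE)
  expect_equal(net$weights, t(net$weights))
})

test_that("duplicated and negated regions give correlations of 1 and -1", {
  set.seed(44)
  x <- rnorm(8)
  vol <- cbind(a = x, b = x, c = -x, d = rnorm(8))
  cov <- data.frame(subject_id = paste0("s", 1:8), age = rnorm(8), sex = 0:1, education = rnorm(8), tiv = rnorm(8))
  tab <- make_tab(vol, cov)
  tab$residualized <- TRUE
  net <- covariance_matrix(tab)
  expect_equal(net$weights["a", "b"], 1)
  expect_equal(net$weights["a", "c"], -1)
})

test_that("zero-variance regions and tiny groups are rejected", {
  vol <- cbind(flat = rep(1, 6), ok = rnorm(6))
  cov <- data.frame(subject_id = paste0("s", 1:6), age = rnorm(6), sex = 0, education = 1, tiv = rnorm(6))
  tab <- make_tab(vol, cov)
  tab$residualized <- TRUE
  expect_error(covariance_matrix(tab), "flat")
  expect_error(covariance_matrix(tab, "high"), "at least 4")
})

test_that("negative weights are zeroed, everything else untouched", {
  set.seed(45)
  w <- matrix(runif(49, -1, 1), 7, 7)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  net <- structure(
    list(labels = paste0("R", 1:7), weights = w, n_subjects = 10, group = "all"),
    class = "cov_network"
  )
  z <- zero_negatives(net)
  expect_true(all(z$weights >= 0))
  expect_equal(z$weights[w >= 0], w[w >= 0])
  expect_true(all(z$weights[w < 0] == 0))
  expect_equal(z$n_negative_zeroed, sum(w < 0))
})

test_that("binarization keeps exactly floor(S * E_max) strongest edges", {
  # 4-node toy, brute-force ranking of all 6 pairs
  w <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  w["A", "B"] <- w["B", "A"] <- 0.9
  w["A", "C"] <- w["C", "A"] <- 0.8
  w["A", "D"] <- w["D", "A"] <- 0.3
  w["B", "C"] <- w["C", "B"] <- 0.2
  w["B", "D"] <- w["D", "B"] <- 0.1
  w["C", "D"] <- w["D", "C"] <- 0.05
  net <- structure(list(labels = LETTERS[1:4], weights = w), class = "cov_network")
  b <- binarize_at_sparsity(net, 0.5)
  expect_equal(sum(b$adjacency) / 2, 3)
  expect_equal(b$adjacency["A", "B"] + b$adjacency["A", "C"] + b$adjacency["A", "D"], 3)

  # full retention: complete graph
  full <- binarize_at_sparsity(net, 1.0)
  expect_equal(sum(full$adjacency) / 2, 6)

  # infeasible request names the achievable maximum
  w2 <- w
  w2[w2 < 0.5] <- 0
  net2 <- structure(list(labels = LETTERS[1:4], weights = w2), class = "cov_network")
  expect_error(binarize_at_sparsity(net2, 1.0), "maximum achievable sparsity")
})

test_that("a 90-node network binarized at 0.25 has exactly 1001 edges", {
  set.seed(46)
  w <- matrix(runif(90 * 90), 90, 90)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  net <- structure(list(labels = paste0("R", 1:90), weights = w), class = "cov_network")
  b <- binarize_at_sparsity(net, 0.25)
  expect_equal(sum(b$adjacency) / 2, 1001)
  expect_equal(diag(b$adjacency), rep(0L, 90), ignore_attr = TRUE)
  expect_equal(b$adjacency, t(b$adjacency))
})

test_that("thresholding is rank-based and nested across sparsities", {
  set.seed(47)
  w <- matrix(runif(400), 20, 20)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  net <- structure(list(labels = paste0("R", 1:20), weights = w), class = "cov_network")
  # invariance to a strictly monotone weight transform
  net_t <- net
  net_t$weights <- sqrt(net$weights) # monotone on [0, 1]
  expect_equal(
    binarize_at_sparsity(net, 0.3)$adjacency,
    binarize_at_sparsity(net_t, 0.3)$adjacency
  )
  # nestedness: lower-sparsity edge sets are subsets of higher ones
  prev <- binarize_at_sparsity(net, 0.1)$adjacency
  for (s in c(0.2, 0.4, 0.8)) {
    cur <- binarize_at_sparsity(net, s)$adjacency
    expect_true(all(cur[prev == 1] == 1))
    prev <- cur
  }
})

test_that("sparsity grid is inclusive and drift-free", {
  g <- sparsity_grid(0.25, 0.53, 0.01)
  expect_length(g, 29)
  expect_equal(g[1], 0.25)
  expect_equal(g[29], 0.53)
  expect_equal(sparsity_grid(0.4, 0.4, 0.01), 0.4)
  expect_equal(sparsity_grid(0.1, 0.2, 0.05), c(0.10, 0.15, 0.20))
  expect_error(sparsity_grid(0.5, 0.2, 0.01), "low")
  expect_error(sparsity_grid(0.2, 0.5, -0.1), "step")
})

test_that("group correlations converge to the generator's analytic matrix", {
  cfg <- morph_config(n_subjects = 2000, seed = 1)
  tab <- residualize(generate_morphometry(cfg, cfg, seed = 48))
  net <- covariance_matrix(tab, "high")
  r <- analytic_correlation(cfg)
  diag(r) <- 0
  dev <- abs(net$weights - r)[upper.tri(r)]
  # sampling sd of one r at n = 2000 is ~0.02; the max over 4005 entries
  # concentrates below ~5 sd, the mean far lower
  expect_lt(max(dev), 0.12)
  expect_lt(mean(dev), 0.025)
})
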