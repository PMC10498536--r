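test_that("group relabeling preserves sizes, reproduces, and is uniform", {
  grp <- rep(c("high", "low"), 35)
  p1 <- permute_groups(grp, seed = 5, rep_index = 1)
  expect_equal(sum(p1 == "high"), 35)
  expect_equal(sum(p1 == "low"), 35)
  expect_identical(p1, permute_groups(grp, seed = 5, rep_index = 1))
  expect_false(identical(p1, permute_groups(grp, seed = 5, rep_index = 2)))

  # each slot lands in the high group about half the time
  freq <- rowMeans(vapply(
    1:1000, function(r) permute_groups(grp, seed = 6, rep_index = r) == "high",
    logical(70)
  ))
  expect_true(all(abs(freq - 0.5) < 4 * sqrt(0.25 / 1000)))
})

test_that("identical groups give zero observed difference and p = 1", {
  cfg <- morph_config(n_subjects = 12, seed = 1)
  one <- generate_morphometry(cfg, cfg, seed = 7)
  # overwrite the low block with an exact copy of the high block
  vol <- one$volumes
  vol[13:24, ] <- vol[1:12, ]
  tab <- morph_table(vol, one$covariates, one$group)
  tab$residualized <- TRUE
  res <- suppressWarnings(permutation_test_global(tab,
    sparsities = 0.25, metrics = "clustering", reps = 60, seed = 8
  ))$results
  expect_equal(res$observed_diff, 0)
  expect_equal(res$p_value, 1)
})

test_that("p-values and null CIs tell a consistent story", {
  tab <- make_test_table("null", seed = 9, n = 20)
  res <- permutation_test_global(tab,
    sparsities = c(0.25, 0.35, 0.45),
    metrics = c("clustering", "path_length"), reps = 199, seed = 10
  )$results
  slack <- 2 / 200 # add-one discreteness
  for (i in seq_len(nrow(res))) {
    inside <- res$observed_diff[i] >= res$ci_low[i] & res$observed_diff[i] <= res$ci_high[i]
    if (res$p_value[i] > 0.05 + slack) expect_true(inside)
    if (res$p_value[i] < 0.05 - slack) expect_false(inside)
  }
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$ci_low <= res$ci_high))
})

test_that("a planted bridge community concentrates the betweenness difference", {
  # community 1 gets stronger cross-community loadings in the high group
  # only, making its regions bridges there; averaged over replicate cohorts
  # the community-mean normalized-BC difference singles it out (per-node
  # betweenness is far too volatile for single-cohort localization)
  comm <- morph_config()$community
  diffs <- vapply(c(11, 21, 31, 41, 51), function(seed) {
    low <- morph_config(n_subjects = 150, seed = 1)
    high <- morph_config(
      n_subjects = 150,
      between_loading = c(0.45, 0.2, 0.2, 0.2), seed = 2
    )
    tab <- residualize(generate_morphometry(high, low, seed = seed))
    discountnet:::nodal_diffs(tab$volumes, tab$group, 0.25)
  }, numeric(90))
  comm_means <- tapply(rowMeans(diffs), comm, mean)
  expect_equal(unname(which.max(comm_means)), 1)
  expect_gt(comm_means[[1]], 0)
})

test_that("the nodal permutation test reports coherent, reproducible inference", {
  tab <- make_test_table("planted", seed = 14)
  pn <- suppressWarnings(permutation_test_nodal(tab, sparsity = 0.25, reps = 99, seed = 15))
  r <- pn$results
  expect_equal(nrow(r), 90)
  expect_true(all(r$p_value > 0 & r$p_value <= 1))
  expect_true(all(r$ci_low <= r$ci_high))
  expect_equal(r$sig_05, r$p_value < 0.05)
  expect_equal(r$sig_corrected, r$p_value < 0.011)
  expect_equal(pn$settings$corrected_threshold, 0.011)
  # full determinism under identical seeds
  pn2 <- suppressWarnings(permutation_test_nodal(tab, sparsity = 0.25, reps = 99, seed = 15))
  expect_identical(pn$results, pn2$results)
})

test_that("the nodal correction threshold is 1/N rounded to 3 decimals", {
  expect_equal(nodal_threshold(90), 0.011)
  expect_equal(nodal_threshold(100), 0.010)
  expect_error(nodal_threshold(0), "positive")
})

test_that("pooled t statistics from summaries and raw data agree", {
  set.seed(71)
  x <- rnorm(35, 10, 2)
  y <- rnorm(35, 11, 2)
  raw <- two_sample_t(x, y)
  summ <- two_sample_t_from_summaries(mean(x), sd(x), 35, mean(y), sd(y), 35)
  expect_equal(raw$t_value, summ$t_value, tolerance = 1e-12)
  expect_equal(raw$df, 68)

  # independent route: stats::t.test with pooled variance
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(raw$t_value, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(raw$p_value, tt$p.value, tolerance = 1e-12)

  expect_equal(two_sample_t_from_summaries(5, 2, 10, 5, 2, 10)$t_value, 0)
  expect_equal(two_sample_t_from_summaries(5, 0, 10, 5, 0, 10)$t_value, 0)
  expect_error(two_sample_t_from_summaries(5, 0, 10, 6, 0, 10), "pooled variance")
})

test_that("2x2 chi-square follows the Pearson formula without correction", {
  expect_equal(chi_square_2x2(10, 10, 10, 10)$chi_square, 0)
  # all expected counts 2.5: chi-square = 4 * (2.5)^2 / 2.5 * ... = 10
  expect_equal(suppressWarnings(chi_square_2x2(5, 0, 0, 5))$chi_square, 10)
  # independent arithmetic: n (ad - bc)^2 / (r1 r2 c1 c2)
  hand <- 40 * (12 * 9 - 8 * 11)^2 / (20 * 20 * 23 * 17)
  expect_equal(chi_square_2x2(12, 8, 11, 9)$chi_square, hand, tolerance = 1e-12)
  expect_error(chi_square_2x2(0, 0, 3, 4), "marginal")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "non-negative")
})
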