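# Seed for one permutation replicate, derived deterministically from the
# master seed and the replicate index (kept below 2^31 - 1).
perm_seed <- function(seed, rep_index) {
  (as.numeric(seed) %% 1e6) * 2039 + rep_index * 7 + 11
}

#' Random group relabeling preserving group sizes
#'
#' Uniformly random reassignment of subjects to two pseudo-groups with
#' exactly the original group sizes, reproducible from `(seed, rep_index)`.
#' Applied to once-corrected volumes: the covariate correction is fixed
#' before permutation and never refitted.
#'
#' @param group Character vector of `"high"`/`"low"` labels.
#' @param seed Master seed.
#' @param rep_index Replicate index (1-based).
#' @return Permuted label vector with the same group sizes.
#' @export
permute_groups <- function(group, seed, rep_index) {
  set.seed(perm_seed(seed, rep_index))
  out <- sample(group)
  stopifnot(all(table(out) == table(group)[names(table(out))]))
  out
}

# Correlation -> zero negatives -> binarize for one group's volume block.
group_weights <- function(vol) {
  w <- stats::cor(vol)
  diag(w) <- 0
  w[w < 0] <- 0
  w
}

binarize_weights <- function(w, sparsity) {
  n <- nrow(w)
  m <- floor(sparsity * n * (n - 1) / 2)
  ij <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  if (m > sum(wt > 0)) {
    stop(sprintf("requested %d edges but only %d positive weights", m, sum(wt > 0)))
  }
  keep <- order(-wt, ij[, 1], ij[, 2])[seq_len(m)]
  a <- matrix(0L, n, n)
  a[ij[keep, , drop = FALSE]] <- 1L
  a + t(a)
}

# Global metric differences (high minus low) for every (metric, sparsity)
# cell: full pipeline re-run under the given labels, including fresh
# degree-preserving nulls when sigma is requested.
global_diffs <- function(vol, labels, sparsities, metrics, n_random, seed_base) {
  per_group <- function(g, goff) {
    w <- group_weights(vol[labels == g, , drop = FALSE])
    out <- matrix(NA_real_, length(metrics), length(sparsities),
      dimnames = list(metrics, NULL)
    )
    for (i in seq_along(sparsities)) {
      a <- binarize_weights(w, sparsities[i])
      gg <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
      cp <- mean(igraph::transitivity(gg, type = "local", isolates = "zero"))
      d <- igraph::distances(gg)
      du <- d[upper.tri(d)]
      lp <- mean(du[is.finite(du)])
      if ("clustering" %in% metrics) out["clustering", i] <- cp
      if ("path_length" %in% metrics) out["path_length", i] <- lp
      if ("sigma" %in% metrics) {
        set.seed(seed_base + goff * 104729 + i)
        ne <- sum(a) / 2
        cps <- lps <- numeric(n_random)
        for (r in seq_len(n_random)) {
          gr <- igraph::rewire(gg, igraph::keeping_degseq(niter = 10 * ne))
          cps[r] <- mean(igraph::transitivity(gr, type = "local", isolates = "zero"))
          dr <- igraph::distances(gr)
          dru <- dr[upper.tri(dr)]
          lps[r] <- mean(dru[is.finite(dru)])
        }
        out["sigma", i] <- (cp / mean(cps)) / (lp / mean(lps))
      }
    }
    out
  }
  per_group("high", 1) - per_group("low", 2)
}

#' Permutation test on global network topology
#'
#' Compares high and low discounters on clustering coefficient,
#' characteristic path length and small-worldness at every sparsity
#' threshold. The observed difference is `metric(high) - metric(low)`; the
#' null distribution re-runs the full pipeline (correlation, negative-edge
#' zeroing, binarization, metric, fresh random-network normalization for
#' sigma) under random relabelings that preserve group sizes. Two-sided
#' p-values use the add-one estimator
#' `(1 + #\{|null| >= |observed|\}) / (1 + reps)`; the 95% interval is the
#' empirical 2.5/97.5 percentile band of the null.
#'
#' Inside permutations sigma is normalized with a reduced null ensemble
#' (`n_random_inner`, default 20) to keep `reps x thresholds` runs
#' tractable; the observed sigma uses the full `n_random`. Replicates where
#' any stage fails are excluded and counted in `n_failed`.
#'
#' @param table Residualized [morph_table()] with `"high"`/`"low"` groups.
#' @param sparsities Sparsity thresholds (default [sparsity_grid()]).
#' @param metrics Any of `"clustering"`, `"path_length"`, `"sigma"`.
#' @param reps Number of permutations (study setting: 1000).
#' @param n_random Null networks for the observed sigma (study setting: 100).
#' @param n_random_inner Null networks for sigma inside permutations.
#' @param seed Master seed.
#' @return List of class `perm_test`: `results` (long data frame with
#'   `metric`, `sparsity`, `observed_diff`, `ci_low`, `ci_high`, `p_value`,
#'   `reps_used`, `n_failed`), `null_diffs` (replicate x metric x sparsity
#'   array) and `settings`.
#' @export
permutation_test_global <- function(table,
                                    sparsities = sparsity_grid(),
                                    metrics = c("clustering", "path_length", "sigma"),
                                    reps = 1000, n_random = 100,
                                    n_random_inner = 20, seed = 1) {
  stopifnot(inherits(table, "morph_table"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!all(table$group %in% c("high", "low"))) stop("groups must be 'high'/'low'; use assign_groups()")
  if (min(table(table$group)) < 4) stop("both groups need at least 4 subjects")
  if (!table$residualized) warning("volumes are not residualized")
  if (reps < 100) warning("fewer than 100 permutations: CI resolution is coarse")

  vol <- table$volumes
  observed <- global_diffs(vol, table$group, sparsities, metrics, n_random, seed)
  nulls <- array(NA_real_, c(reps, length(metrics), length(sparsities)),
    dimnames = list(NULL, metrics, NULL)
  )
  n_failed <- 0L
  for (r in seq_len(reps)) {
    lab <- permute_groups(table$group, seed, r)
    d <- tryCatch(
      global_diffs(vol, lab, sparsities, metrics, n_random_inner, perm_seed(seed, r)),
      error = function(e) NULL
    )
    if (is.null(d)) n_failed <- n_failed + 1L else nulls[r, , ] <- d
  }

  rows <- expand.grid(
    metric = metrics, sparsity = sparsities,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  res <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    m <- rows$metric[i]
    si <- match(rows$sparsity[i], sparsities)
    nd <- nulls[, m, si]
    nd <- nd[!is.na(nd)]
    obs <- observed[m, si]
    data.frame(
      metric = m, sparsity = rows$sparsity[i], observed_diff = obs,
      ci_low = stats::quantile(nd, 0.025, names = FALSE),
      ci_high = stats::quantile(nd, 0.975, names = FALSE),
      p_value = (1 + sum(abs(nd) >= abs(obs))) / (1 + length(nd)),
      reps_used = length(nd), n_failed = n_failed
    )
  }))
  structure(
    list(
      results = res, null_diffs = nulls,
      settings = list(
        reps = reps, n_random = n_random, n_random_inner = n_random_inner,
        seed = seed, sparsities = sparsities, n_failed = n_failed
      )
    ),
    class = "perm_test"
  )
}

# Normalized-betweenness difference per region under the given labels.
nodal_diffs <- function(vol, labels, sparsity) {
  one <- function(g) {
    a <- binarize_weights(group_weights(vol[labels == g, , drop = FALSE]), sparsity)
    gg <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    bc <- igraph::betweenness(gg, directed = FALSE)
    bc / mean(bc)
  }
  one("high") - one("low")
}

#' Permutation test on nodal betweenness centrality
#'
#' Per-region comparison of normalized betweenness between groups at one
#' fixed sparsity (study setting: 0.25, where the network keeps all nodes
#' while minimizing spurious edges). Significance is reported at two levels:
#' the nominal p < 0.05 and the stricter node-count correction
#' p < 1/N (rounded to 3 decimals; 0.011 for 90 nodes, see
#' [nodal_threshold()]).
#'
#' @inheritParams permutation_test_global
#' @param sparsity Single sparsity threshold (default 0.25).
#' @return List of class `perm_test_nodal`: `results` (data frame with
#'   `region`, `observed_diff`, `ci_low`, `ci_high`, `p_value`, `sig_05`,
#'   `sig_corrected`), `null_diffs`, `settings`.
#' @export
permutation_test_nodal <- function(table, sparsity = 0.25, reps = 1000, seed = 1) {
  stopifnot(inherits(table, "morph_table"))
  if (!all(table$group %in% c("high", "low"))) stop("groups must be 'high'/'low'; use assign_groups()")
  if (min(table(table$group)) < 4) stop("both groups need at least 4 subjects")
  if (!table$residualized) warning("volumes are not residualized")
  if (reps < 100) warning("fewer than 100 permutations: CI resolution is coarse")

  vol <- table$volumes
  n_region <- ncol(vol)
  thr <- nodal_threshold(n_region)
  observed <- nodal_diffs(vol, table$group, sparsity)
  nulls <- matrix(NA_real_, reps, n_region)
  n_failed <- 0L
  for (r in seq_len(reps)) {
    lab <- permute_groups(table$group, seed, r)
    d <- tryCatch(nodal_diffs(vol, lab, sparsity), error = function(e) NULL)
    if (is.null(d)) n_failed <- n_failed + 1L else nulls[r, ] <- d
  }
  ok <- !is.na(nulls[, 1])
  p <- vapply(seq_len(n_region), function(j) {
    (1 + sum(abs(nulls[ok, j]) >= abs(observed[j]))) / (1 + sum(ok))
  }, numeric(1))
  res <- data.frame(
    region = colnames(vol), observed_diff = as.numeric(observed),
    ci_low = apply(nulls[ok, , drop = FALSE], 2, stats::quantile, 0.025, names = FALSE),
    ci_high = apply(nulls[ok, , drop = FALSE], 2, stats::quantile, 0.975, names = FALSE),
    p_value = p, sig_05 = p < 0.05, sig_corrected = p < thr
  )
  structure(
    list(
      results = res, null_diffs = nulls,
      settings = list(
        reps = reps, sparsity = sparsity, seed = seed,
        corrected_threshold = thr, n_failed = n_failed
      )
    ),
    class = "perm_test_nodal"
  )
}

#' Node-count correction threshold for nodal tests
#'
#' The stricter per-node significance level `1/N` rounded to 3 decimals:
#' 0.011 for a 90-node parcellation, 0.010 for 100 nodes.
#'
#' @param n_nodes Number of network nodes.
#' @return The rounded threshold.
#' @export
nodal_threshold <- function(n_nodes) {
  if (n_nodes < 1) stop("`n_nodes` must be positive")
  round(1 / n_nodes, 3)
}

#' Pooled two-sample t statistic from summary statistics
#'
#' Classical equal-variance two-sample t computed from group means, standard
#' deviations and sizes, with `df = n1 + n2 - 2`. Used for cohort
#' demographics where only summaries are available.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List with `t_value`, `df`, `p_value` (two-sided).
#' @export
two_sample_t_from_summaries <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be non-negative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) {
    if (m1 == m2) {
      return(list(t_value = 0, df = df, p_value = 1))
    }
    stop("zero pooled variance with unequal means: t undefined")
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t_value = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Pooled two-sample t statistic from raw vectors
#'
#' @param x,y Numeric vectors for the two groups.
#' @return As [two_sample_t_from_summaries()].
#' @export
two_sample_t <- function(x, y) {
  two_sample_t_from_summaries(
    mean(x), stats::sd(x), length(x),
    mean(y), stats::sd(y), length(y)
  )
}

#' Pearson chi-square for a 2x2 table
#'
#' Association test on counts `(a, b)` in row 1 and `(c, d)` in row 2,
#' without continuity correction (matching the conventional report for
#' sex-by-group tables).
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return List with `chi_square`, `df` (= 1), `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("empty table")
  tab <- matrix(c(a, c, b, d), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero marginal total")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi_square = unname(ct$statistic), df = unname(ct$parameter), p_value = ct$p.value)
}
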