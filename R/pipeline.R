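#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis with defaults matching
#' the study design: sparsity 0.25-0.53 in steps of 0.01, 1,000
#' permutations, 100 matched random networks, nodal analysis at sparsity
#' 0.25 with the 1/N node-count correction.
#'
#' @param choices_path Choice-log file (see [read_choice_log()]); `NULL` to
#'   skip the behavioral stage and use `group` labels already present.
#' @param volumes_path,covariates_path Morphometry inputs
#'   (see [read_morphometry()]).
#' @param out_dir Output directory.
#' @param sparsity_low,sparsity_high,sparsity_step Threshold grid.
#' @param nodal_sparsity Sparsity for the nodal (betweenness) analysis.
#' @param reps Permutation repetitions.
#' @param n_random Matched random networks for observed metrics.
#' @param n_random_inner Random networks for sigma inside permutations.
#' @param alpha Nominal significance level.
#' @param residualize_scope `"pooled"` or `"within_group"`.
#' @param covariate_names Covariates regressed out of the volumes.
#' @param seed Master seed for every stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(choices_path = NULL, volumes_path = NULL,
                       covariates_path = NULL, out_dir = "results",
                       sparsity_low = 0.25, sparsity_high = 0.53,
                       sparsity_step = 0.01, nodal_sparsity = 0.25,
                       reps = 1000, n_random = 100, n_random_inner = 20,
                       alpha = 0.05, residualize_scope = "pooled",
                       covariate_names = c("age", "sex", "education", "tiv"),
                       seed = 1) {
  structure(
    list(
      choices_path = choices_path, volumes_path = volumes_path,
      covariates_path = covariates_path, out_dir = out_dir,
      sparsity_low = sparsity_low, sparsity_high = sparsity_high,
      sparsity_step = sparsity_step, nodal_sparsity = nodal_sparsity,
      reps = reps, n_random = n_random, n_random_inner = n_random_inner,
      alpha = alpha, residualize_scope = residualize_scope,
      covariate_names = covariate_names, seed = seed
    ),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Chains every stage: discounting fits and median split (when a choice log
#' is supplied), covariate residualization, group covariance networks,
#' negative-edge zeroing, thresholding over the sparsity grid, global
#' small-world metrics, nodal betweenness with hubs, and the global and
#' nodal permutation tests. All stage outputs land in `config$out_dir` as
#' tab-separated tables, together with a machine-readable JSON manifest
#' (config echo, seeds, edge counts, zeroed-negative and
#' failed-permutation counts). Identical configs give byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param table Optionally, a ready [morph_table()] (bypasses the file
#'   inputs; group labels must be set unless a choice log is given).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, table = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(config$out_dir, f),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  fits <- NULL
  if (!is.null(config$choices_path)) {
    fits <- stage("behavior", {
      log <- read_choice_log(config$choices_path)
      fit_discounting_table(log)
    })
    split <- stage("median_split", median_split(fits$k, fits$subject_id))
    fits$group <- ifelse(fits$subject_id %in% split$high, "high",
      ifelse(fits$subject_id %in% split$low, "low", "excluded")
    )
    wt(fits, "discounting_fits.tsv")
  }

  if (is.null(table)) {
    table <- stage(
      "read_morphometry",
      read_morphometry(config$volumes_path, config$covariates_path)
    )
  }
  if (!is.null(fits)) {
    table <- stage("assign_groups", assign_groups(table, split))
  }
  if (!all(table$group %in% c("high", "low"))) {
    stop("pipeline needs 'high'/'low' group labels (from a choice log or the table)")
  }

  table <- stage("residualize", residualize(table,
    covariate_names = config$covariate_names,
    scope = config$residualize_scope
  ))

  grid <- sparsity_grid(config$sparsity_low, config$sparsity_high, config$sparsity_step)
  nets <- list()
  global_rows <- list()
  edge_log <- list()
  for (g in c("high", "low")) {
    net <- stage("covariance", zero_negatives(covariance_matrix(table, g)))
    nets[[g]] <- net
    write_network(net,
      matrix_path = file.path(config$out_dir, paste0("weights_", g, ".tsv"))
    )
    for (i in seq_along(grid)) {
      b <- stage("binarize", binarize_at_sparsity(net, grid[i]))
      sw <- stage("small_world", small_world(b,
        n_random = config$n_random,
        seed = perm_seed(config$seed, 0) + match(g, c("high", "low")) * 1e5 + i
      ))
      global_rows[[length(global_rows) + 1]] <- data.frame(
        group = g, sparsity = grid[i],
        clustering = sw$clustering, path_length = sw$path_length,
        gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma,
        disconnected_pairs = sw$disconnected_pairs
      )
      edge_log[[length(edge_log) + 1]] <- data.frame(
        group = g, sparsity = grid[i], n_edges = sum(b$adjacency) / 2,
        n_negative_zeroed = net$n_negative_zeroed
      )
      if (grid[i] == config$nodal_sparsity) {
        if (any(rowSums(b$adjacency) == 0)) {
          warning(sum(rowSums(b$adjacency) == 0), " isolated node(s) in the ",
            g, " network at sparsity ", config$nodal_sparsity)
        }
        nm <- stage("nodal_metrics", nodal_metrics(b))
        wt(cbind(group = g, nm), paste0("nodal_metrics_", g, ".tsv"))
      }
    }
  }
  global <- do.call(rbind, global_rows)
  wt(global, "global_metrics.tsv")

  perm_g <- stage("permutation_global", permutation_test_global(table,
    sparsities = grid, reps = config$reps, n_random = config$n_random,
    n_random_inner = config$n_random_inner, seed = config$seed
  ))
  wt(perm_g$results, "permutation_global.tsv")

  perm_n <- stage("permutation_nodal", permutation_test_nodal(table,
    sparsity = config$nodal_sparsity, reps = config$reps, seed = config$seed
  ))
  wt(perm_n$results, "permutation_nodal.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("discountnet")),
    config = unclass(config),
    n_subjects = unname(c(table(table$group))["high"] + c(table(table$group))["low"]),
    n_regions = length(table$regions),
    nodal_threshold = nodal_threshold(length(table$regions)),
    edge_counts = do.call(rbind, edge_log),
    n_failed_permutations = list(
      global = perm_g$settings$n_failed,
      nodal = perm_n$settings$n_failed
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    fits = fits, table = table, networks = nets, global = global,
    permutation_global = perm_g, permutation_nodal = perm_n
  ))
}

#' Write synthetic fixtures for the pipeline
#'
#' Generates a full synthetic study — per-subject choice logs whose fitted
#' discount rates split the cohort, plus factor-model morphometry under the
#' chosen scenario — and writes them in the tabular formats the pipeline
#' reads, together with a ground-truth manifest (true k/beta per subject and
#' generator configs).
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param scenario `"null"` or `"planted"` (see [morph_scenario()]).
#' @param n_per_group Subjects per morphometry group.
#' @return Invisibly, the list of files written.
#' @export
make_fixtures <- function(out_dir, seed = 1, scenario = c("planted", "null"),
                          n_per_group = 35) {
  scenario <- match.arg(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- 2 * n_per_group + 1 # odd cohort: one median scorer to exclude
  set.seed((seed %% 1e6) * 31 + 7)
  k_true <- sort(10^stats::runif(n, -3, -1))
  cohort <- generate_choice_cohort(k_true, seed = seed)
  scen <- morph_scenario(scenario, seed = seed, n_subjects = n_per_group)
  # the whole scanned cohort is in the table; the median scorer (who will be
  # excluded by the split) gets low-group generating parameters
  scen$low$n_subjects <- n_per_group + 1
  tab <- generate_morphometry(scen$high, scen$low, seed = seed)
  ord <- order(k_true)
  ids <- cohort$truth$subject_id
  low_block_ids <- ids[ord[seq_len(n_per_group + 1)]]
  high_ids <- ids[ord[seq(n_per_group + 2, n)]]
  tab$subjects <- c(high_ids, low_block_ids)
  rownames(tab$volumes) <- tab$subjects
  tab$covariates$subject_id <- tab$subjects

  paths <- list(
    choices = file.path(out_dir, "choices.tsv"),
    volumes = file.path(out_dir, "volumes.tsv"),
    covariates = file.path(out_dir, "covariates.tsv"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  utils::write.table(cohort$choices, paths$choices,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_morphometry(tab, paths$volumes, paths$covariates)
  jsonlite::write_json(
    list(
      seed = seed, scenario = scenario, truth = cohort$truth,
      config_high = unclass(scen$high), config_low = unclass(scen$low)
    ),
    paths$truth,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
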