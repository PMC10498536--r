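#' Configuration for the intertemporal-choice generator
#'
#' Trials pit a fixed immediate reward (10,000 KRW now) against a larger
#' delayed reward drawn from the task grid: amounts on 1,000-KRW steps in
#' 11,000-48,000 KRW, delays of 2-180 days, 120 trials per subject.
#'
#' @param k_true Generating discount rate per day (> 0).
#' @param beta_true Generating logistic scaling (>= 0). Default 0.005, a
#'   sensitivity producing realistic choice stochasticity on the KRW scale.
#' @param n_trials Trials per subject (default 120).
#' @param immediate_amount Fixed immediate reward (default 10000).
#' @param amount_range,amount_step Delayed-reward grid (default
#'   11,000-48,000 by 1,000).
#' @param delay_range Delay grid in whole days (default 2-180).
#' @param seed Integer seed.
#' @return List of class `choice_config`.
#' @export
choice_config <- function(k_true, beta_true = 0.005, n_trials = 120,
                          immediate_amount = 10000,
                          amount_range = c(11000, 48000), amount_step = 1000,
                          delay_range = c(2, 180), seed = 1) {
  if (k_true <= 0) stop("`k_true` must be positive")
  if (beta_true < 0) stop("`beta_true` must be non-negative")
  if (n_trials < 1) stop("`n_trials` must be positive")
  structure(
    list(
      k_true = k_true, beta_true = beta_true, n_trials = n_trials,
      immediate_amount = immediate_amount, amount_range = amount_range,
      amount_step = amount_step, delay_range = delay_range, seed = seed
    ),
    class = "choice_config"
  )
}

#' Simulate one subject's intertemporal choices
#'
#' Amounts and delays are sampled uniformly on the task grid; each choice is
#' Bernoulli with probability [choice_probability()] of the generating
#' hyperbolic subjective values. Fully reproducible from the config seed.
#'
#' @param config A [choice_config()].
#' @param subject_id Identifier stored with the trials.
#' @return Data frame with columns `subject_id`, `immediate_amount`,
#'   `delayed_amount`, `delay_days`, `chose_delayed`.
#' @export
generate_choices <- function(config, subject_id = "s1") {
  stopifnot(inherits(config, "choice_config"))
  set.seed(config$seed)
  amounts <- sample(
    seq(config$amount_range[1], config$amount_range[2], by = config$amount_step),
    config$n_trials,
    replace = TRUE
  )
  delays <- sample(seq(config$delay_range[1], config$delay_range[2]),
    config$n_trials,
    replace = TRUE
  )
  p1 <- choice_probability(
    subjective_value(amounts, delays, config$k_true),
    config$immediate_amount, # immediate option: delay 0, SV = amount
    config$beta_true
  )
  data.frame(
    subject_id = subject_id,
    immediate_amount = config$immediate_amount,
    delayed_amount = amounts,
    delay_days = delays,
    chose_delayed = stats::rbinom(config$n_trials, 1, p1)
  )
}

#' Simulate a cohort of choice logs
#'
#' @param k_true Vector of per-subject generating discount rates.
#' @param beta_true Shared scaling factor.
#' @param n_trials Trials per subject.
#' @param seed Master seed; per-subject seeds are derived deterministically.
#' @return List with `choices` (stacked choice log) and `truth` (data frame
#'   of `subject_id`, `k_true`, `beta_true`).
#' @export
generate_choice_cohort <- function(k_true, beta_true = 0.005, n_trials = 120, seed = 1) {
  ids <- sprintf("sub%03d", seq_along(k_true))
  logs <- lapply(seq_along(k_true), function(i) {
    generate_choices(
      choice_config(k_true[i], beta_true,
        n_trials = n_trials,
        seed = (seed %% 1e6) * 1013 + i
      ),
      subject_id = ids[i]
    )
  })
  list(
    choices = do.call(rbind, logs),
    truth = data.frame(subject_id = ids, k_true = k_true, beta_true = beta_true)
  )
}

#' Configuration for the morphometry factor-model generator
#'
#' Regional volumes follow a community factor model: regions are partitioned
#' evenly into `n_communities`; region j in community c loads
#' `within_loading` on community factor c and `between_loading` on every
#' other community's factor. Per-subject covariates (age, sex, education,
#' TIV) shift all regions by `covariate_effects`, and independent Gaussian
#' noise with SD `noise_sd` is added. The implied region-region correlation
#' matrix has the closed form of [analytic_correlation()], which makes every
#' covariance-stage computation testable against an exact oracle.
#'
#' Defaults define the reference study condition: 35 subjects, 90 regions,
#' 4 communities, within 1.0 / between 0.2 / noise 0.6 — strong enough
#' community structure that binarized networks sit in the small-world regime
#' (sigma > 1) over the 0.25-0.53 sparsity range.
#'
#' @param n_subjects Subjects in the group (default 35).
#' @param n_regions Regions (default 90).
#' @param n_communities Number of community factors (default 4).
#' @param within_loading Loading on the own-community factor (>= 0); a
#'   scalar, or one value per community to weaken or strengthen single
#'   communities.
#' @param between_loading Loading of a region on each other community's
#'   factor (>= 0); a scalar, or one value per community (indexed by the
#'   region's own community) to turn single communities into bridges.
#' @param covariate_effects Named vector of per-unit slopes applied to every
#'   region for `age` (years), `sex` (0/1), `education` (years), `tiv`.
#' @param noise_sd Residual SD (> 0).
#' @param baseline Grand mean volume (arbitrary units).
#' @param seed Integer seed.
#' @return List of class `morph_config` (includes the derived `community`
#'   membership vector).
#' @export
morph_config <- function(n_subjects = 35, n_regions = 90, n_communities = 4,
                         within_loading = 1.0, between_loading = 0.2,
                         covariate_effects = c(age = 0.03, sex = 0.25, education = 0.04, tiv = 0.0015),
                         noise_sd = 0.6, baseline = 10, seed = 1) {
  if (any(within_loading < 0) || any(between_loading < 0)) stop("loadings must be non-negative")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  if (n_communities < 1 || n_communities > n_regions) stop("invalid `n_communities`")
  if (!length(within_loading) %in% c(1L, n_communities)) {
    stop("`within_loading` must be a scalar or one value per community")
  }
  if (!length(between_loading) %in% c(1L, n_communities)) {
    stop("`between_loading` must be a scalar or one value per community")
  }
  within_loading <- rep(within_loading, length.out = n_communities)
  between_loading <- rep(between_loading, length.out = n_communities)
  structure(
    list(
      n_subjects = n_subjects, n_regions = n_regions, n_communities = n_communities,
      within_loading = within_loading, between_loading = between_loading,
      covariate_effects = covariate_effects, noise_sd = noise_sd,
      baseline = baseline, seed = seed,
      community = sort(rep(seq_len(n_communities), length.out = n_regions))
    ),
    class = "morph_config"
  )
}

#' The two-group study scenarios
#'
#' `"null"`: both groups share the reference configuration (no planted
#' difference) — used for type-I-error checks. `"planted"`: the
#' high-discounting group's within-community loading is reduced from 1.0 to
#' 0.6, lowering its network segregation (clustering) while keeping it in
#' the small-world regime — the direction reported for high discounters.
#'
#' @param scenario `"null"` or `"planted"`.
#' @param seed Master seed; group sub-seeds are derived from it.
#' @param ... Overrides passed to both groups' [morph_config()].
#' @return List with `high` and `low` morph configs.
#' @export
morph_scenario <- function(scenario = c("planted", "null"), seed = 1, ...) {
  scenario <- match.arg(scenario)
  base_seed <- (seed %% 1e6) * 1021
  low <- morph_config(seed = base_seed + 1, ...)
  high <- if (scenario == "planted") {
    morph_config(within_loading = 0.6, seed = base_seed + 2, ...)
  } else {
    morph_config(seed = base_seed + 2, ...)
  }
  list(high = high, low = low, scenario = scenario)
}

# Draw covariates on the demographic scales of a young-adult cohort.
draw_covariates <- function(n, prefix) {
  data.frame(
    subject_id = paste0(prefix, sprintf("%03d", seq_len(n))),
    age = stats::rnorm(n, 22, 2.7),
    sex = stats::rbinom(n, 1, 0.5),
    education = stats::rnorm(n, 15, 1.3),
    tiv = stats::rnorm(n, 1550, 150)
  )
}

# Region-by-factor loading matrix implied by a morph_config.
loading_matrix <- function(config) {
  p <- config$n_regions
  L <- matrix(config$between_loading[config$community], p, config$n_communities)
  L[cbind(seq_len(p), config$community)] <- config$within_loading[config$community]
  L
}

# One group's volume matrix under a morph_config (covariates supplied).
draw_volumes <- function(config, covariates) {
  p <- config$n_regions
  n <- nrow(covariates)
  L <- loading_matrix(config)
  f <- matrix(stats::rnorm(n * config$n_communities), n, config$n_communities)
  vol <- config$baseline + f %*% t(L) +
    matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  eff <- config$covariate_effects
  for (cv in names(eff)) {
    vol <- vol + eff[[cv]] * covariates[[cv]]
  }
  vol
}

#' Generate a two-group morphometry table
#'
#' Draws covariates and factor-model volumes for a high and a low group and
#' assembles them into a [morph_table()] with group labels. All randomness
#' is funneled through `seed`; the group configs' own seeds are ignored in
#' favor of sub-seeds derived from it, so one integer reproduces the table.
#'
#' @param config_high,config_low [morph_config()]s for the two groups (e.g.
#'   from [morph_scenario()]).
#' @param seed Master seed.
#' @return A [morph_table()] with groups `"high"` and `"low"`.
#' @export
generate_morphometry <- function(config_high, config_low, seed = 1) {
  stopifnot(inherits(config_high, "morph_config"), inherits(config_low, "morph_config"))
  if (config_high$n_regions != config_low$n_regions) stop("groups must share the region count")
  base <- (seed %% 1e6) * 2063
  set.seed(base + 1)
  cov_h <- draw_covariates(config_high$n_subjects, "hi")
  vol_h <- draw_volumes(config_high, cov_h)
  set.seed(base + 2)
  cov_l <- draw_covariates(config_low$n_subjects, "lo")
  vol_l <- draw_volumes(config_low, cov_l)
  morph_table(
    rbind(vol_h, vol_l),
    rbind(cov_h, cov_l),
    group = rep(c("high", "low"), c(nrow(vol_h), nrow(vol_l)))
  )
}

#' Analytic region-region correlation of the factor model
#'
#' Closed-form correlation implied by the loadings and noise SD of a
#' [morph_config()], for the covariate-free construction (equivalently,
#' after perfect covariate correction). With within-loading w, between-
#' loading b, C communities and noise SD s:
#' same community `(w^2 + (C-1) b^2) / v`, different community
#' `(2wb + (C-2) b^2) / v`, with `v = w^2 + (C-1) b^2 + s^2`.
#' Serves as the exact oracle for covariance-stage convergence tests.
#'
#' @param config A [morph_config()].
#' @return `n_regions x n_regions` correlation matrix (unit diagonal).
#' @export
analytic_correlation <- function(config) {
  stopifnot(inherits(config, "morph_config"))
  covm <- tcrossprod(loading_matrix(config)) + diag(config$noise_sd^2, config$n_regions)
  stats::cov2cor(covm)
}
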