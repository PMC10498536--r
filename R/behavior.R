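#' Hyperbolic subjective value
#'
#' Discounted worth of a reward of size `amount` delivered after `delay` days
#' under hyperbolic discounting: `SV = A / (1 + k * D)`. Equals `amount` when
#' either the delay or the discount rate is zero, and is strictly decreasing
#' in delay for `k > 0`.
#'
#' @param amount Reward magnitude (currency units, e.g. KRW). Must be positive.
#' @param delay Delay to receipt in days. Must be non-negative.
#' @param k Discount rate per day. Must be non-negative.
#' @return Numeric vector of subjective values (same recycling rules as base
#'   arithmetic).
#' @examples
#' subjective_value(17000, 24, 0.029)
#' subjective_value(10000, 0, 0.029) # == 10000
#' @export
subjective_value <- function(amount, delay, k) {
  if (any(amount <= 0)) stop("`amount` must be positive")
  if (any(delay < 0)) stop("`delay` must be non-negative")
  if (any(k < 0)) stop("`k` must be non-negative")
  amount / (1 + k * delay)
}

#' Logistic choice probability
#'
#' Probability of choosing the delayed option given the two subjective
#' values: `P1 = 1 / (1 + exp(-beta * (sv_delayed - sv_immediate)))`. The
#' immediate-choice probability is `1 - P1`. Computed via [stats::plogis()],
#' which is numerically stable for arbitrarily large `|beta * dSV|`.
#'
#' @param sv_delayed Subjective value of the delayed option (SV1).
#' @param sv_immediate Subjective value of the immediate option (SV2).
#' @param beta Inverse-temperature scaling factor, `>= 0`. `beta = 0` gives
#'   indifference (0.5) regardless of the values.
#' @return Probability of choosing the delayed option, in \[0, 1\].
#' @export
choice_probability <- function(sv_delayed, sv_immediate, beta) {
  if (any(beta < 0)) stop("`beta` must be non-negative")
  stats::plogis(beta * (sv_delayed - sv_immediate))
}

# Negative Bernoulli log-likelihood on the (log k, log beta) scale.
# Uses plogis(..., log.p = TRUE) so one-sided saturated fits stay finite.
neg_loglik_dd <- function(par, trials) {
  k <- exp(par[1])
  beta <- exp(par[2])
  dsv <- trials$delayed_amount / (1 + k * trials$delay_days) -
    trials$immediate_amount / (1 + k * trials$immediate_delay)
  eta <- beta * dsv
  ll <- ifelse(trials$chose_delayed == 1,
    stats::plogis(eta, log.p = TRUE),
    stats::plogis(-eta, log.p = TRUE)
  )
  -sum(ll)
}

#' Fit the hyperbolic discounting model to one subject's choices
#'
#' Maximum-likelihood estimation of the discount rate `k` and the logistic
#' scaling factor `beta` from a set of intertemporal choices. Each trial pits
#' an immediate reward against a larger delayed reward; the likelihood is
#' Bernoulli with success probability
#' [choice_probability()] applied to the hyperbolic [subjective_value()]s.
#'
#' Optimization runs on `(log k, log beta)` so positivity needs no
#' constraints, using box-bounded L-BFGS-B from a fixed multi-start grid
#' (`log10 k` in -4..-1 crossed with `log10 beta` in -4..-2); the best
#' converged start wins. Subjects who chose the same option on every trial
#' carry no information about their indifference point: they are flagged
#' `degenerate` with `k` pinned at the search bound (lower bound for
#' all-delayed choosers, upper for all-immediate).
#'
#' @param choices Data frame with columns `immediate_amount`,
#'   `delayed_amount`, `delay_days`, `chose_delayed` (0/1). An optional
#'   `immediate_delay` column defaults to 0.
#' @param k_bounds,beta_bounds Search intervals (positive scale).
#' @param k_starts,beta_starts Multi-start values (positive scale).
#' @return A one-row data frame of class `discount_fit`: `k`, `beta`,
#'   `log_k` (natural log), `log10_k`, `neg_log_lik`, `degenerate`,
#'   `converged`, `n_trials`.
#' @export
fit_discounting <- function(choices,
                            k_bounds = c(1e-6, 10),
                            beta_bounds = c(1e-8, 10),
                            k_starts = 10^(-4:-1),
                            beta_starts = 10^(-4:-2)) {
  req <- c("immediate_amount", "delayed_amount", "delay_days", "chose_delayed")
  miss <- setdiff(req, names(choices))
  if (length(miss)) stop("choice table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(choices) == 0) stop("empty choice set")
  if (nrow(choices) < 2) stop("need at least 2 trials to fit")
  if (!all(choices$chose_delayed %in% c(0, 1))) stop("`chose_delayed` must be 0/1")
  if (is.null(choices$immediate_delay)) choices$immediate_delay <- 0
  design <- unique(choices[, c("delayed_amount", "delay_days")])
  if (nrow(design) < 2) stop("trials must span more than one (amount, delay) pair")

  one_sided <- length(unique(choices$chose_delayed)) == 1L
  if (one_sided) {
    # indifference point unidentified; pin k at the bound the data point to
    k <- if (choices$chose_delayed[1] == 1) k_bounds[1] else k_bounds[2]
    par <- c(log(k), log(max(beta_starts)))
    return(new_discount_fit(
      k = k, beta = exp(par[2]),
      neg_log_lik = neg_loglik_dd(par, choices),
      degenerate = TRUE, converged = TRUE, n_trials = nrow(choices)
    ))
  }

  lower <- log(c(k_bounds[1], beta_bounds[1]))
  upper <- log(c(k_bounds[2], beta_bounds[2]))
  starts <- expand.grid(log(k_starts), log(beta_starts))
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), neg_loglik_dd,
        trials = choices,
        method = "L-BFGS-B", lower = lower, upper = upper
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start")
  new_discount_fit(
    k = exp(best$par[1]), beta = exp(best$par[2]),
    neg_log_lik = best$value,
    degenerate = FALSE, converged = any_conv, n_trials = nrow(choices)
  )
}

new_discount_fit <- function(k, beta, neg_log_lik, degenerate, converged, n_trials) {
  out <- data.frame(
    k = k, beta = beta, log_k = log(k), log10_k = log10(k),
    neg_log_lik = neg_log_lik, degenerate = degenerate,
    converged = converged, n_trials = n_trials
  )
  class(out) <- c("discount_fit", class(out))
  out
}

#' Fit discounting parameters for every subject in a choice log
#'
#' @param choice_log Data frame with a `subject_id` column plus the trial
#'   columns of [fit_discounting()].
#' @param ... Passed to [fit_discounting()].
#' @return Data frame with one row per subject (`subject_id` first).
#' @export
fit_discounting_table <- function(choice_log, ...) {
  if (is.null(choice_log$subject_id)) stop("choice log lacks a `subject_id` column")
  ids <- unique(choice_log$subject_id)
  fits <- lapply(ids, function(id) {
    fit_discounting(choice_log[choice_log$subject_id == id, , drop = FALSE], ...)
  })
  out <- cbind(subject_id = ids, do.call(rbind, fits))
  rownames(out) <- NULL
  out
}

#' Median split into high and low discounters
#'
#' Subjects with `k` above the cohort median form the high-discounting group,
#' those below it the low group. With an odd subject count, the single
#' subject scoring exactly the median is excluded, leaving two equal-sized
#' groups; with an even count nobody sits at the median and nobody is
#' excluded. More than one subject exactly at the median makes the split
#' ambiguous and is an error.
#'
#' @param k Numeric vector of fitted discount rates (the split is invariant
#'   to any monotone transform, e.g. log k).
#' @param subject_id Identifiers parallel to `k`; defaults to `seq_along(k)`.
#' @return List of class `group_assignment` with `high`, `low`, `excluded`
#'   (subject-id vectors) and `median_k`.
#' @export
median_split <- function(k, subject_id = seq_along(k)) {
  if (length(k) < 2) stop("need at least 2 subjects to split")
  if (length(subject_id) != length(k)) stop("`subject_id` and `k` lengths differ")
  if (anyNA(k)) stop("missing k values")
  med <- stats::median(k)
  at <- k == med
  if (length(k) %% 2 == 1L) {
    if (sum(at) != 1L) {
      stop("ambiguous median split: ", sum(at), " subjects at the median value ", med)
    }
  } else if (any(at)) {
    stop("ambiguous median split: ", sum(at), " subjects at the median value ", med)
  }
  out <- list(
    high = subject_id[k > med],
    low = subject_id[k < med],
    excluded = subject_id[at],
    median_k = med
  )
  class(out) <- "group_assignment"
  out
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(
    "Median split at k =", format(x$median_k), "\n ",
    length(x$high), "high discounters,", length(x$low), "low discounters,",
    length(x$excluded), "excluded at the median\n"
  )
  invisible(x)
}
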