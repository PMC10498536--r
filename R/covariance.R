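#' Remove covariate effects from regional volumes
#'
#' Replaces each region's volumes with the residuals of an ordinary
#' least-squares regression on the named covariates plus an intercept, fitted
#' once over the pooled cohort (both groups together, before the group split,
#' matching the correction-then-correlate order of structural covariance
#' analyses). Residuals have mean zero and are exactly orthogonal to every
#' covariate column. OLS residuals are invariant to affine recoding of a
#' covariate, so 0/1 versus 1/2 sex coding gives identical output.
#'
#' @param table A [morph_table()].
#' @param covariate_names Covariate columns to regress out. Default: age,
#'   sex, education, total intracranial volume.
#' @param scope `"pooled"` fits one correction over all subjects (default);
#'   `"within_group"` fits separately inside each group label.
#' @return The table with residualized volumes and `residualized = TRUE`.
#' @export
residualize <- function(table,
                        covariate_names = c("age", "sex", "education", "tiv"),
                        scope = c("pooled", "within_group")) {
  stopifnot(inherits(table, "morph_table"))
  scope <- match.arg(scope)
  miss <- setdiff(covariate_names, names(table$covariates))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))

  resid_block <- function(vol, cov) {
    X <- cbind(intercept = 1, as.matrix(cov[, covariate_names, drop = FALSE]))
    if (nrow(X) <= ncol(X)) stop("need more subjects than covariates + intercept")
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop("rank-deficient covariate design; collinear column(s): ", paste(aliased, collapse = ", "))
    }
    qr.resid(qx, vol)
  }

  if (scope == "pooled") {
    table$volumes <- resid_block(table$volumes, table$covariates)
  } else {
    for (g in unique(table$group)) {
      i <- table$group == g
      table$volumes[i, ] <- resid_block(
        table$volumes[i, , drop = FALSE],
        table$covariates[i, , drop = FALSE]
      )
    }
  }
  table$residualized <- TRUE
  table
}

#' Group-level structural covariance matrix
#'
#' Pearson correlation between every pair of regions across the subjects of
#' one group, on corrected (residualized) volumes. The diagonal is set to
#' zero: self-edges are never part of the network.
#'
#' @param table A residualized [morph_table()].
#' @param group Group label selecting the subjects (`"high"` or `"low"`);
#'   `NULL` uses all subjects.
#' @return List of class `cov_network`: `labels`, `weights` (symmetric,
#'   zero-diagonal correlation matrix), `n_subjects`, `group`, and (until
#'   [binarize_at_sparsity()] is applied) `sparsity = NULL`,
#'   `adjacency = NULL`.
#' @export
covariance_matrix <- function(table, group = NULL) {
  stopifnot(inherits(table, "morph_table"))
  if (!table$residualized) {
    warning("volumes are not residualized; correlating raw volumes")
  }
  keep <- if (is.null(group)) rep(TRUE, length(table$subjects)) else table$group == group
  if (sum(keep) < 4) stop("group needs at least 4 subjects, got ", sum(keep))
  vol <- table$volumes[keep, , drop = FALSE]
  sds <- apply(vol, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ", paste(table$regions[sds == 0], collapse = ", "))
  }
  w <- stats::cor(vol)
  diag(w) <- 0
  structure(
    list(
      labels = table$regions, weights = w, n_subjects = sum(keep),
      group = if (is.null(group)) "all" else group,
      sparsity = NULL, adjacency = NULL, n_negative_zeroed = NULL
    ),
    class = "cov_network"
  )
}

#' Zero out negative correlations
#'
#' Only positive correlations count as candidate edges; strictly negative
#' weights are set to zero before thresholding. The number of zeroed entries
#' is stored in `n_negative_zeroed` (off-diagonal cells, both triangles).
#'
#' @param network A `cov_network`.
#' @return The network with non-negative weights.
#' @export
zero_negatives <- function(network) {
  stopifnot(inherits(network, "cov_network"))
  neg <- network$weights < 0
  network$n_negative_zeroed <- sum(neg)
  network$weights[neg] <- 0
  network
}

#' Binarize a covariance network at a fixed sparsity
#'
#' Retains exactly `floor(sparsity * N * (N - 1) / 2)` strongest positive
#' edges, so two groups thresholded at the same sparsity have identical edge
#' counts. Ties at the cutoff weight are broken deterministically by
#' (weight descending, row index ascending, column index ascending). Because
#' retention depends only on weight ranks, the adjacency is invariant to any
#' strictly increasing transform of the weights, and edge sets are nested
#' across increasing sparsity.
#'
#' @param network A `cov_network` with non-negative weights (after
#'   [zero_negatives()]).
#' @param sparsity Fraction of all possible edges to keep, in (0, 1].
#' @return The network with `adjacency` (binary symmetric matrix) and
#'   `sparsity` filled in.
#' @export
binarize_at_sparsity <- function(network, sparsity) {
  stopifnot(inherits(network, "cov_network"))
  if (length(sparsity) != 1 || sparsity <= 0 || sparsity > 1) {
    stop("`sparsity` must be a single value in (0, 1]")
  }
  w <- network$weights
  if (any(w < 0)) stop("weights contain negatives; apply zero_negatives() first")
  n <- nrow(w)
  e_max <- n * (n - 1) / 2
  m <- floor(sparsity * e_max)
  ij <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  n_pos <- sum(wt > 0)
  if (m > n_pos) {
    stop(sprintf(
      "requested %d edges but only %d positive weights; maximum achievable sparsity is %.4f",
      m, n_pos, n_pos / e_max
    ))
  }
  ord <- order(-wt, ij[, 1], ij[, 2])
  keep <- ord[seq_len(m)]
  a <- matrix(0L, n, n, dimnames = dimnames(w))
  a[ij[keep, , drop = FALSE]] <- 1L
  a <- a + t(a)
  network$adjacency <- a
  network$sparsity <- sparsity
  network
}

#' Sparsity threshold grid
#'
#' Inclusive arithmetic sequence of sparsity values, rounded to the decimal
#' precision of the step so floating-point drift never drops the endpoint.
#' The default (0.25, 0.53, 0.01) is the 29-threshold analysis range.
#'
#' @param low,high Grid bounds, `0 < low <= high <= 1`.
#' @param step Positive increment.
#' @return Numeric vector of thresholds.
#' @export
sparsity_grid <- function(low = 0.25, high = 0.53, step = 0.01) {
  if (!(low > 0 && low <= high && high <= 1)) stop("need 0 < low <= high <= 1")
  if (step <= 0) stop("`step` must be positive")
  digits <- 0
  s <- step
  while (digits < 10 && abs(s - round(s)) > 1e-9) {
    s <- s * 10
    digits <- digits + 1
  }
  round(low + step * (0:floor((high - low) / step + 1e-9)), digits)
}

#' @export
print.cov_network <- function(x, ...) {
  cat(
    "cov_network (group ", x$group, "): ", length(x$labels), " regions, n = ",
    x$n_subjects,
    if (!is.null(x$sparsity)) {
      paste0("; binarized at sparsity ", x$sparsity, " (", sum(x$adjacency) / 2, " edges)")
    } else {
      "; weighted"
    }, "\n",
    sep = ""
  )
  invisible(x)
}
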