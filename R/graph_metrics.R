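# Validate a binary symmetric zero-diagonal adjacency matrix and convert to
# an igraph object. All metric functions accept either representation.
as_adjacency <- function(x) {
  if (inherits(x, "cov_network")) {
    if (is.null(x$adjacency)) stop("network is not binarized; call binarize_at_sparsity()")
    x <- x$adjacency
  }
  a <- as.matrix(x)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must have a zero diagonal (no self-loops)")
  if (!all(a %in% c(0, 1))) stop("adjacency must be binary")
  a
}

as_graph <- function(x) {
  igraph::graph_from_adjacency_matrix(as_adjacency(x), mode = "undirected")
}

#' Clustering coefficient
#'
#' Per-node fraction of a node's neighbor pairs that are themselves
#' connected, `2 * triangles / (deg * (deg - 1))`; nodes of degree < 2 score
#' 0. The network value is the unweighted mean over all nodes and indexes
#' segregation.
#'
#' @param adjacency Binary symmetric zero-diagonal matrix (or a binarized
#'   `cov_network`).
#' @return List with `node` (per-node values) and `mean`.
#' @export
clustering_coefficient <- function(adjacency) {
  g <- as_graph(adjacency)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  list(node = cc, mean = mean(cc))
}

#' Characteristic path length
#'
#' Mean breadth-first shortest-path distance over all unordered node pairs
#' with a finite distance; pairs in different connected components are
#' excluded from the mean and their count reported, so disconnection is
#' auditable rather than silently infinite.
#'
#' @inheritParams clustering_coefficient
#' @return List with `mean` (characteristic path length) and
#'   `n_disconnected_pairs`.
#' @export
characteristic_path_length <- function(adjacency) {
  g <- as_graph(adjacency)
  if (igraph::ecount(g) == 0) stop("edgeless graph: no finite node pairs")
  d <- igraph::distances(g)
  du <- d[upper.tri(d)]
  fin <- is.finite(du)
  list(mean = mean(du[fin]), n_disconnected_pairs = sum(!fin))
}

#' Betweenness centrality
#'
#' For each node i, the sum over unordered pairs \{j, k\} (j != i != k) of
#' the fraction of shortest j-k paths that pass through i (endpoints
#' excluded), computed by Brandes accumulation. High-betweenness nodes act as
#' bridges between otherwise distant parts of the network.
#'
#' @inheritParams clustering_coefficient
#' @return Named numeric vector of per-node betweenness values.
#' @export
betweenness_centrality <- function(adjacency) {
  g <- as_graph(adjacency)
  bc <- igraph::betweenness(g, directed = FALSE)
  names(bc) <- igraph::V(g)$name
  bc
}

#' Degree-preserving random networks
#'
#' Maslov-Sneppen double-edge-swap nulls: each null network preserves the
#' node count, edge count and exact degree sequence of the input, with
#' self-loops and multi-edges never introduced. By default `10 * |E|` swaps
#' are attempted per null. For degree sequences admitting no swap (e.g. a
#' complete graph) the nulls equal the input and a warning is raised.
#'
#' @inheritParams clustering_coefficient
#' @param n Number of null networks.
#' @param seed Integer seed; the run is reproducible given (input, n, seed).
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @return List of `n` binary adjacency matrices.
#' @export
random_networks <- function(adjacency, n, seed = NULL, swaps_per_edge = 10) {
  a <- as_adjacency(adjacency)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  ne <- igraph::ecount(g)
  if (n < 1) stop("`n` must be at least 1")
  if (ne < 2) stop("need at least 2 edges to rewire")
  nv <- igraph::vcount(g)
  if (ne == nv * (nv - 1) / 2) {
    warning("complete graph admits no degree-preserving swap; nulls equal the input")
    return(replicate(n, a, simplify = FALSE))
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = swaps_per_edge * ne))
    igraph::as_adjacency_matrix(gr, sparse = FALSE)
  })
}

#' Small-world parameters
#'
#' Clustering coefficient Cp and characteristic path length Lp of the input,
#' normalized by their mean values over `n_random` matched (degree-
#' preserving) random networks: `gamma = Cp / mean(Cp_random)`,
#' `lambda = Lp / mean(Lp_random)`, and small-worldness
#' `sigma = gamma / lambda`. `sigma > 1` marks small-world organization
#' (clustering well above random at near-random path length).
#'
#' @inheritParams clustering_coefficient
#' @param n_random Number of matched random networks (default 100).
#' @param seed Integer seed for the null ensemble.
#' @return List of class `global_metrics`: `clustering`, `path_length`,
#'   `gamma`, `lambda`, `sigma`, `cp_random_mean`, `lp_random_mean`,
#'   `n_random`, `disconnected_pairs`.
#' @export
small_world <- function(adjacency, n_random = 100, seed = NULL) {
  a <- as_adjacency(adjacency)
  cp <- clustering_coefficient(a)$mean
  lp <- characteristic_path_length(a)
  nulls <- random_networks(a, n_random, seed = seed)
  cp_r <- vapply(nulls, function(x) clustering_coefficient(x)$mean, numeric(1))
  lp_r <- vapply(nulls, function(x) characteristic_path_length(x)$mean, numeric(1))
  if (mean(cp_r) == 0) stop("null networks have zero mean clustering; gamma undefined")
  gamma <- cp / mean(cp_r)
  lambda <- lp$mean / mean(lp_r)
  structure(
    list(
      clustering = cp, path_length = lp$mean,
      gamma = gamma, lambda = lambda, sigma = gamma / lambda,
      cp_random_mean = mean(cp_r), lp_random_mean = mean(lp_r),
      n_random = n_random, disconnected_pairs = lp$n_disconnected_pairs
    ),
    class = "global_metrics"
  )
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf(
    "Cp %.4f  Lp %.4f  gamma %.3f  lambda %.3f  sigma %.3f  (%d nulls, %d disconnected pairs)\n",
    x$clustering, x$path_length, x$gamma, x$lambda, x$sigma, x$n_random, x$disconnected_pairs
  ))
  invisible(x)
}

#' Normalize betweenness by the network average
#'
#' Divides each node's betweenness by the mean betweenness over all nodes,
#' so the normalized values average exactly 1 and are comparable across
#' groups and thresholds.
#'
#' @param bc Per-node betweenness values (from [betweenness_centrality()]).
#' @return Per-node normalized values with mean 1.
#' @export
normalize_bc <- function(bc) {
  m <- mean(bc)
  if (m <= 0) stop("network-average betweenness is zero; hub analysis is undefined")
  bc / m
}

#' Identify hub nodes
#'
#' Hubs are nodes whose normalized betweenness exceeds the mean plus one
#' sample standard deviation (denominator N - 1) of the normalized values.
#' Since the normalized values average 1, the threshold is `1 + SD`. A
#' zero-variance profile yields no hubs.
#'
#' @param bc_normalized Per-node normalized betweenness ([normalize_bc()]).
#' @return Indices (named if the input is named) of hub nodes.
#' @export
identify_hubs <- function(bc_normalized) {
  if (length(bc_normalized) < 2) stop("need at least 2 nodes")
  thr <- mean(bc_normalized) + stats::sd(bc_normalized)
  which(bc_normalized > thr)
}

#' Nodal betweenness table for one binarized network
#'
#' Convenience wrapper: betweenness, normalized betweenness and hub flags for
#' every region of a binarized covariance network.
#'
#' @param network A binarized `cov_network`.
#' @return Data frame: `region`, `bc`, `bc_normalized`, `is_hub`.
#' @export
nodal_metrics <- function(network) {
  stopifnot(inherits(network, "cov_network"))
  bc <- betweenness_centrality(network)
  bcn <- normalize_bc(bc)
  hubs <- identify_hubs(bcn)
  data.frame(
    region = network$labels, bc = as.numeric(bc),
    bc_normalized = as.numeric(bcn),
    is_hub = seq_along(bc) %in% hubs
  )
}
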