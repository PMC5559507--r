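#' Weighted node degree
#'
#' Node i's degree is the mean weight of its links, `mean_j W_ij` over
#' `j != i`.
#'
#' @param W A `connectivity_matrix` (or plain symmetric weight matrix).
#' @return Named numeric vector of per-node degrees.
#' @export
node_degree <- function(W) {
  W <- as_weight_matrix(W)
  if (nrow(W) < 2L) stop("need at least 2 nodes", call. = FALSE)
  d <- cpp_graph_core(W)$degree
  names(d) <- rownames(W)
  d
}

# Accept connectivity_matrix or plain matrix; validate shape/symmetry.
as_weight_matrix <- function(W) {
  M <- unclass(as.matrix(W))
  if (nrow(M) != ncol(M)) stop("weight matrix must be square", call. = FALSE)
  if (max(abs(M - t(M))) > 1e-12)
    stop("weight matrix must be symmetric", call. = FALSE)
  if (any(M < 0)) stop("weights must be non-negative", call. = FALSE)
  diag(M) <- 0
  M
}

#' Weighted clustering coefficient
#'
#' Per-node `Ci = sum_{k!=l} Wik Wil Wkl / sum_{k!=l} Wik Wil`; nodes with
#' fewer than two non-zero links have `Ci = 0` by convention. `Cw` is the
#' mean over nodes.
#'
#' @inheritParams node_degree
#' @return List with `ci` (per node) and `cw`.
#' @export
clustering_coefficient <- function(W) {
  W <- as_weight_matrix(W)
  if (nrow(W) < 3L) stop("need at least 3 nodes", call. = FALSE)
  core <- cpp_graph_core(W)
  ci <- core$ci
  names(ci) <- rownames(W)
  list(ci = ci, cw = core$cw)
}

#' Weighted shortest-path length
#'
#' Edge lengths are reciprocal weights (`1/W`, infinite for absent edges);
#' `L_ij` is the shortest-path distance and the average `Lw` uses the
#' harmonic-mean form `Lw = 1 / mean(1/L_ij)` over ordered pairs, so
#' disconnected pairs (with `1/L = 0`) are handled gracefully.
#'
#' @inheritParams node_degree
#' @return List with `L` (pairwise distance matrix) and `lw`.
#' @export
path_length <- function(W) {
  W <- as_weight_matrix(W)
  if (nrow(W) < 2L) stop("need at least 2 nodes", call. = FALSE)
  core <- cpp_graph_core(W)
  L <- core$dist
  dimnames(L) <- dimnames(W)
  list(L = L, lw = core$lw)
}

#' Degree correlation (assortativity)
#'
#' Pearson correlation of the degrees of linked node pairs, computed over
#' both orderings of every undirected edge. Undefined (zero degree
#' variance, e.g. regular graphs) yields `NaN`, never a silent 0.
#'
#' @inheritParams node_degree
#' @return Scalar `Rw`, possibly `NaN`.
#' @export
degree_correlation <- function(W) {
  W <- as_weight_matrix(W)
  cpp_graph_core(W)$rw
}

#' Degree diversity
#'
#' `Kw = <degree^2> / <degree>`, the ratio of the second to the first
#' moment of the node degree distribution, computed on node strength (sum
#' of link weights) following the weighted-network convention; a proxy for
#' hub prevalence.
#'
#' @inheritParams node_degree
#' @return Scalar `Kw`.
#' @export
degree_diversity <- function(W) {
  W <- as_weight_matrix(W)
  if (all(W == 0)) stop("zero matrix: Kw undefined", call. = FALSE)
  cpp_graph_core(W)$kw
}

#' Radius and diameter
#'
#' Node eccentricity is `max_j L_ij`; the radius is the minimum and the
#' diameter the maximum eccentricity. Disconnected graphs give infinite
#' values for both.
#'
#' @inheritParams node_degree
#' @return Named numeric vector `c(radius, diameter)`.
#' @export
radius_diameter <- function(W) {
  W <- as_weight_matrix(W)
  if (nrow(W) < 2L) stop("need at least 2 nodes", call. = FALSE)
  core <- cpp_graph_core(W)
  c(radius = core$radius, diameter = core$diameter)
}

#' Surrogate-normalised clustering and path length
#'
#' Surrogates are generated by randomly permuting the off-diagonal
#' upper-triangle weights (symmetry and the weight distribution are
#' preserved); `Cr` and `Lr` are the surrogate means of `Cw` and `Lw`, and
#' `Gamma = Cw/Cr`, `Lambda = Lw/Lr`. A degenerate matrix whose
#' off-diagonal weights are all equal returns exactly 1 for both (every
#' permutation is identical).
#'
#' @inheritParams node_degree
#' @param n_surrogates Number of surrogate matrices (default 50).
#' @param seed Integer seed for the permutations.
#' @param perms Optional explicit permutation matrix (`n_surrogates` rows,
#'   one 1-based permutation of the upper-triangle slots per row);
#'   overrides `seed`. Exposed for reproducibility checks.
#' @return Named numeric vector `c(gamma, lambda)` with attributes `cr`,
#'   `lr` and `n_surrogates`.
#' @export
surrogate_normalize <- function(W, n_surrogates = 50L, seed = 1L,
                                perms = NULL) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  if (n < 4L) stop("need at least 4 nodes", call. = FALSE)
  ut <- W[upper.tri(W)]
  core <- cpp_graph_core(W)
  if (length(unique(ut)) == 1L) {
    out <- c(gamma = 1, lambda = 1)
    attr(out, "cr") <- core$cw
    attr(out, "lr") <- core$lw
    attr(out, "n_surrogates") <- 0L
    return(out)
  }
  E <- length(ut)
  if (is.null(perms)) {
    set.seed(seed)
    perms <- make_perms(E, n_surrogates)
  }
  storage.mode(perms) <- "integer"
  cl <- cpp_surrogate_cl(W, perms)
  cr <- mean(cl[, "cw"])
  lr <- mean(cl[, "lw"])   # any disconnected surrogate makes Lr infinite
  out <- c(gamma = core$cw / cr, lambda = core$lw / lr)
  attr(out, "cr") <- cr
  attr(out, "lr") <- lr
  attr(out, "n_surrogates") <- nrow(perms)
  out
}

#' All eight weighted graph measures for one connectivity matrix
#'
#' Degree (mean link weight, reported as its node average), average
#' clustering coefficient `Cw` and its surrogate-normalised `Gamma`,
#' average path length `Lw` and its normalised `Lambda`, degree correlation
#' `Rw`, degree diversity `Kw`, and radius/diameter.
#'
#' @inheritParams surrogate_normalize
#' @return One-row data frame with columns `degree`, `cw`, `gamma`, `lw`,
#'   `lambda`, `rw`, `kw`, `radius`, `diameter`, `n_surrogates`.
#' @export
graph_metrics <- function(W, n_surrogates = 50L, seed = 1L) {
  M <- as_weight_matrix(W)
  core <- cpp_graph_core(M)
  gl <- surrogate_normalize(M, n_surrogates, seed)
  data.frame(degree = mean(core$degree), cw = core$cw,
             gamma = unname(gl["gamma"]), lw = core$lw,
             lambda = unname(gl["lambda"]), rw = core$rw, kw = core$kw,
             radius = core$radius, diameter = core$diameter,
             n_surrogates = attr(gl, "n_surrogates"))
}

#' Exhaustive oracle-equivalence sweep of the graph measures
#'
#' Enumerates every weighted graph on `n_nodes` nodes whose edge weights
#' are drawn from `weight_levels`, and compares all eight measures
#' (including `Gamma`/`Lambda` from identical surrogate permutation
#' streams) between the production implementation (Floyd-Warshall and
#' direct sums) and an independent brute-force oracle that enumerates every
#' simple path and recomputes each definition from scratch. Used by the
#' package's validation tests.
#'
#' @param n_nodes Number of nodes (2-6).
#' @param weight_levels Numeric vector of admissible edge weights.
#' @param n_surrogates Surrogates per graph for `Gamma`/`Lambda`.
#' @param seed Seed for the shared permutation stream.
#' @return List with `n_graphs` and `max_abs_diff` (named vector of maximum
#'   absolute discrepancies per measure).
#' @export
validate_graph_metrics <- function(n_nodes, weight_levels = c(0, 0.25, 0.5, 1),
                                   n_surrogates = 20L, seed = 1L) {
  E <- n_nodes * (n_nodes - 1L) / 2L
  set.seed(seed)
  perms <- make_perms(E, n_surrogates)
  cpp_validate_graphs(as.integer(n_nodes), as.numeric(weight_levels), perms)
}

# n_perm x E matrix, one permutation of seq_len(E) per row (uses the
# current RNG state).
make_perms <- function(E, n_perm) {
  p <- matrix(0L, n_perm, E)
  for (i in seq_len(n_perm)) p[i, ] <- sample.int(E)
  p
}
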