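# Network metrics over symmetric nonnegative adjacency matrices.
# Binary metrics are pure matrix algebra; shortest paths go through igraph.

as_graph <- function(adj, mode = "binary") {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

check_adj <- function(adj, what = "adjacency") {
  assert_symmetric(adj, what)
  if (any(adj < 0)) stop(what, " must have nonnegative weights", call. = FALSE)
  diag(adj) <- 0
  adj
}

#' Clustering coefficient
#'
#' Binary mode: per-node fraction of closed triangles among pairs of
#' neighbours (0 for degree < 2). Weighted mode: Onnela variant — geometric
#' mean of the triangle's weights after scaling by the maximum weight,
#' averaged over neighbour pairs.
#'
#' @param adj symmetric nonnegative matrix, zero diagonal.
#' @param mode `"binary"` or `"weighted"`.
#' @return list with `node` (per-node coefficients) and `mean`.
#' @export
#' @examples
#' k3 <- matrix(1, 3, 3); diag(k3) <- 0
#' clustering_coefficient(k3)$mean  # 1
clustering_coefficient <- function(adj, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  adj <- check_adj(adj)
  a <- (adj > 0) + 0
  k <- rowSums(a)
  if (mode == "binary") {
    tri <- diag(a %*% a %*% a) / 2
  } else {
    if (max(adj) == 0) {
      tri <- rep(0, nrow(adj))
    } else {
      w <- (adj / max(adj))^(1 / 3)
      tri <- diag(w %*% w %*% w) / 2
    }
  }
  ci <- ifelse(k < 2, 0, tri / (k * (k - 1) / 2))
  names(ci) <- rownames(adj)
  list(node = ci, mean = mean(ci))
}

pairwise_distances <- function(adj, mode) {
  g <- as_graph(adj)
  w <- if (mode == "weighted") 1 / igraph::E(g)$weight else NA
  igraph::distances(g, weights = w)
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected node pairs; weighted mode maps
#' each weight w to a length 1/w. Disconnected pairs are excluded with a
#' warning and their count attached as attribute `excluded_pairs`.
#'
#' @inheritParams clustering_coefficient
#' @return numeric path length (attribute `excluded_pairs`).
#' @export
characteristic_path_length <- function(adj, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  adj <- check_adj(adj)
  d <- pairwise_distances(adj, mode)
  dv <- d[upper.tri(d)]
  finite <- is.finite(dv)
  if (!any(finite)) stop("graph has no edges: path length undefined", call. = FALSE)
  n_excl <- sum(!finite)
  if (n_excl > 0) {
    warning(n_excl, " disconnected pair(s) excluded from path length")
  }
  structure(mean(dv[finite]), excluded_pairs = n_excl)
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all node pairs, with disconnected
#' pairs contributing 0 — a path-length analogue that stays defined on
#' fragmented networks.
#'
#' @inheritParams clustering_coefficient
#' @return numeric in `[0, 1]` for binary graphs.
#' @export
global_efficiency <- function(adj, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  adj <- check_adj(adj)
  d <- pairwise_distances(adj, mode)
  dv <- d[upper.tri(d)]
  mean(ifelse(is.finite(dv) & dv > 0, 1 / dv, 0))
}

#' Degree-preserving rewired null ensemble
#'
#' Generates `n` randomized versions of a binary graph by double-edge
#' swaps (10 x |E| attempted swaps each), preserving the number of nodes,
#' total edges and the exact degree sequence. Graphs with no rewirable
#' edge pair (e.g. complete graphs) are returned as copies with a warning.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param n ensemble size (default 20).
#' @param seed integer seed.
#' @return `null_ensemble` object: list of adjacency matrices + metadata.
#' @export
rewire_null <- function(adj, n = 20L, seed = 1L) {
  adj <- check_adj(adj)
  if (!all(adj %in% c(0, 1))) stop("rewire_null expects a binary adjacency matrix", call. = FALSE)
  g <- as_graph(adj)
  m <- igraph::ecount(g)
  n_nodes <- nrow(adj)
  complete <- m == n_nodes * (n_nodes - 1) / 2
  graphs <- if (m < 2 || complete) {
    warning("no rewirable edge pairs: returning copies of the input graph")
    replicate(n, adj, simplify = FALSE)
  } else {
    with_seed(seed, lapply(seq_len(n), function(i) {
      r <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
      out <- igraph::as_adjacency_matrix(r, sparse = FALSE)
      dimnames(out) <- dimnames(adj)
      out
    }))
  }
  deg <- rowSums(adj)
  for (gm in graphs) {
    stopifnot(identical(rowSums(gm), deg))
  }
  structure(list(graphs = graphs, n = length(graphs), seed = seed),
            class = "null_ensemble")
}

#' Small-worldness against a null ensemble
#'
#' `gamma` = clustering ratio C/C_random, `lambda` = path-length ratio
#' L/L_random, `sigma` = gamma/lambda. A small-world network has gamma > 1
#' with lambda close to 1, hence sigma > 1.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param ensemble a [rewire_null()] ensemble.
#' @return list with `c`, `l`, `c_random`, `l_random`, `gamma`, `lambda`,
#'   `sigma`.
#' @export
small_worldness <- function(adj, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  adj <- check_adj(adj)
  c_obs <- clustering_coefficient(adj)$mean
  l_obs <- suppressWarnings(as.numeric(characteristic_path_length(adj)))
  c_rand <- mean(vapply(ensemble$graphs, function(g) clustering_coefficient(g)$mean, 0))
  l_rand <- mean(vapply(ensemble$graphs, function(g) {
    suppressWarnings(as.numeric(characteristic_path_length(g)))
  }, 0))
  gamma <- c_obs / c_rand
  lambda <- l_obs / l_rand
  list(c = c_obs, l = l_obs, c_random = c_rand, l_random = l_rand,
       gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Binarize a weighted network at a target edge density
#'
#' Keeps the `floor(density * n * (n - 1) / 2)` largest positive weights.
#' Ties at the cut are broken by lexicographic ROI-pair order so the output
#' is reproducible; zero or negative weights are never kept.
#'
#' @param weighted `group_connectome` (weighted) or plain symmetric matrix.
#' @param density target density in (0, 1].
#' @return binary symmetric adjacency matrix.
#' @export
threshold_at_density <- function(weighted, density) {
  w <- if (inherits(weighted, "group_connectome")) weighted$weights else weighted
  w <- check_adj(w, "weighted matrix")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]", call. = FALSE)
  wv <- upper_vec(w)
  k <- floor(density * length(wv))
  keep <- logical(length(wv))
  # decreasing weight, ties broken by lexicographic (row, col) pair order
  lex <- (row(w)[upper.tri(w)] - 1) * nrow(w) + col(w)[upper.tri(w)]
  ord <- order(-wv, lex)
  ord <- ord[wv[ord] > 0]
  keep[utils::head(ord, k)] <- TRUE
  sym_from_upper(keep + 0, rownames(w))
}
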