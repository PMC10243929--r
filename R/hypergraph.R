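#' Hyperedges from Louvain communities of a KNN affinity graph
#'
#' Sparsifies the affinity matrix to a KNN graph, runs Louvain community
#' detection on it, and returns each community as one hyperedge (a vertex-index
#' set). Singleton communities are merged into the community containing their
#' most similar neighbour, so every hyperedge has at least 2 members.
#'
#' @param A Symmetric non-negative sample similarity matrix.
#' @param knn_k Neighbourhood size for the KNN sparsification
#'   (default `floor(n/2)`).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed Integer seed controlling Louvain's randomized sweep.
#' @return List of integer vectors (vertex indices), one per hyperedge.
#' @export
build_hyperedges_louvain <- function(A, knn_k = NULL, resolution = 1, seed = 1L) {
  n <- nrow(A)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (is.null(knn_k)) knn_k <- max(1L, n %/% 2L)
  W <- knn_graph(A, knn_k)
  if (all(W == 0)) stop("KNN graph has no edges", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comm <- withr::with_seed(as.integer(seed), {
    igraph::cluster_louvain(g, resolution = resolution)
  })
  mem <- igraph::membership(comm)
  # merge singleton communities into their most similar neighbour's community
  repeat {
    sizes <- table(mem)
    singles <- as.integer(names(sizes)[sizes == 1])
    if (length(singles) == 0) break
    cid <- singles[1]
    v <- which(mem == cid)
    s <- A[v, ]
    s[v] <- -Inf
    s[mem == cid] <- -Inf
    nb <- order(-s, seq_len(n))[1]
    mem[v] <- mem[nb]
  }
  ids <- sort(unique(mem))
  lapply(ids, function(cid) which(mem == cid))
}

#' Gaussian-kernel weight of one hyperedge
#'
#' The weight is the total pairwise similarity inside the hyperedge: the sum
#' over unordered sample pairs of `exp(-d2(u,v) / (2*s2_e))`, where the
#' bandwidth `s2_e` is the mean squared Euclidean distance over those pairs.
#' When all members coincide (`s2_e = 0`) each pair contributes the kernel's
#' continuous limit 1, so the weight equals the number of pairs.
#'
#' @param X Feature-by-sample matrix whose columns are the samples.
#' @param vertices Integer vector of >= 2 sample (column) indices.
#' @return Positive scalar weight.
#' @export
hyperedge_weight <- function(X, vertices) {
  if (length(vertices) < 2) stop("a hyperedge needs at least 2 vertices", call. = FALSE)
  v <- unclass(X)[, vertices, drop = FALSE]
  d2 <- as.matrix(stats::dist(t(v)))^2
  pairs <- d2[upper.tri(d2)]
  s2 <- mean(pairs)
  if (s2 == 0) return(length(pairs))
  sum(exp(-pairs / (2 * s2)))
}

#' Assemble a weighted hypergraph from hyperedges
#'
#' Builds the binary incidence matrix P (vertices x hyperedges), hyperedge
#' weights via [hyperedge_weight()] on `X`, vertex degrees
#' `d_v = sum_e w_e P[v,e]` and hyperedge degrees `delta_e = sum_v P[v,e]`.
#'
#' @param X Feature-by-sample matrix used for the kernel weights.
#' @param hyperedges List of integer vertex sets, e.g. from
#'   [build_hyperedges_louvain()].
#' @param n_vertices Number of vertices (default `ncol(X)`).
#' @return An object of class `hypergraph`: list with `incidence`, `weights`,
#'   `vertex_degrees`, `hyperedge_degrees`, `hyperedges`, `sample_ids`.
#' @export
build_hypergraph <- function(X, hyperedges, n_vertices = ncol(X)) {
  if (length(hyperedges) == 0) stop("no hyperedges", call. = FALSE)
  P <- matrix(0, n_vertices, length(hyperedges))
  for (e in seq_along(hyperedges)) P[hyperedges[[e]], e] <- 1
  if (any(colSums(P) < 2)) stop("every hyperedge must have >= 2 vertices", call. = FALSE)
  if (any(rowSums(P) == 0)) stop("every vertex must belong to a hyperedge", call. = FALSE)
  w <- vapply(hyperedges, function(e) hyperedge_weight(X, e), 0)
  structure(list(
    incidence = P,
    weights = w,
    vertex_degrees = as.numeric(P %*% w),
    hyperedge_degrees = colSums(P),
    hyperedges = hyperedges,
    sample_ids = colnames(X)
  ), class = "hypergraph")
}

#' Hypergraph Laplacian
#'
#' `L = D_v - P W D_e^{-1} P^T`, with D_v the diagonal of weighted vertex
#' degrees, W the diagonal hyperedge weights and D_e the diagonal hyperedge
#' degrees. L is symmetric positive semi-definite with zero row sums; its
#' quadratic form penalizes disagreement of latent factors within hyperedges.
#'
#' @param hg A `hypergraph` from [build_hypergraph()].
#' @return Symmetric n x n Laplacian matrix.
#' @export
hypergraph_laplacian <- function(hg) {
  P <- hg$incidence
  L <- diag(hg$vertex_degrees, nrow(P)) -
    P %*% (hg$weights / hg$hyperedge_degrees * t(P))
  L <- (L + t(L)) / 2
  if (!is.null(hg$sample_ids)) dimnames(L) <- list(hg$sample_ids, hg$sample_ids)
  L
}

#' Hypergraph smoothness regularizer Tr(H' L H)
#'
#' Equals `(1/2) * sum_e sum_{i,j in e} (w_e/delta_e) * ||h_i - h_j||^2`:
#' zero when rows of H are constant within every hyperedge.
#'
#' @param H Non-negative n x k factor matrix.
#' @param L Hypergraph (or simple-graph) Laplacian.
#' @return Non-negative scalar.
#' @export
hypergraph_regularizer <- function(H, L) {
  if (nrow(H) != nrow(L)) stop("dimension mismatch", call. = FALSE)
  sum(H * (L %*% H))
}

#' Simple-graph Laplacian of a KNN-sparsified affinity
#'
#' `L = D - W` on the KNN graph of `A`; the pairwise-interaction counterpart
#' used by the GONMF ablation in place of the hypergraph Laplacian.
#'
#' @param A Symmetric similarity matrix.
#' @param knn_k KNN sparsification size (default `floor(n/2)`).
#' @return Symmetric PSD Laplacian with zero row sums.
#' @export
simple_graph_laplacian <- function(A, knn_k = NULL) {
  n <- nrow(A)
  if (is.null(knn_k)) knn_k <- max(1L, n %/% 2L)
  W <- knn_graph(A, knn_k)
  L <- diag(rowSums(W), n) - W
  (L + t(L)) / 2
}

#' Export hyperedges as a plain-text list
#'
#' One line per hyperedge: weight, tab, tab-separated member sample ids.
#'
#' @param hg A `hypergraph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hyperedges <- function(hg, path) {
  ids <- hg$sample_ids
  if (is.null(ids)) ids <- as.character(seq_len(nrow(hg$incidence)))
  lines <- vapply(seq_along(hg$hyperedges), function(e) {
    paste(c(format(hg$weights[e], digits = 17),
            ids[hg$hyperedges[[e]]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
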