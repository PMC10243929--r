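#' Gaussian-kernel sample affinity matrix
#'
#' Computes the n x n sample similarity `A[u,v] = exp(-d2(u,v) / (2 * s2_uv))`
#' from the Euclidean distances between sample columns of `X`. The bandwidth
#' `s2_uv` follows `bandwidth_rule`:
#' \describe{
#'   \item{local_scaling}{`s2_uv = s_u * s_v * scale^2`, where `s_u` is sample
#'     u's mean distance to its `k_local` nearest neighbours (self-tuning
#'     bandwidth; the default, robust to density variation).}
#'   \item{median_sqdist / mean_sqdist}{one global bandwidth, the median/mean of
#'     the off-diagonal squared distances, times `scale^2`.}
#' }
#' A fixed bandwidth can be forced with `sigma2`, which overrides the rule.
#'
#' @param X Abundance matrix (features x samples); affinities are between columns.
#' @param bandwidth_rule Bandwidth selection rule, see Details.
#' @param scale Positive multiplier on the selected bandwidth (default 1).
#' @param sigma2 Optional fixed squared bandwidth overriding `bandwidth_rule`.
#' @param k_local Neighbourhood size for local scaling (default `min(5, n-1)`).
#' @return Symmetric n x n matrix with unit diagonal and entries in (0, 1],
#'   dimnames = sample ids.
#' @export
gaussian_affinity <- function(X,
                              bandwidth_rule = c("local_scaling", "median_sqdist",
                                                 "mean_sqdist"),
                              scale = 1,
                              sigma2 = NULL,
                              k_local = NULL) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  stopifnot(scale > 0)
  v <- unclass(X)
  n <- ncol(v)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  d <- as.matrix(stats::dist(t(v)))
  d2 <- d^2
  off <- d2[upper.tri(d2)]
  if (is.null(sigma2)) {
    if (all(off == 0)) {
      stop("all samples are identical; supply a fixed bandwidth via `sigma2`",
           call. = FALSE)
    }
    s2 <- switch(bandwidth_rule,
      median_sqdist = matrix(stats::median(off) * scale^2, n, n),
      mean_sqdist = matrix(mean(off) * scale^2, n, n),
      local_scaling = {
        if (is.null(k_local)) k_local <- min(5L, n - 1L)
        s_u <- vapply(seq_len(n), function(u) {
          mean(sort(d[u, -u])[seq_len(k_local)])
        }, 0)
        s_u[s_u == 0] <- min(s_u[s_u > 0], 1)
        outer(s_u, s_u) * scale^2
      })
  } else {
    stopifnot(sigma2 > 0)
    s2 <- matrix(sigma2, n, n)
  }
  A <- exp(-d2 / (2 * s2))
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- list(colnames(v), colnames(v))
  A
}

#' Sparsify a similarity matrix to a k-nearest-neighbour graph
#'
#' Each row keeps its `k` largest off-diagonal similarities (ties broken by
#' lowest sample index); the result is symmetrized by union, i.e. an edge is
#' kept if either endpoint selects it. Self-edges are removed.
#'
#' @param S Symmetric similarity matrix.
#' @param k Neighbourhood size, `1 <= k <= n-1`.
#' @return n x n matrix with the retained similarities, zero elsewhere.
#' @export
knn_graph <- function(S, k) {
  n <- nrow(S)
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]", call. = FALSE)
  mask <- matrix(FALSE, n, n)
  for (u in seq_len(n)) {
    s <- S[u, ]
    s[u] <- -Inf
    nb <- order(-s, seq_len(n))[seq_len(k)]
    mask[u, nb] <- TRUE
  }
  mask <- mask | t(mask)
  W <- ifelse(mask, S, 0)
  diag(W) <- 0
  dimnames(W) <- dimnames(S)
  W
}

snf_normalize <- function(W) {
  rs <- rowSums(W) - diag(W)
  rs[rs == 0] <- 1
  P <- W / (2 * rs)
  diag(P) <- 0.5
  P
}

snf_local_kernel <- function(W, k) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (u in seq_len(n)) {
    s <- W[u, ]
    s[u] <- -Inf
    nb <- order(-s, seq_len(n))[seq_len(k)]
    S[u, nb] <- W[u, nb]
  }
  rs <- rowSums(S)
  rs[rs == 0] <- 1
  S / rs
}

#' Fuse per-modality similarity matrices (minimal SNF)
#'
#' Runs the standard similarity-network-fusion cross-diffusion: each modality's
#' row-normalized full kernel is iteratively updated through its KNN-sparsified
#' local kernel and the average of the other modalities' kernels, then the
#' fused matrix is the average of the diffused kernels, renormalized and
#' symmetrized. Used here only to initialize the consensus similarity.
#' A single-matrix input is returned row-normalized and symmetrized unchanged
#' (there is nothing to fuse).
#'
#' @param A_list List of >= 1 symmetric similarity matrices on a common sample
#'   order.
#' @param k_neighbors Local-kernel neighbourhood size; default `max(3, floor(n/10))`.
#' @param iterations Number of diffusion iterations (default 20).
#' @return Fused symmetric non-negative similarity matrix.
#' @export
snf_fuse <- function(A_list, k_neighbors = NULL, iterations = 20L) {
  if (!is.list(A_list) || length(A_list) < 1) {
    stop("A_list must be a non-empty list of similarity matrices", call. = FALSE)
  }
  n <- nrow(A_list[[1]])
  if (any(vapply(A_list, function(a) nrow(a) != n || ncol(a) != n, TRUE))) {
    stop("similarity matrices have mismatched dimensions", call. = FALSE)
  }
  if (is.null(k_neighbors)) k_neighbors <- max(3L, n %/% 10L)
  k_neighbors <- min(k_neighbors, n - 1L)

  P <- lapply(A_list, function(a) {
    p <- snf_normalize(a)
    (p + t(p)) / 2
  })
  if (length(P) == 1L) {
    out <- P[[1]]
    dimnames(out) <- dimnames(A_list[[1]])
    return(out)
  }
  Sk <- lapply(A_list, snf_local_kernel, k = k_neighbors)
  M <- length(P)
  for (iter in seq_len(iterations)) {
    P_new <- vector("list", M)
    for (v in seq_len(M)) {
      others <- Reduce(`+`, P[-v]) / (M - 1)
      p <- Sk[[v]] %*% others %*% t(Sk[[v]])
      p <- snf_normalize(p)
      P_new[[v]] <- (p + t(p)) / 2
    }
    P <- P_new
  }
  W <- Reduce(`+`, P) / M
  W <- snf_normalize(W)
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(A_list[[1]])
  W
}

#' Write / read a similarity matrix as TSV with sample-id header and row names
#'
#' @param S Similarity matrix with sample-id dimnames.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_similarity <- function(S, path) {
  df <- data.frame(sample_id = rownames(S), as.data.frame(unclass(S)),
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
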