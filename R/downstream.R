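#' Cluster samples from a consensus similarity matrix
#'
#' Default method mirrors the model's clustering protocol: build a KNN graph
#' with `k = floor(n/2)` from S and run Louvain community detection on it.
#' Louvain chooses its own number of communities; `method = "spectral_k"`
#' (normalized spectral clustering of S followed by k-means) is provided for
#' when an exact cluster count must be imposed.
#'
#' @param S Symmetric non-negative sample similarity matrix with sample-id
#'   dimnames.
#' @param seed Integer seed (Louvain sweep order / k-means starts).
#' @param method `"louvain"` (default) or `"spectral_k"`.
#' @param k_clusters Required for `"spectral_k"`: the number of clusters.
#' @param knn_k KNN size for the Louvain graph; default `floor(n/2)`.
#' @return Named integer vector of 0-based, contiguous cluster labels.
#' @export
cluster_samples <- function(S, seed = 1L,
                            method = c("louvain", "spectral_k"),
                            k_clusters = NULL, knn_k = NULL) {
  method <- match.arg(method)
  n <- nrow(S)
  if (n < 4) stop("need at least 4 samples to cluster", call. = FALSE)
  ids <- rownames(S)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))

  if (method == "louvain") {
    if (is.null(knn_k)) knn_k <- max(1L, n %/% 2L)
    W <- knn_graph(S, knn_k)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    mem <- withr::with_seed(as.integer(seed), {
      igraph::membership(igraph::cluster_louvain(g))
    })
    labels <- as.integer(factor(mem, levels = unique(mem))) - 1L
  } else {
    if (is.null(k_clusters)) stop("spectral_k requires k_clusters", call. = FALSE)
    d <- rowSums(S)
    d[d <= 0] <- 1
    Dm <- 1 / sqrt(d)
    Snorm <- S * outer(Dm, Dm)
    es <- eigen((Snorm + t(Snorm)) / 2, symmetric = TRUE)
    U <- es$vectors[, seq_len(k_clusters), drop = FALSE]
    rn <- sqrt(rowSums(U^2))
    rn[rn == 0] <- 1
    U <- U / rn
    km <- withr::with_seed(as.integer(seed), {
      stats::kmeans(U, centers = k_clusters, nstart = 25, iter.max = 100)
    })
    labels <- as.integer(factor(km$cluster, levels = unique(km$cluster))) - 1L
  }
  stats::setNames(labels, ids)
}

#' Laplacian score of one feature on the sample-similarity graph
#'
#' With `D = diag(rowSums(S))` and `L = D - S`, the feature vector is
#' D-centred, `ft = f - (f'D1 / 1'D1) 1`, and scored as
#' `SC(f) = (ft' L ft) / (ft' D ft)`. Features smooth on the similarity graph
#' but with high weighted variance score low; the minimal scores mark the most
#' discriminative features. The score is invariant to scaling and shifting of
#' `f`. A (D-weighted) constant feature has an undefined score and returns
#' `Inf` with a warning, so it is never selected.
#'
#' @param f Numeric vector of one feature's abundance over the n samples.
#' @param S Symmetric non-negative n x n similarity matrix.
#' @return Non-negative scalar (or `Inf` for a degenerate feature).
#' @export
laplacian_score <- function(f, S) {
  n <- length(f)
  if (nrow(S) != n) stop("feature length does not match S", call. = FALSE)
  d <- rowSums(S)
  ft <- f - sum(f * d) / sum(d)
  denom <- sum(ft^2 * d)
  if (denom <= 1e-300) {
    warning("constant feature: Laplacian score undefined, returning Inf",
            call. = FALSE)
    return(Inf)
  }
  num <- sum(ft * (d * ft - as.vector(S %*% ft)))
  num / denom
}

#' Rank features by Laplacian score and keep the most discriminative
#'
#' Scores every row of `X` with [laplacian_score()], drops zero-variance
#' features (undefined score), sorts ascending (ties broken by feature index)
#' and returns the `top_k` best-ranked features.
#'
#' @param X Abundance matrix (features x samples).
#' @param S Sample similarity matrix (e.g. the consensus S of a fit).
#' @param top_k Number of features to keep; default all scored features.
#' @param modality Optional modality name recorded in the output.
#' @return A tibble: `feature_id`, `modality`, `score`, `rank` (1 = most
#'   discriminative), `top_k` rows.
#' @export
select_top_features <- function(X, S, top_k = NULL, modality = NA_character_) {
  v <- unclass(X)
  keep <- apply(v, 1, function(f) stats::var(f) > 0)
  scores <- rep(Inf, nrow(v))
  scores[keep] <- apply(v[keep, , drop = FALSE], 1, laplacian_score, S = S)
  n_scored <- sum(is.finite(scores))
  if (is.null(top_k)) top_k <- n_scored
  if (top_k > n_scored) stop("top_k exceeds the number of scorable features",
                             call. = FALSE)
  ord <- order(scores, seq_along(scores))[seq_len(n_scored)]
  tibble::tibble(
    feature_id = rownames(v)[ord],
    modality = modality,
    score = scores[ord],
    rank = seq_len(n_scored))[seq_len(top_k), ]
}

#' Similarity-smoothed correlation between two features
#'
#' Each feature (a 1 x n row vector) is smoothed by right-multiplication with
#' the sample-similarity matrix, `ahat = a S`, and the Pearson correlation of
#' the smoothed vectors is returned. If a smoothed vector is constant the
#' correlation is undefined; 0 is returned with a warning.
#'
#' @param a,b Numeric feature vectors of length n.
#' @param S n x n sample similarity matrix.
#' @return Correlation in \[-1, 1\].
#' @export
smoothed_correlation <- function(a, b, S) {
  ah <- as.vector(a %*% S)
  bh <- as.vector(b %*% S)
  if (stats::sd(ah) == 0 || stats::sd(bh) == 0) {
    warning("smoothed feature is constant: correlation undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  stats::cor(ah, bh)
}

#' Cross-kingdom association network from smoothed correlations
#'
#' Selects the most discriminative features of each modality (Laplacian score),
#' computes the smoothed correlation for every cross-modality feature pair, and
#' retains edges with `|corr| > threshold`. The full pairwise correlation
#' matrices for each modality pair are attached as the `"correlations"`
#' attribute (heat-map ready).
#'
#' @param dataset A `multiomics_dataset`.
#' @param S Consensus sample similarity matrix.
#' @param per_modality_top Integer vector: how many top features per modality
#'   (recycled; default 10).
#' @param threshold Retain edges with `|corr| > threshold` (default 0.5).
#' @return A tibble of edges: `feature_a`, `modality_a`, `feature_b`,
#'   `modality_b`, `corr`, `sign` (`"positive"`/`"negative"`), with attribute
#'   `"correlations"` (named list of full cross-correlation matrices).
#' @export
association_network <- function(dataset, S, per_modality_top = 10,
                                threshold = 0.5) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)",
                                            call. = FALSE)
  M <- length(dataset)
  mods <- names(dataset)
  tops <- rep_len(per_modality_top, M)
  sel <- lapply(seq_len(M), function(m) {
    select_top_features(dataset[[m]], S,
                        top_k = min(tops[m], sum(apply(unclass(dataset[[m]]), 1,
                                                       stats::var) > 0)),
                        modality = mods[m])
  })
  edges <- list()
  mats <- list()
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      fi <- sel[[i]]$feature_id
      fj <- sel[[j]]$feature_id
      cm <- matrix(NA_real_, length(fi), length(fj), dimnames = list(fi, fj))
      for (a in seq_along(fi)) {
        for (b in seq_along(fj)) {
          cm[a, b] <- smoothed_correlation(
            unclass(dataset[[i]])[fi[a], ],
            unclass(dataset[[j]])[fj[b], ], S)
        }
      }
      mats[[paste(mods[i], mods[j], sep = "-")]] <- cm
      hit <- which(abs(cm) > threshold, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        edges[[length(edges) + 1]] <- tibble::tibble(
          feature_a = fi[hit[, 1]], modality_a = mods[i],
          feature_b = fj[hit[, 2]], modality_b = mods[j],
          corr = cm[hit])
      }
    }
  }
  out <- if (length(edges)) {
    dplyr::arrange(dplyr::bind_rows(edges), dplyr::desc(abs(.data$corr)))
  } else {
    tibble::tibble(feature_a = character(), modality_a = character(),
                   feature_b = character(), modality_b = character(),
                   corr = numeric())
  }
  out$sign <- ifelse(out$corr >= 0, "positive", "negative")
  attr(out, "correlations") <- mats
  out
}

#' Export an association network
#'
#' Writes the edge list as TSV and, optionally, as GraphML for network viewers
#' (solid/dashed convention carried in the `sign` edge attribute).
#'
#' @param edges Edge tibble from [association_network()].
#' @param path Output TSV path.
#' @param graphml Optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_association_network <- function(edges, path, graphml = NULL) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml)) {
    verts <- unique(data.frame(
      name = c(edges$feature_a, edges$feature_b),
      modality = c(edges$modality_a, edges$modality_b)))
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$feature_a, to = edges$feature_b,
                 corr = edges$corr, sign = edges$sign),
      directed = FALSE, vertices = verts)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' Plot a feature-score ranking
#'
#' @param scores Tibble from [select_top_features()].
#' @return A ggplot bar chart of Laplacian scores, best rank on top.
#' @export
plot_feature_scores <- function(scores) {
  df <- dplyr::mutate(scores,
                      feature_id = stats::reorder(.data$feature_id,
                                                  -.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Laplacian score (lower = more discriminative)",
                  y = NULL)
}
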