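#' Normalized mutual information between two partitions
#'
#' `NMI(G, P) = MI(G, P) / sqrt(H(G) * H(P))` with natural logarithms
#' (geometric-mean normalization, the standard convention). Values lie in
#' \[0, 1\]; 1 means identical partitions up to label permutation. If either
#' partition has a single cluster its entropy is 0 and the ratio is undefined:
#' 1 is returned when both partitions are the same trivial partition, 0
#' otherwise, each with a warning.
#'
#' @param g,p Integer (or factor/character) label vectors over the same
#'   samples.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(g, p) {
  if (length(g) != length(p)) stop("label vectors differ in length", call. = FALSE)
  N <- length(g)
  tab <- table(g, p)
  ni <- rowSums(tab)
  nj <- colSums(tab)
  hg <- -sum((ni / N) * log(ni / N))
  hp <- -sum((nj / N) * log(nj / N))
  if (hg == 0 || hp == 0) {
    warning("single-cluster partition: NMI degenerate", call. = FALSE)
    return(if (hg == 0 && hp == 0) 1 else 0)
  }
  nz <- tab > 0
  mi <- sum((tab[nz] / N) * log(N * tab[nz] / (ni[row(tab)[nz]] * nj[col(tab)[nz]])))
  min(1, max(0, mi / sqrt(hg * hp)))
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance:
#' `ARI = (sum_ij C(N_ij,2) - E) / (((sum_i C(N_i,2) + sum_j C(N_j,2))/2) - E)`
#' with `E = sum_i C(N_i,2) * sum_j C(N_j,2) / C(N,2)` over the contingency
#' table `N_ij`. Equals 1 iff the partitions are identical; 0 expected for
#' independent partitions.
#'
#' @param g,p Label vectors over the same samples.
#' @return ARI in \[-1, 1\].
#' @export
ari <- function(g, p) {
  if (length(g) != length(p)) stop("label vectors differ in length", call. = FALSE)
  N <- length(g)
  if (N < 2) stop("need at least 2 samples", call. = FALSE)
  tab <- table(g, p)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(N, 2)
  denom <- (sum_i + sum_j) / 2 - expected
  if (denom == 0) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / denom
}

#' Mean silhouette coefficient from a similarity matrix
#'
#' Similarities are converted to distances `d = 1 - S/max(S)` (default; scale
#' invariant) or `d = max(S) - S`, then each sample i gets the three-case
#' silhouette: with `a_i` the mean distance to its own cluster (self excluded)
#' and `b_i` the smallest mean distance to another cluster,
#' `s(i) = 1 - a_i/b_i` if `a_i < b_i`, `0` if equal, `b_i/a_i - 1` otherwise.
#' Singleton-cluster samples get `s(i) = 0` with a warning. The mean over
#' samples is returned.
#'
#' @param S Symmetric non-negative similarity matrix.
#' @param labels Cluster labels over the samples of S (>= 2 clusters).
#' @param conversion `"ratio"` (`1 - S/max(S)`) or `"difference"`
#'   (`max(S) - S`).
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_from_similarity <- function(S, labels,
                                       conversion = c("ratio", "difference")) {
  conversion <- match.arg(conversion)
  n <- nrow(S)
  if (length(labels) != n) stop("labels do not match S", call. = FALSE)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop("need at least 2 clusters", call. = FALSE)
  mx <- max(S)
  if (mx <= 0) stop("similarity matrix has no positive entries", call. = FALSE)
  d <- switch(conversion, ratio = 1 - S / mx, difference = mx - S)
  sil <- numeric(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      sil[i] <- 0
      warned <- TRUE
      next
    }
    a_i <- mean(d[i, setdiff(own, i)])
    b_i <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, 0))
    sil[i] <- if (a_i < b_i) 1 - a_i / b_i else if (a_i == b_i) 0 else b_i / a_i - 1
  }
  if (warned) warning("singleton cluster: silhouette set to 0 for its sample",
                      call. = FALSE)
  mean(sil)
}

#' Clustering metric report
#'
#' Convenience wrapper: NMI and ARI against ground truth (when provided) plus
#' the similarity-based mean silhouette of the predicted labels.
#'
#' @param S Consensus similarity matrix.
#' @param predicted Predicted cluster labels.
#' @param truth Optional ground-truth labels.
#' @return A one-row tibble: `nmi`, `ari` (NA without truth),
#'   `mean_silhouette`, `n_clusters`.
#' @export
evaluate_clustering <- function(S, predicted, truth = NULL) {
  tibble::tibble(
    nmi = if (is.null(truth)) NA_real_ else nmi(truth, predicted),
    ari = if (is.null(truth)) NA_real_ else ari(truth, predicted),
    mean_silhouette = silhouette_from_similarity(S, predicted),
    n_clusters = length(unique(predicted)))
}
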