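#' Simulate a multi-omics microbiome dataset with planted sample clusters
#'
#' Generates M feature-by-sample count tables sharing one planted sample
#' partition, emulating matched bacterial/fungal/viral composition profiles.
#' Each modality carries, per cluster, a disjoint block of features whose mean
#' abundance is elevated over the baseline; the elevation grows with
#' `separation`. Remaining features are undifferentiated noise. Counts are
#' drawn from a negative-binomial (default) or truncated-Gaussian noise model,
#' then zeroed independently with probability `dropout_rate` to mimic sparse,
#' zero-inflated compositions.
#'
#' The planted block for cluster g in modality m spans features
#' `block_size[m]*(g-1)+1 .. block_size[m]*g` with
#' `block_size[m] = max(2, floor(features_per_modality[m] / (n_clusters + 1)))`,
#' so at least one block's worth of features per modality is pure noise.
#' [planted_features()] recovers the block membership for a simulated dataset.
#'
#' @param n_samples Number of samples (>= 3 * n_clusters).
#' @param n_clusters Number of planted clusters (>= 2).
#' @param features_per_modality Integer vector (length 2 or 3) of feature counts.
#' @param separation Signal strength in (0, 1]: the elevated blocks have mean
#'   fold change `1 + 9*separation` over the baseline mean of 5. At
#'   `separation = 1` the planted structure is fully separable (10x elevation,
#'   the strong end of differential abundance); 0.2 gives a subtle 2.8x signal.
#' @param noise_model `"negative_binomial"` (size = 8) or `"gaussian"`
#'   (sd = sqrt(mean), truncated at 0).
#' @param dropout_rate Probability in \[0, 1) of zeroing each entry.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return A list with elements `dataset` (a `multiomics_dataset`) and `labels`
#'   (integer vector of 0-based cluster labels named by sample id).
#' @export
simulate_multiomics <- function(n_samples,
                                n_clusters,
                                features_per_modality,
                                separation = 1,
                                noise_model = c("negative_binomial", "gaussian"),
                                dropout_rate = 0.2,
                                seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (n_clusters < 2) stop("need at least 2 clusters", call. = FALSE)
  if (n_samples < 3 * n_clusters) {
    stop("need n_samples >= 3 * n_clusters", call. = FALSE)
  }
  if (!length(features_per_modality) %in% c(2L, 3L)) {
    stop("features_per_modality must have length 2 or 3", call. = FALSE)
  }
  if (separation <= 0 || separation > 1) stop("separation must be in (0, 1]", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)", call. = FALSE)

  base_mean <- 5
  elevated_mean <- base_mean * (1 + 9 * separation)
  nb_size <- 8

  withr::with_seed(as.integer(seed), {
    labels <- sort(rep_len(seq_len(n_clusters) - 1L, n_samples))
    sample_ids <- sprintf("s%03d", seq_len(n_samples))
    names(labels) <- sample_ids

    modality_names <- c("bacteria", "fungi", "viruses")[seq_along(features_per_modality)]
    tables <- vector("list", length(features_per_modality))
    for (m in seq_along(features_per_modality)) {
      p <- as.integer(features_per_modality[m])
      bsz <- max(2L, p %/% (n_clusters + 1L))
      if (bsz * n_clusters > p) {
        stop("too few features for the planted blocks in modality ", m, call. = FALSE)
      }
      mu <- matrix(base_mean, nrow = p, ncol = n_samples)
      for (g in seq_len(n_clusters)) {
        rows <- (bsz * (g - 1L) + 1L):(bsz * g)
        mu[rows, labels == (g - 1L)] <- elevated_mean
      }
      counts <- switch(noise_model,
        negative_binomial = matrix(
          stats::rnbinom(p * n_samples, size = nb_size, mu = mu),
          nrow = p),
        gaussian = matrix(
          pmax(0, stats::rnorm(p * n_samples, mean = mu, sd = sqrt(mu))),
          nrow = p)
      )
      if (dropout_rate > 0) {
        keep <- matrix(stats::runif(p * n_samples) >= dropout_rate, nrow = p)
        counts <- counts * keep
      }
      tables[[m]] <- abundance_matrix(
        counts,
        feature_ids = sprintf("%s_f%03d", substr(modality_names[m], 1, 4), seq_len(p)),
        sample_ids = sample_ids)
    }
    names(tables) <- modality_names
    list(dataset = structure(tables, class = "multiomics_dataset"),
         labels = labels)
  })
}

#' Planted discriminative features of a simulated dataset
#'
#' Returns, for each modality, the ids of features belonging to a planted
#' cluster block (the discriminative features the simulator elevated), given
#' the same `features_per_modality`/`n_clusters` used in [simulate_multiomics()].
#'
#' @param features_per_modality Integer vector as passed to the simulator.
#' @param n_clusters Number of planted clusters.
#' @return A list (one character vector of feature ids per modality).
#' @export
planted_features <- function(features_per_modality, n_clusters) {
  modality_names <- c("bacteria", "fungi", "viruses")[seq_along(features_per_modality)]
  out <- lapply(seq_along(features_per_modality), function(m) {
    p <- as.integer(features_per_modality[m])
    bsz <- max(2L, p %/% (n_clusters + 1L))
    sprintf("%s_f%03d", substr(modality_names[m], 1, 4), seq_len(bsz * n_clusters))
  })
  names(out) <- modality_names
  out
}

#' Write simulated cluster labels as a two-column TSV
#'
#' @param labels Named integer vector (names are sample ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), cluster = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column labels TSV
#'
#' @param path Path written by [write_labels()].
#' @return Named integer vector of cluster labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$cluster), df$sample_id)
}
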