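test_that("block-diagonal similarity clusters into its blocks", {
  S <- matrix(0, 9, 9)
  S[1:3, 1:3] <- 0.9
  S[4:6, 4:6] <- 0.9
  S[7:9, 7:9] <- 0.9
  diag(S) <- 1
  truth <- rep(0:2, each = 3)
  lab_lou <- cluster_samples(S, seed = 1)
  lab_sp <- cluster_samples(S, seed = 1, method = "spectral_k", k_clusters = 3)
  expect_equal(ari(truth, lab_lou), 1)
  expect_equal(ari(truth, lab_sp), 1)
  expect_setequal(unique(lab_lou), 0:2)

  # structureless similarity collapses to one Louvain community
  Sc <- matrix(0.5, 8, 8)
  diag(Sc) <- 1
  expect_length(unique(cluster_samples(Sc, seed = 1)), 1)

  expect_error(cluster_samples(S[1:3, 1:3], seed = 1), "at least 4")
  expect_error(cluster_samples(S, method = "spectral_k"), "k_clusters")
})

test_that("cluster labels are equivariant under sample permutation", {
  S <- block_affinity(c(4, 4, 4), within = 0.85, across = 0.05)
  dimnames(S) <- list(paste0("s", 1:12), paste0("s", 1:12))
  perm <- withr::with_seed(7, sample(12))
  lab <- cluster_samples(S, seed = 2)
  lab_p <- cluster_samples(S[perm, perm], seed = 2)
  expect_equal(ari(lab[perm], lab_p), 1)
  expect_identical(names(lab_p), rownames(S)[perm])
})

test_that("the Laplacian score matches dense-algebra evaluation", {
  withr::with_seed(11, {
    S <- matrix(runif(36, 0.05, 1), 6, 6)
    S <- (S + t(S)) / 2
    f <- rnorm(6)
  })
  D <- diag(rowSums(S))
  L <- D - S
  one <- rep(1, 6)
  ft <- f - as.numeric(t(f) %*% D %*% one) / as.numeric(t(one) %*% D %*% one)
  expected <- as.numeric(t(ft) %*% L %*% ft) / as.numeric(t(ft) %*% D %*% ft)
  expect_equal(laplacian_score(f, S), expected, tolerance = 1e-12)
})

test_that("the Laplacian score is scale and shift invariant and flags degeneracy", {
  withr::with_seed(12, {
    S <- matrix(runif(49, 0.05, 1), 7, 7)
    S <- (S + t(S)) / 2
    f <- rnorm(7)
  })
  sc <- laplacian_score(f, S)
  expect_equal(laplacian_score(3.7 * f, S), sc, tolerance = 1e-10)
  expect_equal(laplacian_score(-2 * f, S), sc, tolerance = 1e-10)
  expect_equal(laplacian_score(f + 5, S), sc, tolerance = 1e-10)
  expect_warning(res <- laplacian_score(rep(2, 7), S), "constant")
  expect_identical(res, Inf)
})

test_that("a block-indicator feature on block-diagonal similarity scores zero", {
  S <- matrix(0, 8, 8)
  S[1:4, 1:4] <- 1
  S[5:8, 5:8] <- 1
  f <- c(rep(1, 4), rep(0, 4))
  expect_equal(laplacian_score(f, S), 0, tolerance = 1e-12)
})

test_that("feature ranking is a permutation with index tie-breaking", {
  X <- toy_abundance(6, 8, seed = 13)
  withr::with_seed(13, {
    S <- matrix(runif(64, 0.05, 1), 8, 8)
    S <- (S + t(S)) / 2
  })
  full <- select_top_features(X, S)
  expect_identical(sort(full$rank), seq_len(nrow(full)))
  expect_true(all(diff(full$score) >= 0))

  # a duplicated feature row ties exactly; the lower index wins the rank
  Xd <- abundance_matrix(rbind(unclass(X)[1, ], unclass(X)),
                         c("dup", rownames(X)), colnames(X))
  fd <- select_top_features(Xd, S)
  r_dup <- fd$rank[fd$feature_id == "dup"]
  r_f1 <- fd$rank[fd$feature_id == "f1"]
  expect_identical(r_f1, r_dup + 1L)

  expect_error(select_top_features(X, S, top_k = 100), "top_k")
})

test_that("smoothed correlation reduces to Pearson under identity smoothing", {
  expect_equal(smoothed_correlation(c(1, 2, 3), c(3, 2, 1), diag(3)), -1)
  withr::with_seed(14, {
    a <- rnorm(10); b <- rnorm(10)
    S <- matrix(runif(100, 0.05, 1), 10, 10)
    S <- (S + t(S)) / 2
  })
  expect_equal(smoothed_correlation(a, b, diag(10)), stats::cor(a, b),
               tolerance = 1e-12)
  expect_equal(smoothed_correlation(a, a, S), 1, tolerance = 1e-12)
  expect_equal(smoothed_correlation(a, b, S), smoothed_correlation(b, a, S),
               tolerance = 1e-12)
  expect_lte(abs(smoothed_correlation(a, b, S)), 1)
  expect_warning(res <- smoothed_correlation(rep(1, 10), b, matrix(1, 10, 10)),
                 "constant")
  expect_identical(res, 0)
})

test_that("association edges shrink as the threshold rises", {
  sim <- simulate_multiomics(18, 2, c(15, 12), separation = 1, seed = 15)
  fit <- honmf_fit(sim$dataset, honmf_config(k = 2, seed = 15, max_iter = 100))
  n_edges <- vapply(c(0, 0.3, 0.6, 0.9), function(th) {
    nrow(association_network(sim$dataset, fit$S, per_modality_top = 4,
                             threshold = th))
  }, 0L)
  expect_true(all(diff(n_edges) <= 0))
  # threshold 0 keeps the complete cross-modality bipartite set
  expect_identical(n_edges[1], 16L)
  expect_error(association_network(sim$dataset, fit$S, threshold = 1),
               "threshold")
})

test_that("association edges carry signs and full correlation matrices", {
  sim <- simulate_multiomics(18, 2, c(15, 12), separation = 1, seed = 16)
  fit <- honmf_fit(sim$dataset, honmf_config(k = 2, seed = 16, max_iter = 100))
  ed <- association_network(sim$dataset, fit$S, per_modality_top = 4,
                            threshold = 0)
  expect_identical(ed$sign, ifelse(ed$corr >= 0, "positive", "negative"))
  mats <- attr(ed, "correlations")
  expect_named(mats, "bacteria-fungi")
  expect_identical(dim(mats[[1]]), c(4L, 4L))
  expect_true(all(abs(mats[[1]]) <= 1 + 1e-12))

  path <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_association_network(ed, path, graphml = gml)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_identical(nrow(back), nrow(ed))
  expect_true(file.size(gml) > 0)
})
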