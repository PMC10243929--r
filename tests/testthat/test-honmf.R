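# helper: an exact global optimum with orthonormal block-indicator factors,
# A_i = H G H', S = H H' (rows sum to 1), hyperedges = the blocks (L H = 0)
exact_fit_state <- function(sizes = c(3, 3, 3), M = 2) {
  n <- sum(sizes)
  k <- length(sizes)
  H <- matrix(0, n, k)
  start <- cumsum(c(0, sizes))
  for (j in seq_len(k)) {
    H[(start[j] + 1):start[j + 1], j] <- 1 / sqrt(sizes[j])
  }
  A <- tcrossprod(H)  # G = I
  blocks <- lapply(seq_len(k), function(j) (start[j] + 1):start[j + 1])
  L <- hypergraph_laplacian(manual_hypergraph(n, blocks, rep(1, k)))
  list(state = list(H = replicate(M, H, simplify = FALSE),
                    G = replicate(M, diag(k), simplify = FALSE),
                    S = A),
       A_list = replicate(M, A, simplify = FALSE),
       L_list = replicate(M, L, simplify = FALSE),
       blocks = blocks)
}

test_that("the objective evaluates term by term", {
  # all-zero factors and similarities: only the orthogonality and row-sum
  # penalties survive: J = eta*M*k + beta*n
  M <- 3; k <- 2; n <- 5
  zero_state <- list(H = replicate(M, matrix(0, n, k), simplify = FALSE),
                     G = replicate(M, matrix(0, k, k), simplify = FALSE),
                     S = matrix(0, n, n))
  A0 <- replicate(M, matrix(0, n, n), simplify = FALSE)
  L0 <- replicate(M, matrix(0, n, n), simplify = FALSE)
  expect_equal(
    honmf_objective(zero_state, A0, L0, alpha = 3.7, beta = 1, gamma = 2.2,
                    eta = 10),
    10 * 3 * 2 + 5)

  # at an exact factorization every residual term vanishes
  ex <- exact_fit_state()
  expect_lt(
    honmf_objective(ex$state, ex$A_list, ex$L_list, alpha = 2, beta = 1,
                    gamma = 3, eta = 10),
    1e-12)

  # J >= 0 for random states
  withr::with_seed(1, {
    st <- list(H = replicate(2, matrix(runif(12), 6, 2), simplify = FALSE),
               G = replicate(2, diag(2), simplify = FALSE),
               S = matrix(runif(36), 6, 6))
    A <- replicate(2, { a <- matrix(runif(36), 6, 6); (a + t(a)) / 2 },
                   simplify = FALSE)
  })
  expect_gte(honmf_objective(st, A, NULL, 1, 1, 0, 10), 0)
  expect_error(honmf_objective(st, A[1], NULL, 1, 1, 0, 10), "mismatch")
})

test_that("initialization is deterministic with identity G and bounded residual", {
  withr::with_seed(2, {
    A <- lapply(1:2, function(i) {
      a <- matrix(runif(64, 0.1, 1), 8, 8); a <- (a + t(a)) / 2; diag(a) <- 1; a
    })
  })
  s1 <- honmf_init(A, k = 3)
  s2 <- honmf_init(A, k = 3)
  expect_identical(s1, s2)
  expect_equal(s1$G[[1]], diag(3))
  expect_equal(s1$G[[2]], diag(3))
  expect_error(honmf_init(A, k = 9), "exceed")

  # exactly rank-k non-negative symmetric input: init residual cannot exceed
  # the trivial zero-factor residual ||A||_F^2
  ex <- exact_fit_state(sizes = c(4, 4))
  A_rank2 <- ex$A_list[[1]]
  H0 <- nndsvd_symmetric(A_rank2, 2)
  expect_lte(sum((A_rank2 - tcrossprod(H0))^2), sum(A_rank2^2))
})

test_that("auto-selected weights match their defining ratios", {
  withr::with_seed(3, {
    A <- lapply(1:2, function(i) {
      a <- matrix(runif(49, 0.1, 1), 7, 7); a <- (a + t(a)) / 2; diag(a) <- 1; a
    })
    L <- lapply(1:2, function(i) {
      rh <- random_hypergraph(7, 2)
      hypergraph_laplacian(manual_hypergraph(7, rh$hyperedges, rh$weights))
    })
  })
  st <- honmf_init(A, k = 2)
  sel <- auto_select_params(A, L, st)
  # independent recomputation of both sums
  num <- den_a <- den_g <- 0
  for (i in 1:2) {
    H <- st$H[[i]]
    num <- num + norm(A[[i]] - H %*% st$G[[i]] %*% t(H), "F")^2
    den_a <- den_a + norm(st$S - H %*% t(H), "F")^2
    den_g <- den_g + sum(diag(t(H) %*% L[[i]] %*% H))
  }
  expect_equal(sel$alpha, num / den_a, tolerance = 1e-10)
  expect_equal(sel$gamma, num / den_g, tolerance = 1e-10)
})

test_that("degenerate smoothness denominator falls back to gamma = 1", {
  # block-constant factors on a hypergraph whose hyperedges are the blocks:
  # Tr(H' L H) = 0 exactly
  ex <- exact_fit_state(sizes = c(3, 3), M = 2)
  st <- ex$state
  st$S <- st$S + 0.1  # keep the fusion denominator away from zero
  expect_warning(sel <- auto_select_params(ex$A_list, ex$L_list, st),
                 "gamma = 1")
  expect_equal(sel$gamma, 1)
})

test_that("an exact factorization is a fixed point of the update sweep", {
  ex <- exact_fit_state()
  out <- honmf_update_step(ex$state, ex$A_list, ex$L_list,
                           alpha = 2, beta = 1, gamma = 3, eta = 10)
  for (i in 1:2) {
    expect_equal(out$H[[i]], ex$state$H[[i]], tolerance = 1e-8)
    expect_equal(out$G[[i]], ex$state$G[[i]], tolerance = 1e-8)
  }
  expect_equal(out$S, ex$state$S, tolerance = 1e-8)
})

test_that("updates keep the objective non-increasing from random inits", {
  # the derivation audit: split-gradient updates must descend (within
  # relative slack 1e-8) from arbitrary non-negative starting points
  for (s in 1:3) {
    sim <- simulate_multiomics(12, 2, c(20, 15), separation = 0.5, seed = s)
    Xn <- lapply(sim$dataset, normalize_composition)
    A <- lapply(lapply(Xn, gaussian_affinity), unname)
    L <- lapply(seq_along(A), function(i) {
      he <- build_hyperedges_louvain(A[[i]], seed = s)
      unname(hypergraph_laplacian(build_hypergraph(Xn[[i]], he)))
    })
    st <- withr::with_seed(s, list(
      H = lapply(A, function(a) matrix(runif(12 * 3), 12, 3)),
      G = replicate(2, { g <- matrix(runif(9), 3, 3); (g + t(g)) / 2 },
                    simplify = FALSE),
      S = { m <- matrix(runif(144), 12, 12); (m + t(m)) / 2 }))
    J <- honmf_objective(st, A, L, 0.5, 1, 2, 10)
    for (it in 1:200) {
      st <- honmf_update_step(st, A, L, 0.5, 1, 2, 10)
      J_new <- honmf_objective(st, A, L, 0.5, 1, 2, 10)
      expect_lte(J_new, J * (1 + 1e-8))
      J <- J_new
    }
    # non-negativity is preserved exactly through all iterations
    expect_true(all(vapply(st$H, function(h) all(h >= 0), TRUE)))
    expect_true(all(vapply(st$G, function(g) all(g >= 0), TRUE)))
    expect_true(all(st$S >= 0))
    # G stays symmetric
    expect_equal(st$G[[1]], t(st$G[[1]]), tolerance = 1e-8)
  }
})

test_that("fitting tightens orthogonality and consensus agreement", {
  sim <- simulate_multiomics(24, 3, c(30, 24, 18), separation = 1, seed = 4)
  cfg <- honmf_config(k = 3, seed = 4, max_iter = 300)
  fit <- honmf_fit(sim$dataset, cfg)

  init <- honmf_init(fit$A_list, 3)
  for (i in seq_along(fit$H)) {
    ortho_0 <- norm(crossprod(init$H[[i]]) - diag(3), "F")
    ortho_T <- norm(crossprod(unname(fit$H[[i]])) - diag(3), "F")
    expect_lt(ortho_T, ortho_0)
    fuse_0 <- norm(init$S - tcrossprod(init$H[[i]]), "F")
    fuse_T <- norm(unname(fit$S) - tcrossprod(unname(fit$H[[i]])), "F")
    expect_lte(fuse_T, fuse_0)
  }
})

test_that("ablation variants zero the corresponding weight", {
  sim <- simulate_multiomics(15, 3, c(20, 16), separation = 1, seed = 5)
  f_eta <- honmf_fit(sim$dataset, honmf_config(k = 3, seed = 5, max_iter = 30,
                                               variant = "no_eta"))
  expect_identical(f_eta$eta, 0)
  f_gam <- honmf_fit(sim$dataset, honmf_config(k = 3, seed = 5, max_iter = 30,
                                               variant = "no_gamma"))
  expect_identical(f_gam$gamma, 0)
  expect_null(f_gam$L_list)
  f_gon <- honmf_fit(sim$dataset, honmf_config(k = 3, seed = 5, max_iter = 30,
                                               variant = "gonmf"))
  expect_null(f_gon$hypergraphs)
  # simple-graph Laplacians in use
  expect_length(f_gon$L_list, 2)
})

test_that("the fit is equivariant under sample permutation", {
  sim <- simulate_multiomics(20, 2, c(30, 20), separation = 1, seed = 3)
  perm <- withr::with_seed(99, sample(20))
  ds_p <- structure(
    lapply(sim$dataset, function(x) {
      abundance_matrix(unclass(x)[, perm], rownames(x), colnames(x)[perm])
    }),
    class = "multiomics_dataset")
  cfg <- honmf_config(k = 2, seed = 3, max_iter = 100)
  f1 <- honmf_fit(sim$dataset, cfg)
  f2 <- honmf_fit(ds_p, cfg)
  expect_equal(unname(f1$S)[perm, perm], unname(f2$S), tolerance = 1e-12)
})

test_that("tidy, glance, autoplot and the writer expose the fit", {
  sim <- simulate_multiomics(12, 2, c(14, 12), separation = 1, seed = 6)
  fit <- honmf_fit(sim$dataset, honmf_config(k = 2, seed = 6, max_iter = 40))

  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 2L * 12L * 2L)
  expect_named(td, c("modality", "sample_id", "factor", "loading"))

  gl <- generics::glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$k, 2L)
  expect_equal(gl$objective, fit$objective_trace[length(fit$objective_trace)])

  expect_s3_class(ggplot2::autoplot(fit), "ggplot")

  dir <- withr::local_tempdir()
  write_honmf_fit(fit, dir)
  expect_true(all(file.exists(file.path(
    dir, c("S.tsv", "H_bacteria.tsv", "G_fungi.tsv", "objective_trace.tsv",
           "config.yaml")))))
  S_back <- read_similarity(file.path(dir, "S.tsv"))
  expect_equal(S_back, unclass(fit$S), tolerance = 1e-12, ignore_attr = TRUE)
})
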