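#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

EPS <- 1e-12

#' Symmetric NNDSVD-style non-negative initialization
#'
#' Initializes the n x k factor H of the symmetric problem
#' `min ||A - H H^T||_F^2` from the top-k eigenpairs of A: each eigenvector is
#' split into its positive and negative parts, the dominant part (larger norm)
#' is kept and scaled by the square root of the eigenvalue. The leading
#' eigenvector of a non-negative A is non-negative (Perron-Frobenius), so the
#' first column is exact. Zeros are filled with `mean(A)/100` so multiplicative
#' updates are not locked at zero. Deterministic.
#'
#' @param A Symmetric non-negative n x n matrix.
#' @param k Number of factors, `2 <= k <= n`.
#' @return Non-negative n x k matrix.
#' @export
nndsvd_symmetric <- function(A, k) {
  n <- nrow(A)
  if (k > n) stop("k must not exceed the number of samples", call. = FALSE)
  es <- eigen((A + t(A)) / 2, symmetric = TRUE)
  H <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lam <- es$values[j]
    if (lam <= 0) next
    x <- es$vectors[, j]
    xp <- pmax(x, 0)
    xn <- pmax(-x, 0)
    H[, j] <- if (sum(xp^2) >= sum(xn^2)) sqrt(lam) * xp else sqrt(lam) * xn
  }
  H[H <= 0] <- mean(A) / 100
  H
}

#' HONMF configuration
#'
#' Bundles the model and optimizer settings. `alpha` and `gamma` default to
#' `"auto"`, selected from the initialization as the ratio of the tri-factor
#' residual to, respectively, the fusion residual and the hypergraph smoothness
#' (see [auto_select_params()]). `eta = 10` (orthogonality pressure) and
#' `beta = 1` (row-sum-to-one pressure on S) are fixed defaults across datasets.
#'
#' @param k Number of latent factors (>= 2).
#' @param alpha Fusion weight: `"auto"` or a non-negative number.
#' @param gamma Hypergraph-regularization weight: `"auto"` or non-negative.
#' @param beta Row-sum penalty weight on S (default 1).
#' @param eta Column-orthogonality penalty weight on H_i (default 10).
#' @param variant One of `"honmf"` (full model), `"gonmf"` (simple-graph
#'   Laplacian in place of the hypergraph), `"no_alpha"`, `"no_gamma"`,
#'   `"no_eta"` (the corresponding weight forced to 0).
#' @param max_iter Maximum update sweeps (default 500).
#' @param tol Relative objective-change convergence threshold (default 1e-6).
#' @param seed Integer seed for all stochastic components (Louvain sweeps).
#' @param knn_k KNN size for hyperedge construction; default `floor(n/2)`.
#' @param resolution Louvain resolution for hyperedge construction.
#' @param bandwidth_rule Kernel bandwidth rule for [gaussian_affinity()].
#' @param relative,log_c Composition normalization, see [normalize_composition()].
#' @param snf_k,snf_iterations Settings for [snf_fuse()] at initialization.
#' @param damping Exponent on the multiplicative factor of the H_i update.
#'   The default 1 is the plain split-gradient ratio; values below 1 (e.g. 1/2)
#'   damp the step, a safeguard for quartic objectives (see the vignette).
#' @return A list of class `honmf_config`.
#' @export
honmf_config <- function(k,
                         alpha = "auto", gamma = "auto",
                         beta = 1, eta = 10,
                         variant = c("honmf", "gonmf", "no_alpha", "no_gamma",
                                     "no_eta"),
                         max_iter = 500L, tol = 1e-6, seed = 1L,
                         knn_k = NULL, resolution = 1,
                         bandwidth_rule = "local_scaling",
                         relative = TRUE, log_c = NULL,
                         snf_k = NULL, snf_iterations = 20L,
                         damping = 1) {
  variant <- match.arg(variant)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  stopifnot(beta >= 0, eta >= 0, max_iter >= 1, tol > 0)
  structure(list(k = as.integer(k), alpha = alpha, gamma = gamma, beta = beta,
                 eta = eta, variant = variant, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed), knn_k = knn_k,
                 resolution = resolution, bandwidth_rule = bandwidth_rule,
                 relative = relative, log_c = log_c, snf_k = snf_k,
                 snf_iterations = as.integer(snf_iterations),
                 damping = damping),
            class = "honmf_config")
}

#' @export
print.honmf_config <- function(x, ...) {
  cat("honmf_config: k =", x$k, " variant =", x$variant,
      " alpha =", format(x$alpha), " gamma =", format(x$gamma),
      " beta =", x$beta, " eta =", x$eta, "\n")
  invisible(x)
}

#' HONMF objective function
#'
#' `J = sum_i ||A_i - H_i G_i H_i'||_F^2 + (alpha/2) sum_i ||S - H_i H_i'||_F^2
#'    + eta sum_i ||H_i'H_i - I||_F^2 + beta ||S 1 - 1||^2
#'    + gamma sum_i Tr(H_i' L_i H_i)`
#'
#' @param state List with elements `H` (list of n x k matrices), `G` (list of
#'   k x k symmetric matrices), `S` (n x n matrix).
#' @param A_list Per-modality sample similarity matrices.
#' @param L_list Per-modality Laplacians (ignored when `gamma = 0`; may be NULL
#'   then).
#' @param alpha,beta,gamma,eta Non-negative term weights.
#' @return Non-negative scalar.
#' @export
honmf_objective <- function(state, A_list, L_list, alpha, beta, gamma, eta) {
  M <- length(A_list)
  if (length(state$H) != M || nrow(state$H[[1]]) != nrow(A_list[[1]]) ||
      nrow(state$S) != nrow(A_list[[1]])) {
    stop("state/similarity dimension mismatch", call. = FALSE)
  }
  k <- ncol(state$H[[1]])
  J <- beta * sum((rowSums(state$S) - 1)^2)
  for (i in seq_len(M)) {
    H <- state$H[[i]]
    G <- state$G[[i]]
    HHt <- tcrossprod(H)
    J <- J + sum((A_list[[i]] - H %*% G %*% t(H))^2) +
      (alpha / 2) * sum((state$S - HHt)^2) +
      eta * sum((crossprod(H) - diag(k))^2)
    if (gamma > 0) J <- J + gamma * sum(H * (L_list[[i]] %*% H))
  }
  J
}

#' Initialize the HONMF state
#'
#' Per modality, H_i comes from [nndsvd_symmetric()] on A_i; G_i is set to the
#' identity; the consensus S is initialized by fusing the A_i with [snf_fuse()].
#' Deterministic.
#'
#' @param A_list Per-modality similarity matrices.
#' @param k Number of factors (<= n).
#' @param snf_k,snf_iterations Passed to [snf_fuse()].
#' @return List with `H`, `G`, `S`.
#' @export
honmf_init <- function(A_list, k, snf_k = NULL, snf_iterations = 20L) {
  n <- nrow(A_list[[1]])
  if (k > n) stop("k must not exceed the number of samples", call. = FALSE)
  list(H = lapply(A_list, nndsvd_symmetric, k = k),
       G = replicate(length(A_list), diag(k), simplify = FALSE),
       S = unname(snf_fuse(A_list, k_neighbors = snf_k,
                           iterations = snf_iterations)))
}

#' Automatic selection of the fusion and graph-regularization weights
#'
#' From the initialized state, `alpha` is the ratio of the total tri-factor
#' residual to the total fusion residual, and `gamma` is the ratio of the
#' tri-factor residual to the total hypergraph smoothness:
#' `alpha = sum_i ||A_i - H_i G_i H_i'||_F^2 / sum_i ||S - H_i H_i'||_F^2`,
#' `gamma = sum_i ||A_i - H_i G_i H_i'||_F^2 / sum_i Tr(H_i' L_i H_i)`.
#' A zero denominator falls back to 1 with a warning.
#'
#' @param A_list,L_list Per-modality similarities and Laplacians.
#' @param state Initialized state from [honmf_init()].
#' @return Named list with `alpha` and `gamma`.
#' @export
auto_select_params <- function(A_list, L_list, state) {
  M <- length(A_list)
  num <- 0; den_a <- 0; den_g <- 0
  for (i in seq_len(M)) {
    H <- state$H[[i]]
    num <- num + sum((A_list[[i]] - H %*% state$G[[i]] %*% t(H))^2)
    den_a <- den_a + sum((state$S - tcrossprod(H))^2)
    if (!is.null(L_list)) den_g <- den_g + sum(H * (L_list[[i]] %*% H))
  }
  alpha <- if (den_a <= EPS) {
    warning("fusion residual ~ 0 at initialization; falling back to alpha = 1",
            call. = FALSE)
    1
  } else num / den_a
  gamma <- if (is.null(L_list) || den_g <= EPS) {
    if (!is.null(L_list)) {
      warning("hypergraph smoothness ~ 0 at initialization; falling back to gamma = 1",
              call. = FALSE)
    }
    1
  } else num / den_g
  list(alpha = alpha, gamma = gamma)
}

# split a Laplacian into its elementwise positive and negative parts
laplacian_split <- function(L) {
  list(pos = pmax(L, 0), neg = pmax(-L, 0))
}

#' One multiplicative block-coordinate update sweep
#'
#' Updates each H_i, then each G_i, then S. Each block's multiplicative factor
#' is the ratio of the negative to the positive part of its gradient
#' (split-gradient rule), so non-negativity is preserved exactly; denominators
#' carry a machine-epsilon floor. The H_i factor may optionally be damped with
#' exponent `damping < 1`, a stabilization for the quartic-in-H_i terms; the
#' monotonicity of the objective trace is audited in the test suite. G_i is
#' re-symmetrized after its update.
#'
#' @param state List with `H`, `G`, `S`.
#' @param A_list,L_list Per-modality similarities and Laplacian splits
#'   (`L_list` as matrices; ignored when `gamma = 0`).
#' @param alpha,beta,gamma,eta Term weights.
#' @param damping Exponent on the H_i multiplicative factor.
#' @return Updated state.
#' @export
honmf_update_step <- function(state, A_list, L_list, alpha, beta, gamma, eta,
                              damping = 1) {
  M <- length(A_list)
  n <- nrow(state$S)
  S <- state$S
  Ssym <- (S + t(S)) / 2
  splits <- if (gamma > 0) lapply(L_list, laplacian_split) else NULL

  for (i in seq_len(M)) {
    H <- state$H[[i]]
    G <- state$G[[i]]
    HtH <- crossprod(H)
    num <- 4 * A_list[[i]] %*% H %*% G + 2 * alpha * Ssym %*% H + 4 * eta * H
    den <- 4 * H %*% (G %*% HtH %*% G) + 2 * alpha * H %*% HtH +
      4 * eta * H %*% HtH
    if (gamma > 0) {
      num <- num + 2 * gamma * splits[[i]]$neg %*% H
      den <- den + 2 * gamma * splits[[i]]$pos %*% H
    }
      ratio <- num / (den + EPS)
    state$H[[i]] <- H * (if (damping == 1) ratio else ratio^damping)
  }
  for (i in seq_len(M)) {
    H <- state$H[[i]]
    HtH <- crossprod(H)
    G <- state$G[[i]]
    num <- t(H) %*% A_list[[i]] %*% H
    den <- HtH %*% G %*% HtH
    G <- G * (num / (den + EPS))
    state$G[[i]] <- (G + t(G)) / 2
  }
  K_sum <- Reduce(`+`, lapply(state$H, tcrossprod))
  num <- alpha * K_sum + 2 * beta
  den <- alpha * M * S + 2 * beta * matrix(rowSums(S), n, n)
  state$S <- S * (num / (den + EPS))
  state
}

#' Fit the HONMF model to a multi-omics dataset
#'
#' Full procedure: per modality, normalize the composition profile, build the
#' Gaussian-kernel affinity A_i and (unless `gamma = 0`) the Louvain-community
#' hypergraph Laplacian L_i (simple-graph Laplacian for the `gonmf` variant);
#' initialize H_i by symmetric NNDSVD, G_i = I, and S by SNF; auto-select
#' `alpha`/`gamma` unless given; then iterate multiplicative update sweeps
#' until the relative objective change falls below `tol` or `max_iter` is
#' reached. The final S is symmetrized once.
#'
#' @param dataset A `multiomics_dataset` from [align_modalities()] or
#'   [simulate_multiomics()].
#' @param config An [honmf_config()]. Alternatively pass `k` and `...`
#'   overrides directly.
#' @param k,... Convenience: forwarded to [honmf_config()] when `config` is
#'   missing.
#' @return An object of class `honmf_fit`: list with factor lists `H`, `G`,
#'   consensus `S` (dimnamed by sample ids), `objective_trace`, resolved
#'   `alpha`/`gamma`, the per-modality affinities `A_list`, Laplacians
#'   `L_list`, hypergraphs `hypergraphs`, the `config`, `iterations` and
#'   `converged`.
#' @export
honmf_fit <- function(dataset, config = NULL, k = 3L, ...) {
  if (is.null(config)) config <- honmf_config(k = k, ...)
  stopifnot(inherits(config, "honmf_config"))
  M <- length(dataset)
  if (!M %in% 2:3) stop("need 2 or 3 modalities", call. = FALSE)
  sample_ids <- colnames(dataset[[1]])
  n <- length(sample_ids)

  alpha <- config$alpha
  gamma <- config$gamma
  eta <- config$eta
  beta <- config$beta
  if (config$variant == "no_alpha") alpha <- 0
  if (config$variant == "no_gamma") gamma <- 0
  if (config$variant == "no_eta") eta <- 0

  Xn <- lapply(dataset, normalize_composition,
               relative = config$relative, log_c = config$log_c)
  A_list <- lapply(Xn, gaussian_affinity, bandwidth_rule = config$bandwidth_rule)
  A_list <- lapply(A_list, unname)

  need_laplacian <- !identical(gamma, 0)
  hypergraphs <- NULL
  L_list <- NULL
  if (need_laplacian) {
    if (config$variant == "gonmf") {
      L_list <- lapply(A_list, simple_graph_laplacian, knn_k = config$knn_k)
    } else {
      hypergraphs <- vector("list", M)
      L_list <- vector("list", M)
      for (i in seq_len(M)) {
        he <- build_hyperedges_louvain(A_list[[i]], knn_k = config$knn_k,
                                       resolution = config$resolution,
                                       seed = config$seed + i - 1L)
        hypergraphs[[i]] <- build_hypergraph(Xn[[i]], he)
        L_list[[i]] <- unname(hypergraph_laplacian(hypergraphs[[i]]))
      }
      names(hypergraphs) <- names(dataset)
    }
  }

  state <- honmf_init(A_list, config$k, snf_k = config$snf_k,
                      snf_iterations = config$snf_iterations)
  if (identical(alpha, "auto") || identical(gamma, "auto")) {
    auto <- auto_select_params(A_list, L_list, state)
    if (identical(alpha, "auto")) alpha <- auto$alpha
    if (identical(gamma, "auto")) gamma <- if (need_laplacian) auto$gamma else 0
  }
  stopifnot(is.numeric(alpha), is.numeric(gamma), alpha >= 0, gamma >= 0)

  J <- honmf_objective(state, A_list, L_list, alpha, beta, gamma, eta)
  trace <- numeric(config$max_iter + 1L)
  trace[1] <- J
  iter <- 0L
  converged <- FALSE
  while (iter < config$max_iter) {
    iter <- iter + 1L
    state <- honmf_update_step(state, A_list, L_list, alpha, beta, gamma, eta,
                               damping = config$damping)
    J_new <- honmf_objective(state, A_list, L_list, alpha, beta, gamma, eta)
    trace[iter + 1L] <- J_new
    if (abs(J - J_new) / max(J, EPS) < config$tol) {
      converged <- TRUE
      J <- J_new
      break
    }
    J <- J_new
  }

  S <- (state$S + t(state$S)) / 2
  dimnames(S) <- list(sample_ids, sample_ids)
  H <- lapply(state$H, function(h) {
    dimnames(h) <- list(sample_ids, paste0("factor", seq_len(config$k)))
    h
  })
  names(H) <- names(dataset)
  G <- state$G
  names(G) <- names(dataset)

  structure(list(H = H, G = G, S = S,
                 objective_trace = trace[seq_len(iter + 1L)],
                 alpha = alpha, gamma = gamma, beta = beta, eta = eta,
                 A_list = A_list, L_list = L_list, hypergraphs = hypergraphs,
                 config = config, iterations = iter, converged = converged,
                 sample_ids = sample_ids, modality_names = names(dataset)),
            class = "honmf_fit")
}

#' @export
print.honmf_fit <- function(x, ...) {
  cat(sprintf(
    "honmf_fit: %d modalities, %d samples, k = %d (%s)\n",
    length(x$H), length(x$sample_ids), x$config$k, x$config$variant))
  cat(sprintf("  alpha = %.4g, gamma = %.4g, beta = %g, eta = %g\n",
              x$alpha, x$gamma, x$beta, x$eta))
  cat(sprintf("  %d iterations, objective %.6g -> %.6g (%s)\n",
              x$iterations, x$objective_trace[1],
              x$objective_trace[length(x$objective_trace)],
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Tidy the latent factors of a fitted HONMF model
#'
#' @param x An `honmf_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (modality, sample, factor) loading.
#' @method tidy honmf_fit
#' @export
tidy.honmf_fit <- function(x, ...) {
  purrr::map_dfr(x$modality_names, function(m) {
    h <- x$H[[m]]
    tibble::tibble(
      modality = m,
      sample_id = rep(rownames(h), times = ncol(h)),
      factor = rep(colnames(h), each = nrow(h)),
      loading = as.vector(h))
  })
}

#' One-row summary of a fitted HONMF model
#'
#' @param x An `honmf_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sizes, resolved weights, iterations, the final
#'   objective and convergence flag.
#' @method glance honmf_fit
#' @export
glance.honmf_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$sample_ids),
    n_modalities = length(x$H),
    k = x$config$k,
    variant = x$config$variant,
    alpha = x$alpha, gamma = x$gamma, beta = x$beta, eta = x$eta,
    iterations = x$iterations,
    objective = x$objective_trace[length(x$objective_trace)],
    converged = x$converged)
}

#' Plot the objective trace of a fitted HONMF model
#'
#' @param object An `honmf_fit`.
#' @param ... Unused.
#' @return A ggplot of objective value versus iteration (log10 y scale).
#' @method autoplot honmf_fit
#' @export
autoplot.honmf_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1L,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "objective J",
                  title = "HONMF objective trace")
}

#' Write the fitted factors and consensus similarity to a directory
#'
#' Writes `S.tsv`, per-modality `H_<name>.tsv` and `G_<name>.tsv`,
#' `objective_trace.tsv` and a `config.yaml`-style echo of the resolved
#' settings.
#'
#' @param fit An `honmf_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_honmf_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_similarity(fit$S, file.path(dir, "S.tsv"))
  for (m in fit$modality_names) {
    utils::write.table(fit$H[[m]], file.path(dir, paste0("H_", m, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(fit$G[[m]], file.path(dir, paste0("G_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(iteration = seq_along(fit$objective_trace) - 1L,
               objective = fit$objective_trace),
    file.path(dir, "objective_trace.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- fit$config
  writeLines(c(
    paste0("k: ", cfg$k),
    paste0("variant: ", cfg$variant),
    paste0("alpha: ", format(fit$alpha)),
    paste0("gamma: ", format(fit$gamma)),
    paste0("beta: ", format(fit$beta)),
    paste0("eta: ", format(fit$eta)),
    paste0("max_iter: ", cfg$max_iter),
    paste0("tol: ", format(cfg$tol)),
    paste0("seed: ", cfg$seed)
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}
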