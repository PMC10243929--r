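# Independent reference implementations used as oracles. These are written in
# deliberately naive loop/enumeration style and must stay independent of the
# package internals they check.

# pair-counting adjusted Rand index: iterate over all unordered sample pairs
ref_ari_paircount <- function(g, p) {
  n <- length(g)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_g <- g[i] == g[j]
      same_p <- p[i] == p[j]
      if (same_g && same_p) a <- a + 1
      else if (same_g && !same_p) b <- b + 1
      else if (!same_g && same_p) c_ <- c_ + 1
      else d <- d + 1
    }
  }
  tot <- a + b + c_ + d
  expected <- (a + b) * (a + c_) / tot
  denom <- ((a + b) + (a + c_)) / 2 - expected
  if (denom == 0) return(ifelse(a == expected, 1, 0))
  (a - expected) / denom
}

# contingency-table NMI with explicit loops
ref_nmi_contingency <- function(g, p) {
  n <- length(g)
  gu <- unique(g); pu <- unique(p)
  nij <- matrix(0, length(gu), length(pu))
  for (s in seq_len(n)) {
    nij[match(g[s], gu), match(p[s], pu)] <- nij[match(g[s], gu), match(p[s], pu)] + 1
  }
  ni <- rowSums(nij); nj <- colSums(nij)
  hg <- 0; for (x in ni) hg <- hg - (x / n) * log(x / n)
  hp <- 0; for (x in nj) hp <- hp - (x / n) * log(x / n)
  if (hg == 0 || hp == 0) return(ifelse(hg == 0 && hp == 0, 1, 0))
  mi <- 0
  for (i in seq_along(gu)) for (j in seq_along(pu)) {
    if (nij[i, j] > 0) {
      mi <- mi + (nij[i, j] / n) * log(n * nij[i, j] / (ni[i] * nj[j]))
    }
  }
  mi / sqrt(hg * hp)
}

# brute-force hypergraph smoothness: (1/2) sum_e sum_{i,j in e} (w_e/delta_e) ||h_i - h_j||^2
ref_hypergraph_smoothness <- function(H, hyperedges, weights) {
  tot <- 0
  for (e in seq_along(hyperedges)) {
    verts <- hyperedges[[e]]
    delta <- length(verts)
    for (i in verts) for (j in verts) {
      tot <- tot + (weights[e] / delta) * sum((H[i, ] - H[j, ])^2)
    }
  }
  tot / 2
}

# brute-force simple-graph smoothness: (1/2) sum_{u,v} w_uv ||h_u - h_v||^2
ref_graph_smoothness <- function(H, W) {
  tot <- 0
  n <- nrow(W)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    tot <- tot + W[u, v] * sum((H[u, ] - H[v, ])^2)
  }
  tot / 2
}

# straight-line reference of the SNF cross-diffusion iteration
ref_snf <- function(A_list, k, iterations) {
  norm1 <- function(W) {
    rs <- rowSums(W) - diag(W)
    rs[rs == 0] <- 1
    P <- W / (2 * rs)
    diag(P) <- 0.5
    P
  }
  local_k <- function(W, k) {
    n <- nrow(W)
    S <- matrix(0, n, n)
    for (u in seq_len(n)) {
      s <- W[u, ]; s[u] <- -Inf
      nb <- order(-s, seq_len(n))[seq_len(k)]
      S[u, nb] <- W[u, nb]
    }
    S / pmax(rowSums(S), .Machine$double.eps)
  }
  P <- lapply(A_list, function(a) { p <- norm1(a); (p + t(p)) / 2 })
  Sk <- lapply(A_list, local_k, k = k)
  M <- length(P)
  for (t in seq_len(iterations)) {
    Pn <- vector("list", M)
    for (v in seq_len(M)) {
      acc <- matrix(0, nrow(P[[1]]), ncol(P[[1]]))
      for (u in seq_len(M)) if (u != v) acc <- acc + P[[u]]
      p <- Sk[[v]] %*% (acc / (M - 1)) %*% t(Sk[[v]])
      p <- norm1(p)
      Pn[[v]] <- (p + t(p)) / 2
    }
    P <- Pn
  }
  W <- Reduce(`+`, P) / M
  W <- norm1(W)
  (W + t(W)) / 2
}

# random valid hypergraph over n vertices: every vertex covered (vertices are
# partitioned over the hyperedges, then each hyperedge gains random extras),
# every hyperedge of size >= 2
random_hypergraph <- function(n, n_edges) {
  assign <- sample(rep_len(seq_len(n_edges), n))
  hyperedges <- lapply(seq_len(n_edges), function(e) {
    base <- which(assign == e)
    pool <- setdiff(seq_len(n), base)
    extra <- if (length(pool) > 0) {
      pool[sample.int(length(pool), sample.int(length(pool) + 1L, 1) - 1L)]
    } else integer(0)
    out <- sort(unique(c(base, extra)))
    if (length(out) < 2) out <- sort(c(out, pool[1]))
    out
  })
  list(hyperedges = hyperedges, weights = runif(n_edges, 0.2, 2))
}

# assemble a `hypergraph` object from explicit parts (bypasses kernel weights)
manual_hypergraph <- function(n, hyperedges, weights) {
  P <- matrix(0, n, length(hyperedges))
  for (e in seq_along(hyperedges)) P[hyperedges[[e]], e] <- 1
  structure(list(incidence = P, weights = weights,
                 vertex_degrees = as.numeric(P %*% weights),
                 hyperedge_degrees = colSums(P),
                 hyperedges = hyperedges, sample_ids = NULL),
            class = "hypergraph")
}

# two-block toy affinity: high similarity within blocks, low across
block_affinity <- function(sizes, within = 0.9, across = 0.05) {
  lab <- rep(seq_along(sizes), sizes)
  A <- ifelse(outer(lab, lab, "=="), within, across)
  diag(A) <- 1
  A
}

# small abundance matrix with distinct sample columns
toy_abundance <- function(p = 4, n = 5, seed = 42) {
  withr::with_seed(seed, {
    abundance_matrix(matrix(rpois(p * n, 10), p, n),
                     feature_ids = paste0("f", seq_len(p)),
                     sample_ids = paste0("s", seq_len(n)))
  })
}
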