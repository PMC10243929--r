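---
title: "Integrating multi-omics microbiome profiles with hypergraph-regularized orthogonal NMF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating multi-omics microbiome profiles with hypergraph-regularized orthogonal NMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honmf)
```

## The problem

Bacterial (16S), fungal (ITS) and viral composition profiles can now be
measured on the *same* biological samples. Each kingdom's profile carries its
own signal about how samples group — disease state, antibiotic exposure, soil
ecosystem — but also its own noise, sparsity and batch structure. Methods that
force a single shared latent representation (MOFA-style) or a single shared
similarity network (SNF-style) onto all kingdoms can blur kingdom-specific
structure. This package takes the middle road: each modality keeps its own
latent factors, and a consensus sample-similarity matrix is learned that the
per-modality factor kernels are softly pulled towards.

## The model

For modality $i = 1,\dots,M$ ($M \in \{2,3\}$) with non-negative abundance
matrix $X_i$ (features $\times$ $n$ samples), a Gaussian-kernel sample
similarity $A_i \in \mathbb{R}^{n \times n}_{+}$ is computed. The model
estimates per-modality factors $H_i \in \mathbb{R}^{n \times k}_{+}$,
symmetric mixing matrices $G_i \in \mathbb{R}^{k \times k}_{+}$ and a
consensus similarity $S \in \mathbb{R}^{n \times n}_{+}$ by minimizing

$$
J = \sum_i \lVert A_i - H_i G_i H_i^\top \rVert_F^2
  + \frac{\alpha}{2} \sum_i \lVert S - H_i H_i^\top \rVert_F^2
  + \eta \sum_i \lVert H_i^\top H_i - I \rVert_F^2
  + \beta \lVert S\mathbf{1} - \mathbf{1} \rVert^2
  + \gamma \sum_i \operatorname{tr}(H_i^\top L_i H_i),
$$

subject to non-negativity of all factors. The five terms are, in order: the
symmetric tri-factorization of each modality's kernel; the graph-fusion pull
of each kernel $H_i H_i^\top$ towards the consensus $S$; a soft
column-orthogonality constraint that keeps $H_i$ close to a cluster-indicator
form; a soft row-normalization of $S$; and a hypergraph smoothness penalty
that asks each modality's factors to be constant across groups of samples
that already look alike in that modality.

### The hypergraph term

$L_i$ is the Laplacian $L = D_v - P W D_e^{-1} P^\top$ of a hypergraph whose
hyperedges are Louvain communities of the KNN-sparsified affinity graph of
modality $i$ (KNN size $\lfloor n/2 \rfloor$ by default, matching the
clustering protocol). A hyperedge connects a whole community at once, so the
penalty couples *groups* of samples rather than pairs — the high-order
structure a pairwise graph Laplacian cannot express. Each hyperedge's weight
is the total pairwise Gaussian similarity among its members, with the kernel
bandwidth set to the mean squared distance within the hyperedge; an all-
identical hyperedge takes the continuous limit (kernel value 1 per pair).
The quadratic form satisfies the identity
$\operatorname{tr}(H^\top L H) = \tfrac12 \sum_e \sum_{u,v \in e}
(w_e/\delta_e)\lVert h_u - h_v \rVert^2$, which the test suite verifies
against a brute-force double sum. Replacing $L_i$ by the simple-graph
Laplacian $D - W$ of the KNN affinity gives the `gonmf` ablation variant.

Three choices here were genuinely open and are worth recording:

* **Which graph Louvain runs on.** Community detection runs on the
  KNN-sparsified kernel, not the dense one: dense Gaussian kernels on small
  $n$ are near-complete graphs on which modularity has little contrast.
  The KNN size and Louvain resolution are exposed in the configuration.
* **"Total similarity" as a hyperedge weight** is read as the sum over
  unordered member pairs: including self-pairs would only add a constant
  $|e|$ offset per hyperedge.
* **Singleton communities** are merged into the community of their most
  similar neighbour, since a singleton hyperedge contributes identically
  zero to $L$ and would leave its vertex unregularized.

### Initialization and automatic weights

$H_i$ is initialized by a symmetric NNDSVD-style scheme: the top-$k$
eigenpairs of $A_i$, each eigenvector split into positive and negative parts
with the dominant part kept and scaled by $\sqrt{\lambda_j}$. Exact zeros are
filled with $\mathrm{mean}(A_i)/100$ — multiplicative updates cannot move an
exact zero, and the fill keeps the initialization deterministic.
$G_i$ starts at the identity. $S$ starts from a minimal similarity-network-
fusion (SNF) pass over the $A_i$ (row-normalized kernels, KNN local kernels
with $k = \max(3, \lfloor n/10 \rfloor)$, 20 cross-diffusion iterations) —
only the quality of the starting point depends on these settings.

$\eta = 10$ and $\beta = 1$ are fixed defaults. $\alpha$ and $\gamma$
default to automatic selection from the initialized state:

$$
\alpha = \frac{\sum_i \lVert A_i - \hat H_i \hat G_i \hat H_i^\top \rVert_F^2}
              {\sum_i \lVert \hat S - \hat H_i \hat H_i^\top \rVert_F^2},
\qquad
\gamma = \frac{\sum_i \lVert A_i - \hat H_i \hat G_i \hat H_i^\top \rVert_F^2}
              {\sum_i \operatorname{tr}(\hat H_i^\top L_i \hat H_i)},
$$

i.e. each regularizer enters at the scale of the reconstruction residual. A
zero denominator (e.g. factors already block-constant on the hyperedges)
falls back to 1 with a warning.

### Optimization

No closed-form solution exists; the package uses block-coordinate
multiplicative updates derived by the split-gradient rule: for each block,
the gradient is separated into its non-negative positive and negative parts
and the block is multiplied elementwise by (negative part)/(positive part),
with a $10^{-12}$ floor in denominators. For $H_i$ the parts are

* numerator: $4 A_i H_i G_i + 2\alpha S H_i + 4\eta H_i + 2\gamma L_i^- H_i$
* denominator: $4 H_i G_i H_i^\top H_i G_i + 2\alpha H_i H_i^\top H_i +
  4\eta H_i H_i^\top H_i + 2\gamma L_i^+ H_i$

where $L^\pm$ are the elementwise positive/negative parts of the Laplacian.
$G_i$ and $S$ see objectives quadratic in themselves and use the analogous
plain ratios; $G_i$ is re-symmetrized after each update, and $S$ is
symmetrized once at the end (its update couples rows through the soft
row-sum penalty, which is mildly asymmetric during iteration).

The objective is quartic in $H_i$, and plain multiplicative ratios are not
guaranteed monotone for quartic terms in general. The suite therefore audits
monotonicity explicitly — from random non-negative starting points and from
the standard initialization, the trace must be non-increasing within a
relative slack of $10^{-8}$ per step — and the audit passes with the plain
ratio. A `damping` exponent ($<1$, the square-root damping familiar from
symmetric NMF) is exposed in the configuration as a safeguard but is not
needed under the default settings. Convergence is declared when the relative
objective change drops below `tol` ($10^{-6}$ by default, at most 500
sweeps). Within each sweep the order is $H_1..H_M$, $G_1..G_M$, then $S$.

Two numerical notes. The automatic $\alpha/\gamma$ ratios are defined on the
kernel matrices $A_i$: the abundance matrices $X_i$ ($p \times n$) would be
dimensionally incompatible with $\hat H \hat G \hat H^\top$ ($n \times n$),
so the kernels are the only reading consistent with the first objective
term. The per-iteration factors are not re-normalized; the monotonicity
audit is the guard for that choice. And with $G_i$ initialized at the
identity, off-diagonal entries of $G_i$ stay zero under multiplicative
updates, so $G_i$ remains diagonal throughout — a consequence of the
identity initialization, not a bug; $G_i$ then carries per-factor scales.

## Downstream analyses

**Clustering.** The learned $S$ is sparsified to a KNN graph with
$k = \lfloor n/2 \rfloor$ and Louvain communities are reported as clusters.
Louvain chooses its own number of communities; when a fixed cluster count
must be imposed (as when comparing against a known $k$), normalized spectral
clustering of $S$ with k-means is provided (`method = "spectral_k"`).

**Feature selection.** Features are ranked by the Laplacian score on $S$:
with $D = \mathrm{diag}(S\mathbf{1})$, $L = D - S$ and the $D$-centred
feature $\tilde f$, $SC(f) = (\tilde f^\top L \tilde f)/(\tilde f^\top D
\tilde f)$. Low scores mark features smooth on the similarity structure yet
variable across it — the discriminative ones. The score is scale- and
shift-invariant; constant features are undefined and receive an `Inf`
sentinel so they are never selected. Features are interpreted as row vectors
(1 × n) of the abundance matrix throughout.

**Cross-kingdom associations.** For selected features $a, b$ from different
modalities, the association is the Pearson correlation of the smoothed
vectors $\hat a = aS$, $\hat b = bS$; edges with $|corr| > 0.5$ are
retained, signed. The raw (un-normalized) final $S$ is used for smoothing.
A caution the synthetic experiments make vivid: smoothing projects every
feature onto the sample-similarity structure, so even structure-free noise
features can appear strongly correlated *after* smoothing. The Laplacian-
score selection step is what keeps such features out of the network; the
association analysis is meaningful only downstream of selection.

**Metrics.** ARI (pair-counting, chance-corrected), NMI (geometric-mean
normalization $MI/\sqrt{H(G)H(P)}$, the convention of the clustering
literature the model builds on) and a similarity-based silhouette. For the
silhouette, similarities are converted to distances by $d = 1 - S/\max(S)$
(bounded and invariant to positive rescaling of $S$; $d = \max(S) - S$ is
available as an option), then the standard three-case per-sample score is
averaged; singleton clusters contribute 0. Partitions are encoded as 0-based
contiguous integer labels.

## The synthetic generator

`simulate_multiomics()` emulates the shape of matched multi-kingdom
composition data: $M$ feature-by-sample count tables over one planted sample
partition. Per modality, each cluster owns a disjoint block of
`floor(p/(K+1))` features whose negative-binomial mean is elevated
(fold change $1 + 9 \cdot \mathrm{separation}$ over a baseline mean of 5,
dispersion size 8); remaining features are undifferentiated noise; entries
are independently zeroed at the dropout rate (0.2 by default) to mimic
zero-inflation. At `separation = 1` the planted structure is fully
separable — the regime in which the pipeline is expected to recover the
partition exactly — while 0.2 (a 2.8-fold change) is deliberately hard and
leaves recovery partial. The generator is a pure function of its arguments
(seed included).

What it does *not* emulate: compositional closure coupling across features,
taxon-correlated dropout, library-size gradients, batch effects, or
phylogenetic correlation among features. Tests passing on this generator
show the algorithm recovers planted block structure under count noise and
sparsity; they do not certify performance on real sequencing data.

## Study sizes and numerical choices

The packaged tests and the acceptance script run at $n = 30$ samples, 3
planted clusters, feature counts (40, 30, 20) over 10 seeds — comfortably
past the regime where the model is identifiable, while keeping a full
multi-seed sweep fast on one core. Tie-breaks everywhere (KNN neighbour
selection, feature-rank ties) go to the lowest index, for reproducibility.
KNN graphs are symmetrized by union, which keeps small-$n$ graphs connected;
intersection symmetrization is not offered. All stochastic components
(Louvain sweeps, k-means restarts) are driven by an explicit seed, and a
fixed configuration plus seed reproduces $S$, $H_i$, $G_i$ bit for bit.

## Limitations

* The automatic $\alpha/\gamma$ rule is a heuristic scale-matching at the
  initial point, not an optimality condition; poor initializations propagate
  into the weights.
* Multiplicative updates converge to stationary points only; different seeds
  can reach different local minima (the orthogonality penalty reduces but
  does not remove this).
* Louvain on the $\lfloor n/2 \rfloor$-NN graph can be unstable for very
  small $n$ or near-uniform similarity; the spectral path is the fallback.
* Samples missing from any modality are dropped, not imputed: the model
  requires matched samples.
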