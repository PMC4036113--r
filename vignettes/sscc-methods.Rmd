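---
title: "Semi-supervised consensus clustering: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised consensus clustering: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sscc)
```

## The problem

Class discovery in gene-expression data — grouping tumour samples into
subtypes, say — has two chronic difficulties: the matrices are noisy and
extremely wide (tens to hundreds of samples against thousands of genes), and
a single clustering algorithm run once is fragile in that geometry. Two ideas
help. *Consensus clustering* runs many base clusterings on perturbed views of
the data and combines them, trading variance for robustness. *Semi-supervised
clustering* injects the small amount of prior knowledge that is often
available — pairs of samples known to belong to the same class — directly
into the clustering objective. This package combines the two: prior knowledge
is injected into every member of a subspace ensemble, and the ensemble is
combined with a link-based consensus function.

Prior knowledge takes the form of pairwise constraints: a **must-link**
asserts two samples belong to the same cluster, a **cannot-link** that they
do not. Only must-links are used by default (see *Constraint policy* below).

## The pipeline

Given an $n \times d$ matrix $X$ of $n$ samples and $d$ genes, a target
cluster count $k$, and a set of $l$ must-link pairs:

1. **Random gene subspaces.** Each of $m$ ensemble members sees a random
   subspace of $q$ genes, with
   $q = q_{\min} + \lfloor \alpha (q_{\max} - q_{\min}) \rfloor$,
   $\alpha \sim U[0,1]$, and $q_{\min} = \lfloor 0.75\,d \rfloor$,
   $q_{\max} = \lfloor 0.85\,d \rfloor$ by default. Genes are drawn without
   replacement, fresh per member.

2. **Constraint-injected spectral clustering** (the base algorithm). On each
   subspace: Gaussian similarity with per-point local scaling
   $s_{ij} = \exp(-\lVert x_i - x_j \rVert^2 / \sigma_i \sigma_j)$, where
   $\sigma_i$ is the distance from sample $i$ to its $t$-th nearest
   neighbour; sparsification to the $t$-nearest-neighbour graph (an edge
   survives if either endpoint lists the other among its $t$ most similar
   — the union rule, so the graph stays symmetric); then constraint
   injection, $s_{ij} = s_{ji} = 1$ for each must-link (creating the edge if
   the t-NN graph lacked it). Normalized spectral clustering follows: the top
   $k$ eigenvectors of $D^{-1/2} W D^{-1/2}$, rows normalized to unit length,
   partitioned by seeded k-means.

3. **Association matrices.** The basic matrix $BM$ ($n \times g$,
   $g = \sum_i k_i$) records crisp memberships: $BM(x_i, C_j) = 1$ iff
   sample $i$ was assigned to ensemble cluster $C_j$. The refined matrix
   $RM$ keeps the ones and fills each zero with the similarity between
   $C_j$ and the cluster that $x_i$ *was* assigned to in the same member.
   Cluster–cluster similarity comes from a weighted cluster graph: edge
   weights are Jaccard indices of the clusters' sample sets, the
   weighted-connected-triple score of a pair accumulates
   $\min(w_{ac}, w_{cb})$ over shared neighbours $c$, and scores are
   normalized by the maximum over distinct pairs and scaled by a decay
   constant (0.9 by default). Clusters of the same member never overlap, so
   their direct weight is zero — their similarity arises purely through
   connected triples, which is exactly what makes the refinement
   informative.

4. **Hybrid bipartite consensus.** Samples and ensemble clusters together
   form the two sides of a bipartite graph with biadjacency $RM$; normalized
   spectral clustering of all $n + g$ vertices yields the final partition
   (read off the sample vertices). This keeps sample–sample and
   cluster–cluster relations in one spectral problem rather than collapsing
   to a co-association matrix first.

With no constraints the pipeline is a pure (unsupervised) consensus
clusterer; with k-means base members instead of spectral ones it reproduces
the classic link-based cluster ensemble configuration (`algorithm = "lce"`),
and the single-run algorithms (`ssc`, `sc`, `kmeans`) are available for
comparison.

## Evaluation protocol

External validity is scored with normalized mutual information,
$\mathrm{NMI}(X,Y) = I(X,Y)/\sqrt{H(X)H(Y)}$, and the Hubert–Arabie adjusted
Rand index. Both are computed from the contingency table; NMI uses the
convention $0 \log 0 = 0$ and returns 1/0 in the zero-entropy corner cases
depending on whether the partitions coincide.

The effect of prior knowledge is measured with a constraint-aware $h$-fold
cross-validation (default $h = 5$): per run, samples are shuffled into
class-stratified folds; per fold, the $l$ must-links are drawn only from
within-class pairs among the $h-1$ training folds; the algorithm clusters
*all* samples (clustering is transductive); and NMI/ARI are computed on the
held-out fold alone, whose samples contributed no prior knowledge. All
algorithms inside a run share the fold split, the constraint draw and the
seed, so comparisons are paired — and an algorithm that ignores its
constraints (e.g. `sc`) is run-for-run identical to its constrained
counterpart at $l = 0$. Summaries report the mean across run means with a
normal-approximation 95% confidence interval ($\pm 1.96\,\mathrm{SE}$).

A small accounting helper reports $l$ constraints over $n$ samples as
$100\,l/(n^2/2)$ truncated to two decimals, the convention under which the
usual benchmark tables quote "constraints % in total".

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | — | number of clusters; assumed known (class count) |
| `m` | 10 | ensemble size; gains beyond 10–20 are usually small |
| `t` | 5 | neighbourhood size of the similarity graph and of the local scaling; smaller tends to work better on expression data |
| `subspace_bounds` | (0.75, 0.85) | gene-subspace fraction range |
| `decay` | 0.9 | scales connected-triple similarities into $[0, 0.9]$ |
| `l` | — | number of must-links; the interesting experimental dial |
| `seed` | 1 | master seed; every stochastic component derives its own stream from it |

## Numerical and design choices

- **Local vs global bandwidth.** Per-point local scaling
  ($\sigma_i$ = distance to the $t$-th neighbour) is the default; a single
  global bandwidth (the mean local scale) is available via
  `scaling = "global"`. Duplicated points that make $\sigma_i = 0$ fall back
  to the smallest positive distance, or 1 if none exists.
- **Eigendecomposition.** Dense symmetric `eigen()` throughout. At the
  problem sizes this package targets (a few hundred vertices, including the
  bipartite consensus graph) the dense path is exact, deterministic and
  fast; eigenvector signs are fixed so the largest-magnitude entry is
  positive.
- **k-means.** k-means++ seeding, 10 restarts, Lloyd iterations capped at
  300, best within-cluster sum of squares kept, fully seeded. When the data
  have at most $k$ distinct rows, each distinct row becomes its own cluster.
- **Two-way cuts.** For $k = 2$ the k-means result is complemented by the
  classical sweep cut over the second normalized eigenvector and the
  candidate with the smaller normalized cut is kept. On small random graphs
  this reliably attains the exhaustively-verified minimum normalized cut,
  which the embed+k-means path alone does not.
- **Isolated vertices** (possible after constraint edits) get degree
  contribution zero and a zero embedding row; they are then assigned
  deterministically by k-means rather than crashing the pipeline.
- **Empty final clusters.** If the bipartite partition leaves one of the $k$
  final clusters without samples (it may capture only cluster vertices), the
  partition is re-run with derived seeds up to 3 times, then repaired by
  moving the sample nearest the empty cluster's centroid.
- **Constraint policy.** Must-links are applied after t-NN sparsification,
  so a must-link edge survives regardless of neighbourhood structure.
  Cannot-links are implemented but disabled by default (`apply_cannot`):
  breaking t-NN edges between genuinely similar samples is
  counterproductive on expression data. No transitive closure of must-links
  is computed — raw pairs only. One constraint set is shared by all ensemble
  members (resampling per member would be an alternative; sharing matches
  the protocol in which a fixed pool of prior knowledge is available per
  training set).
- **Random-k ensembles.** The `random_fullspace` ensemble type draws each
  member's cluster count uniformly from $\{2, \dots, \lceil\sqrt{n}\rceil\}$,
  the customary range in the cluster-ensemble literature.
- **Final step variant.** `final = "rowsim"` clusters samples on the cosine
  similarity of their $RM$ rows instead of the bipartite graph; the
  bipartite formulation is the default.

## The synthetic generator

`make_dataset()` draws a Gaussian class-conditional model: a fraction of
genes (default 20%) is informative, with class $c$ centred at
$c \cdot \mathrm{separation} \cdot s_j$ on informative gene $j$ (random sign
$s_j$, unit noise); the remaining genes are pure noise. Columns are shuffled;
the informative identities are returned for oracle checks. The default shape
(72 samples × 1877 genes, 3 classes) mirrors a typical leukaemia benchmark
matrix. The test suite and the acceptance script use a reduced 72 × 300
matrix at separation 0.7 — chosen so that classes genuinely overlap
(unsupervised spectral clustering recovers them only partially) while
remaining learnable — with 20 CV runs in the heaviest check, sizes chosen to
keep the full suite comfortably interactive.

The generator emulates the *geometry* of pre-processed microarray matrices
(n ≪ d, a minority of informative genes, overlapping classes) but not their
artefacts: no probe effects, batch effects, heavy tails, class-size
imbalance or correlated gene blocks. Conclusions from it transfer to real
data only to the extent that those artefacts do not dominate. Two
consequences observed in this package's own experiments are worth stating
plainly. First, on isotropic Gaussian mixtures a k-means-based ensemble is
close to optimal — spherical classes are k-means' best case — so the
advantage of a spectral base clustering that is visible on real cancer
datasets need not appear here. Second, must-links reliably improve
*full-sample* consensus accuracy and improve the single semi-supervised
spectral clusterer on held-out folds, but the consensus step already
averages away most member noise without constraints, so on this generator
the *held-out-fold* benefit of constraints under consensus can vanish: the
remaining test errors are boundary samples that prior knowledge about other
samples cannot move. The cross-validated quantities that the package
computes make both effects visible and reproducible.

## Known limitations

- Complexity is dominated by building the t-NN similarity matrix per member,
  $O(m n^2 d)$ overall; thousands of samples call for approximate
  neighbour search, which is out of scope here.
- The number of clusters $k$ is assumed known; no model selection.
- Constraints are hard (weight exactly 1); no soft or weighted constraints.
- Fully-connected similarity graphs are not offered — the t-NN graph is the
  designed regime for expression data.
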