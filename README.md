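# sscc — semi-supervised consensus clustering for gene expression data

`sscc` clusters samples in gene-expression matrices (bulk microarray or
RNA-seq style, samples × genes) when a small amount of prior knowledge is
available as pairwise **must-link** constraints — pairs of samples known to
belong to the same class, e.g. from a handful of confirmed diagnoses. It is
aimed at class-discovery problems such as cancer subtype identification,
where matrices are wide (n ≪ d), noisy, and no single clustering run is
trustworthy.

## The method

The core algorithm combines consensus clustering with constraint-injected
spectral clustering:

1. **Base clusterings.** Each of m ensemble members clusters a random gene
   subspace of size q = q_min + ⌊α(q_max − q_min)⌋, α ~ U[0,1], with
   q_min = 0.75 d and q_max = 0.85 d. The base algorithm is normalized
   spectral clustering on a t-nearest-neighbour graph with locally scaled
   Gaussian similarity s_ij = exp(−‖x_i − x_j‖²/σ_i σ_j); every must-link
   (i, j) sets s_ij = s_ji = 1 after sparsification.
2. **Link-based refinement.** The crisp sample × cluster association matrix
   BM is refined into RM by filling its zeros with cluster–cluster
   similarities from a weighted cluster graph (Jaccard edge weights,
   weighted connected-triple scores, decay 0.9).
3. **Bipartite consensus.** Samples and ensemble clusters form a bipartite
   graph with biadjacency RM; normalized spectral clustering of all
   n + g vertices yields the final k-way partition.

Partitions are scored against known labels with NMI
(I(X,Y)/√(H(X)H(Y))) and the adjusted Rand index, and the value of prior
knowledge is quantified by a constraint-aware h-fold cross-validation:
constraints are drawn only from training-fold pairs, clustering is
transductive, and scores are computed on the held-out fold alone.

The package also provides the comparison algorithms from the same family —
single semi-supervised spectral clustering (`ssc`), its unsupervised form
(`sc`), the unsupervised k-means-based link ensemble (`lce`), and plain
k-means — plus a seeded synthetic expression-data generator
(`make_dataset()`) with controllable class separation, informative-gene
fraction and noise.

## Worked example

```r
library(sscc)

ds <- make_dataset(n = 72, d = 300, k = 3, informative_frac = 0.2,
                   separation = 0.7, noise_sd = 1, seed = 7)
cs <- generate_must_links(ds$labels, l = 50, seed = 7)

unsup <- run_sscc(ds$expression, k = 3, seed = 7)
semi  <- run_sscc(ds$expression, k = 3, constraints = cs, seed = 7)

nmi(unsup, ds$labels)  # 0.652
nmi(semi,  ds$labels)  # 0.895
ari(semi,  ds$labels)  # 0.917

cross_validate(ds$expression, ds$labels, k = 3,
               algorithms = c("sscc", "sc"), l = 50, h = 5, runs = 3,
               seed = 7)
#>   algorithm n_constraints runs nmi_mean nmi_lo nmi_hi ari_mean ari_lo ari_hi
#> 1        sc            50    3   0.5338 0.5120 0.5555   0.3726 0.3558 0.3894
#> 2      sscc            50    3   0.8474 0.8241 0.8707   0.7892 0.7457 0.8328
```

The first three numbers show the effect of prior knowledge on one full-data
run: 50 must-links (0.77% of all sample pairs at this n) lift NMI from 0.652
to 0.895. The cross-validation table scores only held-out samples whose
labels contributed no constraints; the consensus pipeline (`sscc`) clearly
outperforms a single spectral clustering (`sc`) under identical folds and
seeds.

A command-line wrapper is installed with the package
(`<library>/sscc/exec/sscc`) with `cluster`, `eval` and `simulate`
subcommands; run it with `--help` for options.

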