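#' Basic cluster-association matrix
#'
#' Binary n x g matrix over the ensemble's g = sum(k_i) clusters: entry
#' (i, j) is 1 iff sample i belongs to ensemble cluster j. Columns group the
#' members consecutively and are labelled `member:cluster`.
#'
#' @param ensemble a `cluster_ensemble` from [build_ensemble()].
#' @return Binary matrix with attributes `member` and `cluster` (integer
#'   vectors mapping each column to its ensemble member and within-member
#'   cluster index).
#' @export
build_bm <- function(ensemble) {
  sols <- ensemble$solutions
  if (length(sols) == 0L) abort("empty ensemble")
  n <- length(sols[[1L]])
  if (any(lengths(sols) != n)) abort("ensemble solutions have inconsistent lengths")
  k_list <- ensemble$k_list
  g <- sum(k_list)
  bm <- matrix(0L, n, g)
  member <- integer(g); cluster <- integer(g)
  off <- 0L
  for (i in seq_along(sols)) {
    ki <- k_list[i]
    lab <- sols[[i]]
    if (any(lab < 1L | lab > ki)) abort("member %d labels outside 1..%d", i, ki)
    bm[cbind(seq_len(n), off + lab)] <- 1L
    member[off + seq_len(ki)] <- i
    cluster[off + seq_len(ki)] <- seq_len(ki)
    off <- off + ki
  }
  colnames(bm) <- paste(member, cluster, sep = ":")
  attr(bm, "member") <- member
  attr(bm, "cluster") <- cluster
  bm
}

#' Weighted cluster graph with connected-triple similarity
#'
#' Edge weight between two ensemble clusters is the Jaccard index of their
#' member-sample sets. The weighted-connected-triple score of a pair (a, b)
#' accumulates min(w_ac, w_cb) over all other clusters c; scores are
#' normalized by the global maximum and scaled by the decay constant, giving
#' the final cluster-cluster similarity (diagonal 1). Clusters from the same
#' member have Jaccard weight 0 (disjoint sample sets) but can still earn
#' similarity through shared neighbours — that is what fills the zeros of the
#' basic association matrix.
#'
#' @param bm basic association matrix from [build_bm()].
#' @param decay decay constant in \[0, 1\] (default 0.9).
#' @return A list of class `cluster_graph`: `weights` (g x g Jaccard matrix,
#'   zero diagonal), `wct` (raw connected-triple scores), `sim` (final
#'   similarity, unit diagonal), `decay`.
#' @export
cluster_similarity_wct <- function(bm, decay = 0.9) {
  if (!is.numeric(decay) || length(decay) != 1L || decay < 0 || decay > 1) {
    abort("decay must be a single value in [0, 1]")
  }
  g <- ncol(bm)
  inter <- crossprod(bm)                       # |a intersect b|
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter      # |a union b|
  w <- ifelse(uni > 0, inter / uni, 0)
  diag(w) <- 0
  # WCT_ab = sum_c min(w_ac, w_cb); zero diagonal makes the c = a, b terms vanish
  wct <- matrix(0, g, g)
  for (a in seq_len(g)) wct[a, ] <- colSums(pmin(w, w[, a]))
  diag(wct) <- 0   # only distinct pairs are scored or normalized against
  wct_max <- max(wct)
  sim <- if (wct_max > 0) wct / wct_max * decay else matrix(0, g, g)
  diag(sim) <- 1
  dimnames(w) <- dimnames(wct) <- dimnames(sim) <- list(colnames(bm), colnames(bm))
  structure(list(weights = w, wct = wct, sim = sim, decay = decay),
            class = "cluster_graph")
}

#' Refined cluster-association matrix
#'
#' Keeps the 1 entries of the basic matrix and fills each 0 entry (i, j) with
#' the cluster-graph similarity between cluster j and the cluster that sample
#' i belongs to in the same ensemble member as j — the association a sample
#' "probably" has with clusters it was not assigned to.
#'
#' @param bm basic association matrix from [build_bm()].
#' @param graph a `cluster_graph` from [cluster_similarity_wct()] on the same
#'   ensemble.
#' @return Numeric n x g matrix with entries in \[0, 1\], equal to 1 wherever
#'   `bm` is 1.
#' @export
refine_bm <- function(bm, graph) {
  sim <- graph$sim
  if (ncol(bm) != ncol(sim)) {
    abort("association matrix has %d clusters but cluster graph has %d",
          ncol(bm), ncol(sim))
  }
  member <- attr(bm, "member")
  n <- nrow(bm)
  rm_ <- matrix(0, n, ncol(bm))
  for (mi in unique(member)) {
    cols <- which(member == mi)
    assigned <- cols[max.col(bm[, cols, drop = FALSE], ties.method = "first")]
    rm_[, cols] <- sim[assigned, cols, drop = FALSE]
  }
  rm_[bm == 1L] <- 1
  dimnames(rm_) <- dimnames(bm)
  attr(rm_, "member") <- member
  attr(rm_, "cluster") <- attr(bm, "cluster")
  rm_
}

#' Final consensus partition via the hybrid bipartite graph
#'
#' Models samples and ensemble clusters together as the two vertex sets of a
#' bipartite graph whose biadjacency is the refined association matrix, runs
#' normalized spectral clustering on all n + g vertices, and returns the
#' assignment of the n sample vertices. If some of the k clusters receive no
#' samples (they may capture only cluster vertices), the partition is re-run
#' with derived seeds up to 3 times and then repaired by moving, for each
#' empty cluster, the sample vertex closest to that cluster's centroid in the
#' spectral embedding.
#'
#' @param rm_ refined (or basic) association matrix, n samples x g clusters.
#' @param k number of final clusters, `k <= n`.
#' @param seed integer seed.
#' @return Integer vector of length n with labels in `1..k`.
#' @export
hbgf_partition <- function(rm_, k, seed = 1L) {
  n <- nrow(rm_); g <- ncol(rm_)
  k <- check_count(k, "k")
  if (k > n) abort("k (%d) must not exceed the number of samples (%d)", k, n)
  if (all(rm_ == 0)) abort("degenerate ensemble: association matrix is all zero")
  if (k == 1L) return(rep(1L, n))

  adj <- rbind(cbind(matrix(0, n, n), rm_),
               cbind(t(rm_), matrix(0, g, g)))
  emb <- spectral_embed(adj, k)

  labels <- NULL
  for (attempt in 0:3) {
    lab <- kmeans_assign(emb, k, seed = derive_seed(seed, attempt))
    if (attempt == 0L && k == 2L) {
      sw <- sweep_cut2(adj)
      if (ncut_of(adj, sw) < ncut_of(adj, lab)) lab <- sw
    }
    labels <- lab[seq_len(n)]
    if (length(unique(labels)) == k) return(labels)
  }
  # nearest-centroid repair: pull one sample into each sample-empty cluster
  full <- lab
  for (j in setdiff(seq_len(k), unique(labels))) {
    members <- which(full == j)
    if (length(members) == 0L) next
    centroid <- colMeans(emb[members, , drop = FALSE])
    d2 <- colSums((t(emb[seq_len(n), , drop = FALSE]) - centroid)^2)
    movable <- which(tabulate(labels, k)[labels] > 1L)
    if (length(movable) == 0L) movable <- seq_len(n)
    pick <- movable[which.min(d2[movable])]
    labels[pick] <- j
    full[pick] <- j
  }
  labels
}

#' Semi-supervised consensus clustering
#'
#' End-to-end pipeline: build the base-clustering ensemble (constraint-
#' injected spectral clustering on random gene subspaces by default), form the
#' basic and refined cluster-association matrices through the weighted
#' cluster graph, and partition the hybrid bipartite graph with spectral
#' clustering. With an empty constraint set this is a pure consensus
#' clusterer; with `base = "kmeans"` and no constraints it is the unsupervised
#' link-based cluster ensemble configuration.
#'
#' @inheritParams build_ensemble
#' @param decay decay constant of the cluster graph (default 0.9).
#' @param final `"hbgf"` (default) partitions the bipartite sample+cluster
#'   graph; `"rowsim"` instead clusters samples on the similarity of their
#'   refined association rows (cosine), kept as a variant.
#' @return Integer vector of final cluster labels in `1..k`.
#' @export
run_sscc <- function(x, k, constraints = NULL, m = 10L, t = 5L,
                     type = c("fixed_subspace", "random_fullspace"),
                     base = c("ssc", "kmeans"),
                     subspace_bounds = c(0.75, 0.85), decay = 0.9,
                     final = c("hbgf", "rowsim"), seed = 1L) {
  type <- match.arg(type)
  base <- match.arg(base)
  final <- match.arg(final)
  ens <- build_ensemble(x, k = k, m = m, constraints = constraints,
                        type = type, t = t, base = base,
                        subspace_bounds = subspace_bounds, seed = seed)
  bm <- build_bm(ens)
  graph <- cluster_similarity_wct(bm, decay = decay)
  rm_ <- refine_bm(bm, graph)
  if (final == "hbgf") {
    hbgf_partition(rm_, k, seed = derive_seed(seed, 7L))
  } else {
    # cosine similarity between refined association rows, then spectral
    nr <- sqrt(rowSums(rm_^2)); nr[nr == 0] <- 1
    u <- rm_ / nr
    s <- tcrossprod(u)
    s <- pmin(pmax((s + t(s)) / 2, 0), 1)
    diag(s) <- 0
    spectral_cluster(k = k, seed = derive_seed(seed, 7L), w = s)
  }
}

#' Cluster an expression matrix with a named algorithm
#'
#' Dispatcher used by the command-line interface and the cross-validation
#' protocol. Algorithms: `"sscc"` (semi-supervised consensus clustering),
#' `"ssc"` (single semi-supervised spectral clustering), `"lce"` (unsupervised
#' link-based consensus: k-means base clustering on subspaces, constraints
#' ignored), `"sc"` (spectral clustering, constraints ignored), `"kmeans"`
#' (k-means on the raw expression values).
#'
#' @param x samples x genes numeric matrix.
#' @param algorithm one of `"sscc"`, `"ssc"`, `"lce"`, `"sc"`, `"kmeans"`.
#' @param k number of clusters.
#' @param constraints a [constraint_set()] or `NULL`; used by sscc and ssc.
#' @param m ensemble size for consensus algorithms (default 10).
#' @param t neighbourhood size for spectral algorithms (default 5).
#' @param type ensemble type for consensus algorithms.
#' @param subspace_bounds fraction pair for subspace ensembles.
#' @param decay cluster-graph decay constant.
#' @param seed integer seed.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
cluster_expression <- function(x, algorithm = c("sscc", "ssc", "lce", "sc", "kmeans"),
                               k, constraints = NULL, m = 10L, t = 5L,
                               type = c("fixed_subspace", "random_fullspace"),
                               subspace_bounds = c(0.75, 0.85), decay = 0.9,
                               seed = 1L) {
  algorithm <- match.arg(algorithm)
  type <- match.arg(type)
  switch(algorithm,
    sscc = run_sscc(x, k = k, constraints = constraints, m = m, t = t,
                    type = type, base = "ssc",
                    subspace_bounds = subspace_bounds, decay = decay,
                    seed = seed),
    lce = run_sscc(x, k = k, constraints = NULL, m = m, t = t,
                   type = type, base = "kmeans",
                   subspace_bounds = subspace_bounds, decay = decay,
                   seed = seed),
    ssc = ssc(x, k = k, constraints = constraints, t = t, seed = seed),
    sc = ssc(x, k = k, constraints = NULL, t = t, seed = seed),
    kmeans = kmeans_assign(as.matrix(x), k = k, seed = seed)
  )
}

#' Write basic/refined association matrices as TSV (debug aid)
#' @param mat association matrix from [build_bm()] or [refine_bm()].
#' @param path output file path.
#' @export
write_association <- function(mat, path) {
  df <- data.frame(sample = seq_len(nrow(mat)), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
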