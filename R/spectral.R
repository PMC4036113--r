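#' Local scaling parameters for Gaussian similarity
#'
#' Self-tuning bandwidths: sigma_i is the Euclidean distance from sample i to
#' its `t_sigma`-th nearest other sample. When duplicated points make that
#' distance zero, the smallest positive distance from i is used instead, or 1
#' if sample i has no positive distance to any other point.
#'
#' @param x numeric matrix, samples in rows.
#' @param t_sigma which nearest neighbour defines the scale (default 5, tied to
#'   the similarity graph's neighbourhood size).
#' @return Positive numeric vector of length `nrow(x)`.
#' @export
local_scale <- function(x, t_sigma = 5L) {
  n <- nrow(x)
  t_sigma <- check_count(t_sigma, "t_sigma")
  if (t_sigma >= n) abort("t_sigma (%d) must be smaller than n (%d)", t_sigma, n)
  dm <- as.matrix(stats::dist(x))
  vapply(seq_len(n), function(i) {
    d <- sort(dm[i, -i])
    s <- d[t_sigma]
    if (s > 0) return(s)
    pos <- d[d > 0]
    if (length(pos) > 0L) pos[1L] else 1
  }, numeric(1L))
}

#' Dense Gaussian similarity matrix with local scaling
#'
#' s_ij = exp(-||x_i - x_j||^2 / (sigma_i sigma_j)) for i != j, zero diagonal.
#'
#' @param x numeric matrix, samples in rows.
#' @param sigma strictly positive bandwidth vector, length `nrow(x)` (e.g. from
#'   [local_scale()]); a single global sigma may be given and is recycled,
#'   yielding the classical exp(-d^2/sigma^2) kernel.
#' @return Symmetric n x n similarity matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @export
pairwise_similarity <- function(x, sigma) {
  n <- nrow(x)
  if (length(sigma) == 1L) sigma <- rep(sigma, n)
  if (length(sigma) != n) abort("sigma must have length 1 or n = %d", n)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) abort("sigma entries must be positive")
  d2 <- as.matrix(stats::dist(x))^2
  s <- exp(-d2 / outer(sigma, sigma))
  s <- (s + t(s)) / 2   # enforce exact symmetry against rounding
  diag(s) <- 0
  s
}

#' Sparsify a similarity matrix to a t-nearest-neighbour graph
#'
#' Keeps s_ij iff j is among the t most similar vertices to i or i is among
#' the t most similar to j (union rule), so the result is symmetric. All other
#' off-diagonal entries are set to zero.
#'
#' @param s dense symmetric similarity matrix, zero diagonal.
#' @param t neighbourhood size, `t < n`.
#' @return Symmetric n x n matrix with at most `2 t n` nonzero entries.
#' @export
knn_sparsify <- function(s, t = 5L) {
  n <- nrow(s)
  t <- check_count(t, "t")
  if (t >= n) abort("t (%d) must be smaller than n (%d)", t, n)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(s[i, ], decreasing = TRUE)   # stable: ties broken by index
    ord <- ord[ord != i]
    keep[i, ord[seq_len(t)]] <- TRUE
  }
  keep <- keep | t(keep)
  w <- s * keep
  diag(w) <- 0
  w
}

#' Spectral embedding from the symmetric normalized affinity
#'
#' Forms D^{-1/2} W D^{-1/2} (isolated vertices contribute degree zero and get
#' a zero embedding row), takes the k eigenvectors of largest eigenvalue, and
#' normalizes each row to unit Euclidean length (zero rows stay zero). This is
#' the Ng-Jordan-Weiss variant of normalized spectral clustering.
#'
#' @param w symmetric non-negative similarity/affinity matrix.
#' @param k number of embedding dimensions (target cluster count), `k <= n`.
#' @return n x k numeric matrix of spectral coordinates.
#' @export
spectral_embed <- function(w, k) {
  n <- nrow(w)
  k <- check_count(k, "k")
  if (k > n) abort("k (%d) must not exceed n (%d)", k, n)
  deg <- rowSums(w)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  a <- w * outer(dinv, dinv)
  a <- (a + t(a)) / 2
  es <- eigen(a, symmetric = TRUE)
  v <- es$vectors[, seq_len(k), drop = FALSE]
  # fix eigenvector signs deterministically (largest-|entry| component positive)
  for (j in seq_len(k)) {
    p <- which.max(abs(v[, j]))
    if (v[p, j] < 0) v[, j] <- -v[, j]
  }
  rn <- sqrt(rowSums(v^2))
  rn[rn == 0] <- 1
  v / rn
}

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to squared distance from the chosen set. Uses the current RNG.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- colSums((t(x) - x[idx[1L], ])^2)
  for (j in seq_len(k)[-1L]) {
    if (sum(d2) <= 0) {
      cand <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- cand[sample.int(length(cand), 1L)]
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, colSums((t(x) - x[idx[j], ])^2))
  }
  x[idx, , drop = FALSE]
}

#' Seeded k-means assignment
#'
#' Lloyd's algorithm (via [stats::kmeans()]) with k-means++ initialization and
#' multiple restarts, keeping the solution with the smallest total
#' within-cluster sum of squares. Fully deterministic given `seed`. When the
#' data contain at most `k` distinct rows, each distinct row becomes its own
#' cluster.
#'
#' @param x numeric matrix, samples in rows (typically a spectral embedding).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_restarts number of k-means++ restarts (default 10).
#' @param iter_max maximum Lloyd iterations per restart (default 300).
#' @return Integer vector of cluster labels in `1..k`.
#' @export
kmeans_assign <- function(x, k, seed = 1L, n_restarts = 10L, iter_max = 300L) {
  k <- check_count(k, "k")
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) abort("k (%d) must not exceed n (%d)", k, n)
  if (k == 1L) return(rep(1L, n))

  ux <- unique(x)
  if (nrow(ux) <= k) {
    key <- apply(x, 1L, paste, collapse = "\r")
    return(as.integer(factor(key, levels = unique(key))))
  }

  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_centers(x, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) abort("k-means failed on all restarts")
  as.integer(best$cluster)
}

# normalized cut of a labelled partition of the weighted graph w
ncut_of <- function(w, labels) {
  total <- 0
  for (g in unique(labels)) {
    a <- labels == g
    vol <- sum(w[a, , drop = FALSE])
    if (vol == 0) return(Inf)
    total <- total + sum(w[a, !a, drop = FALSE]) / vol
  }
  total
}

# 2-way sweep cut: order vertices by the Fiedler-style coordinate
# z = D^{-1/2} v_2 of the normalized affinity and take the prefix split with
# the smallest normalized cut
sweep_cut2 <- function(w) {
  n <- nrow(w)
  deg <- rowSums(w)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  a <- w * outer(dinv, dinv)
  v2 <- eigen((a + t(a)) / 2, symmetric = TRUE)$vectors[, 2L]
  ord <- order(dinv * v2)
  best <- NULL; best_val <- Inf
  labels <- integer(n)
  for (m in seq_len(n - 1L)) {
    labels[] <- 2L
    labels[ord[seq_len(m)]] <- 1L
    val <- ncut_of(w, labels)
    if (val < best_val) { best_val <- val; best <- labels }
  }
  best
}

# shared final step of all spectral partitioners: embed, k-means, and for
# k = 2 also the sweep cut, keeping whichever 2-partition has the smaller
# normalized cut
normalized_spectral_partition <- function(w, k, seed) {
  e <- spectral_embed(w, k)
  labels <- kmeans_assign(e, k, seed = seed)
  if (k == 2L) {
    sw <- sweep_cut2(w)
    if (ncut_of(w, sw) < ncut_of(w, labels)) labels <- sw
  }
  labels
}

#' Normalized spectral clustering on a t-nearest-neighbour graph
#'
#' Full pipeline: local scaling, Gaussian similarity, t-NN sparsification,
#' normalized spectral embedding, seeded k-means. A precomputed similarity
#' graph may be supplied instead of data, in which case the first three steps
#' are skipped.
#'
#' For two-way partitions the k-means result is complemented by the classical
#' sweep cut over the second normalized eigenvector and the candidate with the
#' smaller normalized cut is returned.
#'
#' @param x numeric matrix, samples in rows; ignored when `w` is given.
#' @param k number of clusters.
#' @param t neighbourhood size for both the graph and the local scaling.
#' @param seed integer seed for the k-means step.
#' @param w optional precomputed symmetric similarity graph.
#' @param scaling `"local"` (default) uses per-point bandwidths sigma_i;
#'   `"global"` uses one shared bandwidth, the mean of the local scales.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
spectral_cluster <- function(x = NULL, k, t = 5L, seed = 1L, w = NULL,
                             scaling = c("local", "global")) {
  if (is.null(w)) {
    if (is.null(x)) abort("supply either data `x` or a similarity graph `w`")
    scaling <- match.arg(scaling)
    x <- as.matrix(x)
    sigma <- local_scale(x, t_sigma = t)
    if (scaling == "global") sigma <- mean(sigma)
    s <- pairwise_similarity(x, sigma)
    w <- knn_sparsify(s, t)
  }
  n <- nrow(w)
  k <- check_count(k, "k")
  if (k > n) abort("k (%d) must not exceed n (%d)", k, n)
  if (k == 1L) return(rep(1L, n))
  normalized_spectral_partition(w, k, seed = seed)
}
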