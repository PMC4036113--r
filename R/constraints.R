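#' Sample must-link constraints from class labels
#'
#' Prior knowledge is emulated by drawing `l` distinct unordered within-class
#' sample pairs uniformly without replacement from the eligible samples. Pairs
#' of samples sharing a class label become must-links; no cannot-links are
#' generated.
#'
#' @param labels class labels, length n.
#' @param eligible integer vector of sample indices the pairs may be drawn
#'   from (default all samples). In cross-validation this is the training set,
#'   so that held-out samples contribute no prior knowledge.
#' @param l number of must-links to draw.
#' @param seed integer seed.
#' @return A [constraint_set()] with `l` must-links and no cannot-links.
#' @export
generate_must_links <- function(labels, eligible = seq_along(labels), l, seed = 1L) {
  n <- length(labels)
  if (!is_count(l) || l < 0) abort("`l` must be a single non-negative integer")
  l <- as.integer(l)
  eligible <- sort(unique(as.integer(eligible)))
  if (any(eligible < 1L | eligible > n)) abort("eligible indices out of range 1..%d", n)

  pairs <- within_class_pairs(labels, eligible)
  if (l > nrow(pairs)) {
    abort("requested %d must-links but only %d within-class pairs exist among eligible samples",
          l, nrow(pairs))
  }
  if (l == 0L) return(constraint_set(n = n))
  pick <- withr::with_seed(seed, sample.int(nrow(pairs), l))
  constraint_set(must = pairs[pick, , drop = FALSE], n = n)
}

# all unordered within-class pairs among the eligible indices
within_class_pairs <- function(labels, eligible) {
  out <- lapply(split(eligible, labels[eligible]), function(idx) {
    if (length(idx) < 2L) return(matrix(integer(), 0L, 2L))
    t(utils::combn(idx, 2L))
  })
  do.call(rbind, out)
}

#' Inject pairwise constraints into a similarity graph
#'
#' Must-link pairs get similarity 1 (the edge is created if the t-NN graph did
#' not contain it); cannot-link pairs get similarity 0. All other entries are
#' unchanged and symmetry is preserved. Cannot-links break t-NN edges between
#' genuinely similar samples, which is counterproductive on expression data,
#' so they are ignored with a warning unless `apply_cannot = TRUE`.
#'
#' @param w symmetric similarity graph.
#' @param constraints a [constraint_set()].
#' @param apply_cannot set `TRUE` to zero out cannot-link pairs (default FALSE).
#' @return A new similarity graph of the same dimension.
#' @export
apply_constraints <- function(w, constraints, apply_cannot = FALSE) {
  if (is.null(constraints)) return(w)
  n <- nrow(w)
  if (constraints$n != n) {
    abort("constraint set is over %d samples but graph has %d vertices",
          constraints$n, n)
  }
  m <- constraints$must
  if (nrow(m) > 0L) {
    w[cbind(m[, 1L], m[, 2L])] <- 1
    w[cbind(m[, 2L], m[, 1L])] <- 1
  }
  cl <- constraints$cannot
  if (nrow(cl) > 0L) {
    if (!apply_cannot) {
      warning("cannot-links present but disabled by policy; ignoring them ",
              "(set apply_cannot = TRUE to break graph edges)", call. = FALSE)
    } else {
      w[cbind(cl[, 1L], cl[, 2L])] <- 0
      w[cbind(cl[, 2L], cl[, 1L])] <- 0
    }
  }
  w
}

#' Semi-supervised spectral clustering
#'
#' Spectral clustering with pairwise prior knowledge: Gaussian similarity with
#' local scaling, t-nearest-neighbour sparsification, then constraint
#' injection (must-links to 1, optionally cannot-links to 0), followed by
#' normalized spectral embedding and seeded k-means. With an empty constraint
#' set this reduces exactly to unsupervised spectral clustering.
#'
#' @param x numeric matrix, samples in rows.
#' @param k number of clusters.
#' @param constraints a [constraint_set()] or `NULL`.
#' @param t neighbourhood size (default 5).
#' @param seed integer seed.
#' @param apply_cannot whether cannot-links are applied (default FALSE).
#' @param scaling `"local"` per-point bandwidths (default) or `"global"`, one
#'   shared bandwidth (the mean local scale).
#' @return Integer vector of cluster labels in `1..k`.
#' @export
ssc <- function(x, k, constraints = NULL, t = 5L, seed = 1L,
                apply_cannot = FALSE, scaling = c("local", "global")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  sigma <- local_scale(x, t_sigma = t)
  if (scaling == "global") sigma <- mean(sigma)
  s <- pairwise_similarity(x, sigma)
  w <- knn_sparsify(s, t)
  w <- apply_constraints(w, constraints, apply_cannot = apply_cannot)
  spectral_cluster(k = k, seed = seed, w = w)
}
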