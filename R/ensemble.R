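#' Draw a random gene subspace
#'
#' The subspace size is q = q_min + floor(alpha (q_max - q_min)) with alpha
#' uniform on \[0, 1\] and q_min, q_max set to fractions of the gene count
#' (defaults 0.75 d and 0.85 d, floored). The q genes are then chosen uniformly
#' without replacement. Uses the current RNG state.
#'
#' @param d total number of genes.
#' @param bounds numeric pair of fractions `(lo, hi)` of `d` (default
#'   `c(0.75, 0.85)`).
#' @return A list with `gene_indices` (sorted), `q`, `q_min`, `q_max`, `alpha`.
#' @export
sample_subspace <- function(d, bounds = c(0.75, 0.85)) {
  d <- check_count(d, "d", min = 2L)
  if (length(bounds) != 2L || any(bounds <= 0) || any(bounds > 1) ||
      bounds[1L] > bounds[2L]) {
    abort("subspace bounds must satisfy 0 < lo <= hi <= 1")
  }
  q_min <- max(1L, as.integer(floor(bounds[1L] * d)))
  q_max <- max(q_min, as.integer(floor(bounds[2L] * d)))
  alpha <- stats::runif(1L)
  q <- q_min + as.integer(floor(alpha * (q_max - q_min)))
  list(gene_indices = sort(sample.int(d, q)),
       q = q, q_min = q_min, q_max = q_max, alpha = alpha)
}

#' Generate a base-clustering ensemble
#'
#' Two ensemble types: `"fixed_subspace"` runs the base algorithm with a fixed
#' cluster count k on m fresh random gene subspaces (the default, and the
#' configuration that performs best); `"random_fullspace"` runs it on all
#' genes with a per-member cluster count drawn uniformly from 2..ceiling(
#' sqrt(n)). The base algorithm is semi-supervised spectral clustering
#' (`base = "ssc"`, constraints injected into every member) or plain k-means on
#' the raw subspace values (`base = "kmeans"`, the configuration used by the
#' unsupervised link-based cluster ensemble). Member seeds are derived
#' deterministically from `seed`.
#'
#' @param x samples x genes numeric matrix.
#' @param k cluster count for fixed-subspace members.
#' @param m ensemble size (default 10).
#' @param constraints a [constraint_set()] or `NULL`.
#' @param type `"fixed_subspace"` or `"random_fullspace"`.
#' @param t neighbourhood size for spectral members (default 5).
#' @param base `"ssc"` or `"kmeans"`.
#' @param subspace_bounds fraction pair for [sample_subspace()].
#' @param seed integer seed.
#' @return An object of class `cluster_ensemble`: list with `solutions`
#'   (list of m integer label vectors over all n samples), `subspaces`
#'   (list of m subspace specs, `NULL` entries for full-space members),
#'   `k_list`, `n`, `type`, `base`.
#' @export
build_ensemble <- function(x, k, m = 10L, constraints = NULL,
                           type = c("fixed_subspace", "random_fullspace"),
                           t = 5L, base = c("ssc", "kmeans"),
                           subspace_bounds = c(0.75, 0.85), seed = 1L) {
  type <- match.arg(type)
  base <- match.arg(base)
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  m <- check_count(m, "m")
  k <- check_count(k, "k")
  if (type == "fixed_subspace" && k < 2L) abort("fixed-subspace ensembles need k >= 2")
  if (type == "random_fullspace" && n < 5L) {
    abort("random_fullspace needs n >= 5 (cluster-count range 2..ceiling(sqrt(n)) is degenerate)")
  }

  solutions <- vector("list", m)
  subspaces <- vector("list", m)
  k_list <- integer(m)
  for (i in seq_len(m)) {
    seed_i <- derive_seed(seed, i)
    if (type == "fixed_subspace") {
      sub <- withr::with_seed(seed_i, sample_subspace(d, subspace_bounds))
      xi <- x[, sub$gene_indices, drop = FALSE]
      ki <- k
      subspaces[[i]] <- sub
    } else {
      ki <- withr::with_seed(seed_i, sample.int(ceiling(sqrt(n)) - 1L, 1L) + 1L)
      xi <- x
    }
    solutions[[i]] <- if (base == "ssc") {
      ssc(xi, k = ki, constraints = constraints, t = t,
          seed = derive_seed(seed_i, 1L))
    } else {
      kmeans_assign(xi, k = ki, seed = derive_seed(seed_i, 1L))
    }
    k_list[i] <- ki
  }
  structure(list(solutions = solutions, subspaces = subspaces,
                 k_list = k_list, n = n, type = type, base = base),
            class = "cluster_ensemble")
}

#' @export
print.cluster_ensemble <- function(x, ...) {
  cat(sprintf("<cluster_ensemble> m = %d members (%s, base %s) over %d samples; k: %s\n",
              length(x$solutions), x$type, x$base, x$n,
              paste(x$k_list, collapse = ",")))
  invisible(x)
}
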