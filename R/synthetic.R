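#' Generate a labelled synthetic expression matrix
#'
#' Gaussian class-conditional model emulating pre-processed cancer microarray
#' matrices (tens to a few hundred samples, one to a few thousand genes, 2-14
#' classes). A fraction of genes is informative: on informative gene j with a
#' random sign s_j, class c has mean c * separation * s_j and unit-variance
#' Gaussian noise. The remaining genes carry zero-mean Gaussian noise with
#' standard deviation `noise_sd`. Gene columns are shuffled so informative
#' genes are not positionally identifiable; their identity is returned for
#' oracle checks. Deterministic given `seed`.
#'
#' The default shape (72 samples, 1877 genes, 3 classes) mirrors a typical
#' leukaemia benchmark matrix and exercises the n << d geometry the methods
#' are designed for.
#'
#' @param n number of samples.
#' @param d number of genes.
#' @param k number of classes.
#' @param informative_frac fraction of genes carrying class signal (default 0.2).
#' @param separation distance between consecutive class means on each
#'   informative gene, in expression units (default 1).
#' @param noise_sd standard deviation of non-informative genes (default 1).
#' @param class_props optional class proportions (length k, summing to 1);
#'   default equal sizes with the remainder assigned to the earliest classes.
#' @param seed integer seed.
#' @return A list with `expression` (n x d matrix, dimnames `s1..sn` /
#'   `g1..gd`), `labels` (character vector `c1..ck`), and `informative`
#'   (integer indices of the signal-carrying columns after shuffling).
#' @export
make_dataset <- function(n = 72L, d = 1877L, k = 3L, informative_frac = 0.2,
                         separation = 1, noise_sd = 1, class_props = NULL,
                         seed = 1L) {
  n <- check_count(n, "n", min = 1L)
  d <- check_count(d, "d", min = 2L)
  k <- check_count(k, "k", min = 1L)
  if (n < k) abort("n (%d) must be at least k (%d)", n, k)
  if (informative_frac <= 0 || informative_frac > 1) {
    abort("informative_frac must be in (0, 1]")
  }
  if (separation < 0) abort("separation must be non-negative")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (!is.null(class_props)) {
    if (length(class_props) != k || abs(sum(class_props) - 1) > 1e-8) {
      abort("class_props must have k entries summing to 1")
    }
  }

  sizes <- if (is.null(class_props)) {
    base <- rep(n %/% k, k)
    base + (seq_len(k) <= n %% k)
  } else {
    sz <- floor(class_props * n)
    rem <- n - sum(sz)
    sz + (seq_len(k) <= rem)
  }
  labels <- rep(paste0("c", seq_len(k)), sizes)

  d_inf <- max(1L, round(informative_frac * d))
  withr::with_seed(seed, {
    signs <- sample(c(-1, 1), d_inf, replace = TRUE)
    class_idx <- as.integer(factor(labels, levels = paste0("c", seq_len(k))))
    inf_means <- outer(class_idx, seq_len(d_inf),
                       function(c, j) c * separation * signs[j])
    inf_block <- inf_means + matrix(stats::rnorm(n * d_inf), n, d_inf)
    noise_block <- matrix(stats::rnorm(n * (d - d_inf), sd = noise_sd), n, d - d_inf)
    xmat <- cbind(inf_block, noise_block)
    perm <- sample.int(d)
    xmat <- xmat[, perm, drop = FALSE]
    informative <- which(perm %in% seq_len(d_inf))
  })
  dimnames(xmat) <- list(paste0("s", seq_len(n)), paste0("g", seq_len(d)))
  list(expression = xmat, labels = labels, informative = sort(informative))
}

#' Write a synthetic dataset as expression + label TSV files
#'
#' @param dataset a list from [make_dataset()].
#' @param prefix output path prefix; writes `<prefix>_expression.tsv`
#'   (genes-in-rows layout) and `<prefix>_labels.tsv`.
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, prefix) {
  expr_path <- paste0(prefix, "_expression.tsv")
  lab_path <- paste0(prefix, "_labels.tsv")
  write_expression(dataset$expression, expr_path, orientation = "genes_rows")
  utils::write.table(
    data.frame(sample_id = rownames(dataset$expression), label = dataset$labels),
    lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = expr_path, labels = lab_path))
}
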