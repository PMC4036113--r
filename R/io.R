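#' Read a gene-expression matrix from delimited text
#'
#' Loads a samples-by-genes numeric matrix from a TSV or CSV file with one
#' header row and one identifier column. Microarray matrices are conventionally
#' stored genes-in-rows; the `orientation` flag says how the file on disk is
#' laid out and the returned matrix is always oriented samples x genes.
#'
#' @param path path to a delimited text file (tab-separated by default; files
#'   ending in `.csv` are read comma-separated).
#' @param orientation `"genes_rows"` (default, microarray convention: rows are
#'   genes, columns are samples) or `"samples_rows"`.
#' @param sep field separator; `NULL` (default) picks `","` for `.csv` files
#'   and tab otherwise.
#' @return A numeric matrix with samples in rows and genes in columns;
#'   `rownames` are sample identifiers, `colnames` gene identifiers.
#' @export
read_expression <- function(path,
                            orientation = c("genes_rows", "samples_rows"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort("expression file not found: %s", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  if (ncol(tab) < 2L) abort("expression file needs an id column plus data columns: %s", path)

  row_ids <- tab[[1L]]
  col_ids <- colnames(tab)[-1L]
  if (anyDuplicated(row_ids)) {
    abort("duplicate row identifiers in %s: %s", path,
          paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  if (anyDuplicated(col_ids)) {
    abort("duplicate column identifiers in %s: %s", path,
          paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }

  raw <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    abort("non-numeric or missing value '%s' at row '%s', column '%s' in %s",
          raw[i, j], row_ids[i], col_ids[j], path)
  }
  dimnames(vals) <- list(row_ids, col_ids)

  x <- if (orientation == "genes_rows") t(vals) else vals
  if (nrow(x) < 2L || ncol(x) < 2L) {
    abort("expression matrix must have at least 2 samples and 2 genes (got %d x %d)",
          nrow(x), ncol(x))
  }
  x
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression()]: writes the matrix with an identifier column
#' and header row, in the requested on-disk orientation.
#'
#' @param x samples x genes numeric matrix with dimnames.
#' @param path output file path.
#' @param orientation on-disk layout, as in [read_expression()].
#' @param sep field separator (default tab).
#' @export
write_expression <- function(x, path, orientation = c("genes_rows", "samples_rows"),
                             sep = "\t") {
  orientation <- match.arg(orientation)
  m <- if (orientation == "genes_rows") t(x) else x
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- if (orientation == "genes_rows") "gene_id" else "sample_id"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a pairwise-constraint set
#'
#' Pairwise prior knowledge: must-links assert two samples belong to the same
#' cluster, cannot-links that they belong to different clusters. Pairs are
#' stored with the smaller index first and de-duplicated.
#'
#' @param must two-column integer matrix of sample-index pairs (may have 0 rows).
#' @param cannot two-column integer matrix of sample-index pairs.
#' @param n number of samples the indices refer to.
#' @return An object of class `constraint_set` with elements `must`, `cannot`
#'   (two-column integer matrices) and `n`.
#' @export
constraint_set <- function(must = matrix(integer(), 0L, 2L),
                           cannot = matrix(integer(), 0L, 2L),
                           n) {
  n <- check_count(n, "n", min = 2L)
  norm_pairs <- function(p, what) {
    p <- matrix(as.integer(p), ncol = 2L)
    if (nrow(p) == 0L) return(p)
    if (any(p < 1L | p > n)) abort("%s pair index out of range 1..%d", what, n)
    if (any(p[, 1L] == p[, 2L])) abort("self-pair not allowed in %s constraints", what)
    p <- cbind(pmin(p[, 1L], p[, 2L]), pmax(p[, 1L], p[, 2L]))
    unique(p)
  }
  must <- norm_pairs(must, "must-link")
  cannot <- norm_pairs(cannot, "cannot-link")
  if (nrow(must) > 0L && nrow(cannot) > 0L) {
    key <- function(p) paste(p[, 1L], p[, 2L])
    clash <- intersect(key(must), key(cannot))
    if (length(clash) > 0L) {
      abort("pair(s) listed as both must-link and cannot-link: %s",
            paste(clash, collapse = "; "))
    }
  }
  structure(list(must = must, cannot = cannot, n = n), class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("<constraint_set> %d must-link(s), %d cannot-link(s) over %d samples\n",
              nrow(x$must), nrow(x$cannot), x$n))
  invisible(x)
}

#' Number of constraints in a set
#' @param x a `constraint_set`.
#' @return Integer count of must-links plus cannot-links.
#' @export
n_constraints <- function(x) nrow(x$must) + nrow(x$cannot)

#' Read pairwise constraints from delimited text
#'
#' Each row is `sample_a<TAB>sample_b<TAB>relation` with relation `must` or
#' `cannot`. A header row is detected and skipped. Identifiers are mapped to
#' indices in `sample_ids`; duplicate pairs are collapsed and pair order is
#' normalized.
#'
#' @param path path to the constraint file.
#' @param sample_ids character vector of sample identifiers giving the index
#'   mapping (typically `rownames` of the expression matrix).
#' @param sep field separator (default tab).
#' @return A [constraint_set()].
#' @export
read_constraints <- function(path, sample_ids, sep = "\t") {
  if (!file.exists(path)) abort("constraint file not found: %s", path)
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           col.names = c("a", "b", "relation"))
  looks_like_header <- nrow(tab) > 0L &&
    !tolower(tab$relation[1L]) %in% c("must", "cannot") &&
    !tab$a[1L] %in% sample_ids && !tab$b[1L] %in% sample_ids
  if (looks_like_header) tab <- tab[-1L, , drop = FALSE]
  rel <- tolower(tab$relation)
  if (!all(rel %in% c("must", "cannot"))) {
    abort("constraint relation must be 'must' or 'cannot' (got '%s')",
          rel[!rel %in% c("must", "cannot")][1L])
  }
  ia <- match(tab$a, sample_ids)
  ib <- match(tab$b, sample_ids)
  unk <- c(tab$a[is.na(ia)], tab$b[is.na(ib)])
  if (length(unk) > 0L) {
    abort("unknown sample id(s) in constraint file: %s",
          paste(unique(unk), collapse = ", "))
  }
  constraint_set(must = cbind(ia, ib)[rel == "must", , drop = FALSE],
                 cannot = cbind(ia, ib)[rel == "cannot", , drop = FALSE],
                 n = length(sample_ids))
}

#' Write a cluster assignment to a two-column TSV
#'
#' @param assignment integer vector of cluster labels (1-based), length n.
#' @param sample_ids character vector of sample identifiers, length n.
#' @param path output file path.
#' @export
write_assignment <- function(assignment, sample_ids, path) {
  if (length(assignment) == 0L) abort("empty cluster assignment")
  if (length(assignment) != length(sample_ids)) {
    abort("assignment length (%d) does not match number of sample ids (%d)",
          length(assignment), length(sample_ids))
  }
  df <- data.frame(sample_id = sample_ids, cluster = as.integer(assignment))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cluster assignment written by [write_assignment()]
#' @param path path to the two-column TSV.
#' @return Named integer vector of cluster labels.
#' @export
read_assignment <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$cluster), df$sample_id)
}

#' Read sample class labels from delimited text
#'
#' Accepts either a one-column file of labels (in expression-matrix sample
#' order) or a two-column file `sample_id<TAB>label`, with a header row.
#'
#' @param path path to the label file.
#' @param sample_ids optional sample identifiers; if supplied and the file has
#'   two columns, labels are reordered to match.
#' @return Character vector of class labels.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) == 1L) return(as.character(df[[1L]]))
  ids <- as.character(df[[1L]])
  labs <- as.character(df[[2L]])
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, ids)
    if (anyNA(idx)) {
      abort("label file missing sample id(s): %s",
            paste(sample_ids[is.na(idx)], collapse = ", "))
    }
    labs <- labs[idx]
  }
  labs
}
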