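#' Contingency table of two partitions
#'
#' @param a,b cluster/class label vectors of equal length (any atomic type).
#' @return Integer matrix of joint counts, rows indexed by the distinct values
#'   of `a`, columns by those of `b`.
#' @export
contingency <- function(a, b) {
  if (length(a) != length(b)) {
    abort("partitions have different lengths (%d vs %d)", length(a), length(b))
  }
  unclass(table(a = a, b = b))
}

#' Normalized mutual information between two partitions
#'
#' I(X, Y) / sqrt(H(X) H(Y)) computed from the contingency table, with the
#' convention 0 log 0 = 0. The ratio is invariant to the logarithm base. If
#' either partition has zero entropy (a single cluster), the score is 1 when
#' the two partitions are identical as set partitions and 0 otherwise.
#'
#' @param a,b label vectors of equal length.
#' @return A value in \[0, 1\]; 1 iff the partitions are identical up to
#'   relabelling.
#' @export
nmi <- function(a, b) {
  ct <- contingency(a, b)
  n <- sum(ct)
  p <- ct / n
  pr <- rowSums(p); pc <- colSums(p)
  hx <- -sum(pr[pr > 0] * log(pr[pr > 0]))
  hy <- -sum(pc[pc > 0] * log(pc[pc > 0]))
  if (hx == 0 || hy == 0) {
    return(if (same_partition(ct)) 1 else 0)
  }
  nz <- which(p > 0, arr.ind = TRUE)
  i_xy <- sum(p[nz] * log(p[nz] / (pr[nz[, 1L]] * pc[nz[, 2L]])))
  max(0, min(1, i_xy / sqrt(hx * hy)))
}

# identical as set partitions: contingency is a (possibly rectangular-trimmed)
# permutation-like table with exactly one nonzero per row and per column
same_partition <- function(ct) {
  nrow(ct) == ncol(ct) &&
    all(rowSums(ct > 0) == 1L) && all(colSums(ct > 0) == 1L)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie form: (Index - Expected) / (Max - Expected), where Index is
#' the number of co-clustered pairs counted through the contingency table and
#' Expected is its value under random labelling with fixed marginals. Equals 1
#' for identical partitions and has expectation 0 under chance. In the
#' degenerate case Max = Expected (e.g. both partitions are all singletons or
#' one cluster) it returns 1 if the partitions are identical, 0 otherwise.
#'
#' @param a,b label vectors of equal length, n >= 2.
#' @return A value in (-1, 1\].
#' @export
ari <- function(a, b) {
  ct <- contingency(a, b)
  n <- sum(ct)
  if (n < 2L) abort("adjusted Rand index needs n >= 2")
  idx <- sum(choose(ct, 2))
  ra <- sum(choose(rowSums(ct), 2))
  cb <- sum(choose(colSums(ct), 2))
  expected <- ra * cb / choose(n, 2)
  mx <- (ra + cb) / 2
  if (abs(mx - expected) < .Machine$double.eps * max(1, mx)) {
    return(if (same_partition(ct)) 1 else 0)
  }
  (idx - expected) / (mx - expected)
}

#' Constraint count as a percentage of all sample pairs
#'
#' Reports l constraints over n samples as 100 * l / (n^2 / 2), truncated (not
#' rounded) to two decimal places — the accounting convention used when
#' quoting "constraints % in total" for a dataset.
#'
#' @param n number of samples (>= 2).
#' @param l number of pairwise constraints (>= 0).
#' @return The truncated percentage.
#' @export
constraint_fraction <- function(n, l) {
  n <- check_count(n, "n", min = 2L)
  if (!is_count(l) || l < 0) abort("`l` must be a single non-negative integer")
  pct <- 100 * l / (n^2 / 2)
  floor(pct * 100 + 1e-9) / 100
}

# stratified fold assignment: shuffle within class, deal round-robin with a
# rotating start so fold sizes stay balanced across classes
stratified_folds <- function(labels, h, seed) {
  n <- length(labels)
  folds <- integer(n)
  withr::with_seed(seed, {
    start <- 0L
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < h) {
        warning(sprintf("class '%s' has %d < %d members; stratification relaxed",
                        cls, length(idx), h), call. = FALSE)
      }
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((start + seq_along(idx) - 1L) %% h) + 1L
      start <- start + length(idx)
    }
  })
  folds
}

#' Constraint-aware h-fold cross-validation of clustering algorithms
#'
#' Evaluates how pairwise prior knowledge affects clustering quality. Per run,
#' samples are shuffled into h class-stratified folds. Per fold, `l`
#' must-links are drawn only from within-class pairs among the h-1 training
#' folds, the algorithm clusters ALL n samples (clustering is transductive),
#' and NMI/ARI are computed on the held-out test-fold samples alone — samples
#' whose labels contributed no prior knowledge. All algorithms within a run
#' share the same fold split and constraint draw, so comparisons are paired.
#'
#' @param x samples x genes numeric matrix.
#' @param labels true class labels, length n.
#' @param k number of clusters (typically the number of classes).
#' @param algorithms character vector of algorithm names accepted by
#'   [cluster_expression()].
#' @param l must-links drawn per fold (constraints are ignored by the
#'   unsupervised algorithms).
#' @param h number of folds (default 5).
#' @param runs number of repetitions with reshuffled folds (default 50).
#' @param m,t,type,decay passed to [cluster_expression()].
#' @param seed integer master seed.
#' @param keep_constraints if `TRUE`, the per-run, per-fold constraint sets
#'   are returned in the report (for auditing that no test-fold sample ever
#'   contributes prior knowledge).
#' @return An object of class `cv_report`: list with `records` (data.frame:
#'   run, fold, algorithm, n_constraints, nmi, ari) and `summary`
#'   (per-algorithm mean and normal-approximation 95% confidence interval of
#'   each metric across run means).
#' @export
cross_validate <- function(x, labels, k, algorithms = "sscc", l = 0L,
                           h = 5L, runs = 50L, m = 10L, t = 5L,
                           type = "fixed_subspace", decay = 0.9, seed = 1L,
                           keep_constraints = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(labels) != n) abort("labels length (%d) != samples (%d)", length(labels), n)
  h <- check_count(h, "h", min = 2L)
  runs <- check_count(runs, "runs")

  recs <- vector("list", runs * h * length(algorithms))
  kept <- if (keep_constraints) vector("list", runs * h) else NULL
  ri <- 0L
  for (run in seq_len(runs)) {
    seed_run <- derive_seed(seed, run)
    folds <- stratified_folds(labels, h, seed = seed_run)
    for (fold in seq_len(h)) {
      test <- which(folds == fold)
      train <- which(folds != fold)
      cs <- generate_must_links(labels, eligible = train, l = l,
                                seed = derive_seed(seed_run, fold))
      if (keep_constraints) {
        kept[[(run - 1L) * h + fold]] <-
          list(run = run, fold = fold, test = test, constraints = cs)
      }
      # one seed per (run, fold), shared by all algorithms: comparisons are
      # paired, and an algorithm that ignores its constraints is run-for-run
      # identical to its unconstrained counterpart
      seed_rf <- derive_seed(seed_run, fold, 977L)
      for (alg in algorithms) {
        sol <- cluster_expression(x, algorithm = alg, k = k, constraints = cs,
                                  m = m, t = t, type = type, decay = decay,
                                  seed = seed_rf)
        ri <- ri + 1L
        recs[[ri]] <- data.frame(run = run, fold = fold, algorithm = alg,
                                 n_constraints = l,
                                 nmi = nmi(sol[test], labels[test]),
                                 ari = ari(sol[test], labels[test]))
      }
    }
  }
  records <- do.call(rbind, recs)
  structure(list(records = records, summary = summarize_cv(records),
                 constraint_log = kept),
            class = "cv_report")
}

# per-algorithm mean and 95% CI across run means
summarize_cv <- function(records) {
  out <- lapply(split(records, records$algorithm), function(df) {
    run_nmi <- tapply(df$nmi, df$run, mean)
    run_ari <- tapply(df$ari, df$run, mean)
    ci <- function(v) {
      se <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
      c(mean = mean(v), lo = mean(v) - 1.96 * se, hi = mean(v) + 1.96 * se)
    }
    cn <- ci(run_nmi); ca <- ci(run_ari)
    data.frame(algorithm = df$algorithm[1L], n_constraints = df$n_constraints[1L],
               runs = length(run_nmi),
               nmi_mean = cn["mean"], nmi_lo = cn["lo"], nmi_hi = cn["hi"],
               ari_mean = ca["mean"], ari_lo = ca["lo"], ari_hi = ca["hi"],
               row.names = NULL)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a cross-validation report to disk
#'
#' Per-record rows as TSV; the per-algorithm summary as JSON.
#'
#' @param report a `cv_report` from [cross_validate()].
#' @param tsv_path path for the per-record TSV (skipped if `NULL`).
#' @param json_path path for the summary JSON (skipped if `NULL`).
#' @export
write_cv_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report$records, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report$summary, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(report)
}
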