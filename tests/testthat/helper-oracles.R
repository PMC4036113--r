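# Independent oracles used to cross-check the package implementations.
# Deliberately written with different code paths (bits instead of nats,
# explicit loops instead of matrix algebra).

# canonical relabelling by first occurrence; equality up to label permutation
canon_labels <- function(l) as.integer(factor(l, levels = unique(l)))
partitions_equal <- function(a, b) identical(canon_labels(a), canon_labels(b))

# NMI by direct definition, in bits
oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (i in ua) for (j in ub) {
    pij <- sum(a == i & b == j) / n
    if (pij > 0) {
      mi <- mi + pij * log2(pij / ((sum(a == i) / n) * (sum(b == j) / n)))
    }
  }
  h <- function(v) {
    p <- as.numeric(table(v)) / n
    -sum(p * log2(p))
  }
  ha <- h(a); hb <- h(b)
  if (ha == 0 || hb == 0) return(if (partitions_equal(a, b)) 1 else 0)
  max(0, min(1, mi / sqrt(ha * hb)))   # NMI is defined on [0, 1]
}

# pairwise-counting ARI (loop over all sample pairs), independent of the
# contingency-table shortcut
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  tot <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / tot
  mx <- ((n11 + n10) + (n11 + n01)) / 2
  if (abs(mx - expected) < 1e-12) return(if (partitions_equal(a, b)) 1 else 0)
  (n11 - expected) / (mx - expected)
}

# brute-force weighted-connected-triple similarity over explicit member sets
brute_wct <- function(bm, decay) {
  g <- ncol(bm)
  sets <- lapply(seq_len(g), function(j) which(bm[, j] == 1))
  jac <- function(a, b) {
    u <- length(union(sets[[a]], sets[[b]]))
    if (u == 0) 0 else length(intersect(sets[[a]], sets[[b]])) / u
  }
  w <- matrix(0, g, g)
  for (a in seq_len(g)) for (b in seq_len(g)) if (a != b) w[a, b] <- jac(a, b)
  wct <- matrix(0, g, g)
  for (a in seq_len(g)) for (b in seq_len(g)) if (a != b) {
    s <- 0
    for (cc in seq_len(g)) if (cc != a && cc != b) s <- s + min(w[a, cc], w[cc, b])
    wct[a, b] <- s
  }
  mx <- max(wct)
  sim <- if (mx > 0) wct / mx * decay else matrix(0, g, g)
  diag(sim) <- 1
  list(weights = w, wct = wct, sim = sim)
}

# random ensemble of m labelings for WCT / consensus oracles
random_ensemble <- function(n, m, kmax, seed) {
  withr::with_seed(seed, {
    k_list <- sample(2:kmax, m, replace = TRUE)
    sols <- lapply(k_list, function(k) sample.int(k, n, replace = TRUE))
  })
  structure(list(solutions = sols, subspaces = vector("list", m),
                 k_list = k_list, n = n, type = "fixed_subspace",
                 base = "ssc"),
            class = "cluster_ensemble")
}

unanimous_ensemble <- function(assignment, m, k) {
  structure(list(solutions = rep(list(as.integer(assignment)), m),
                 subspaces = vector("list", m),
                 k_list = rep(as.integer(k), m),
                 n = length(assignment), type = "fixed_subspace",
                 base = "ssc"),
            class = "cluster_ensemble")
}

# ---- normalized-cut oracle ----

ncut_value <- function(w, in_a) {
  a <- which(in_a); b <- which(!in_a)
  cut <- sum(w[a, b, drop = FALSE])
  vol_a <- sum(w[a, , drop = FALSE]); vol_b <- sum(w[b, , drop = FALSE])
  if (vol_a == 0 || vol_b == 0) return(Inf)
  cut / vol_a + cut / vol_b
}

# exhaustive minimum over all 2-partitions (vertex 1 pinned to side A)
min_ncut <- function(w) {
  n <- nrow(w)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    side <- c(TRUE, bitwAnd(code, 2^(0:(n - 2))) > 0)
    v <- ncut_value(w, side)
    if (v < best) best <- v
  }
  best
}

graph_connected <- function(w) {
  n <- nrow(w)
  seen <- 1L; frontier <- 1L
  while (length(frontier) > 0) {
    nb <- which(colSums(w[frontier, , drop = FALSE] > 0) > 0)
    frontier <- setdiff(nb, seen)
    seen <- union(seen, frontier)
  }
  length(seen) == n
}

random_connected_graph <- function(n) {
  repeat {
    w <- matrix(0, n, n)
    up <- upper.tri(w)
    vals <- stats::runif(sum(up))
    vals[stats::runif(sum(up)) < 0.4] <- 0
    w[up] <- vals
    w <- w + t(w)
    if (graph_connected(w)) return(w)
  }
}

# exhaustive minimum within-cluster sum of squares over all 2-partitions
best_wcss_2part <- function(x) {
  n <- nrow(x)
  best <- NULL; best_val <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    side <- c(TRUE, bitwAnd(code, 2^(0:(n - 2))) > 0)
    val <- 0
    for (s in list(which(side), which(!side))) {
      cx <- x[s, , drop = FALSE]
      val <- val + sum(sweep(cx, 2, colMeans(cx))^2)
    }
    if (val < best_val) { best_val <- val; best <- side }
  }
  ifelse(best, 1L, 2L)
}
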