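# the worked 4-sample, 2-member example: member 1 has clusters A = {1,2},
# B = {3,4}; member 2 has C = {1,2,3}, D = {4}
worked_ensemble <- function() {
  structure(list(solutions = list(c(1L, 1L, 2L, 2L), c(1L, 1L, 1L, 2L)),
                 subspaces = list(NULL, NULL), k_list = c(2L, 2L), n = 4L,
                 type = "fixed_subspace", base = "ssc"),
            class = "cluster_ensemble")
}

test_that("basic association matrix encodes crisp memberships", {
  bm <- build_bm(worked_ensemble())
  expect_equal(dim(bm), c(4L, 4L))
  expect_equal(bm[1, ], c(1, 0, 1, 0), ignore_attr = TRUE)
  expect_equal(unname(rowSums(bm)), rep(2, 4))  # one cluster per member

  # m = 1: one-hot encoding
  e1 <- unanimous_ensemble(c(1L, 2L, 2L, 3L), m = 1, k = 3)
  bm1 <- build_bm(e1)
  expect_equal(unname(bm1),
               matrix(c(1, 0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE),
               ignore_attr = TRUE)

  bad <- worked_ensemble(); bad$solutions[[2]] <- c(1L, 2L)
  expect_error(build_bm(bad), "inconsistent")
})

test_that("connected-triple similarity reproduces the worked example", {
  bm <- build_bm(worked_ensemble())
  g <- cluster_similarity_wct(bm, decay = 0.9)
  # Jaccard weights
  expect_equal(g$weights[1, 3], 2 / 3)   # A-C
  expect_equal(g$weights[2, 4], 1 / 2)   # B-D
  expect_equal(g$weights[2, 3], 1 / 4)   # B-C
  expect_equal(g$weights[1, 4], 0)       # A-D
  # WCT and decay-scaled similarity
  expect_equal(g$wct[1, 2], 1 / 4)
  expect_equal(g$wct[3, 4], 1 / 4)
  expect_equal(g$sim[1, 2], 0.9)
  expect_equal(g$sim[3, 4], 0.9)
  expect_equal(diag(g$sim), rep(1, 4), ignore_attr = TRUE)

  expect_error(cluster_similarity_wct(bm, decay = 1.5), "decay")
})

test_that("connected-triple similarity matches brute-force enumeration", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(4:12, 1); m <- sample(2:4, 1); kmax <- 3
    })
    ens <- random_ensemble(n, m, kmax, seed = seed + 100)
    bm <- build_bm(ens)
    got <- cluster_similarity_wct(bm, decay = 0.9)
    want <- brute_wct(bm, decay = 0.9)
    expect_equal(unname(got$weights), want$weights, tolerance = 1e-12)
    expect_equal(unname(got$wct), want$wct, tolerance = 1e-12)
    expect_equal(unname(got$sim), want$sim, tolerance = 1e-12)
  }
})

test_that("refined association fills zeros with cluster-graph similarity", {
  bm <- build_bm(worked_ensemble())
  g <- cluster_similarity_wct(bm, decay = 0.9)
  rm_ <- refine_bm(bm, g)
  # sample 4 belongs to D in member 2; its association with C is sim(C, D)
  expect_equal(unname(rm_[4, 3]), 0.9)
  # ones of BM are preserved; RM dominates BM; entries bounded
  expect_true(all(rm_[bm == 1] == 1))
  expect_true(all(rm_ >= bm))
  expect_true(all(rm_ >= 0 & rm_ <= 1))

  # decay 0 collapses the refinement: RM = BM
  g0 <- cluster_similarity_wct(bm, decay = 0)
  expect_equal(unname(refine_bm(bm, g0)), unname(bm * 1))

  # unanimous ensembles have no connected triples: zeros stay zero
  ens_u <- unanimous_ensemble(rep(1:3, each = 4), m = 5, k = 3)
  bm_u <- build_bm(ens_u)
  rm_u <- refine_bm(bm_u, cluster_similarity_wct(bm_u, decay = 0.9))
  expect_equal(unname(rm_u), unname(bm_u * 1))

  expect_error(refine_bm(bm[, 1:3], g), "clusters")
})

test_that("bipartite consensus returns the unanimous partition", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- sample(6:40, 1); k <- sample(2:4, 1); m <- sample(2:10, 1)
      part <- sample.int(k, n, replace = TRUE)
      while (length(unique(part)) < k) part <- sample.int(k, n, replace = TRUE)
    })
    ens <- unanimous_ensemble(part, m = m, k = k)
    bm <- build_bm(ens)
    rm_ <- refine_bm(bm, cluster_similarity_wct(bm, decay = 0.9))
    got <- hbgf_partition(rm_, k, seed = seed)
    expect_true(partitions_equal(got, part))
  }
})

test_that("bipartite consensus respects agreed pairs of orthogonal members", {
  # two orthogonal 2-partitions of 4 samples: the consensus must return one of
  # them, never split a pair both members agree on... here no pair is agreed
  # by both, so the answer must simply equal one input partition
  ens <- structure(list(solutions = list(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L)),
                        subspaces = list(NULL, NULL), k_list = c(2L, 2L),
                        n = 4L, type = "fixed_subspace", base = "ssc"),
                   class = "cluster_ensemble")
  bm <- build_bm(ens)
  rm_ <- refine_bm(bm, cluster_similarity_wct(bm, decay = 0.9))
  got <- hbgf_partition(rm_, 2, seed = 4)
  expect_true(partitions_equal(got, c(1, 1, 2, 2)) ||
              partitions_equal(got, c(1, 2, 1, 2)))

  expect_equal(hbgf_partition(rm_, 1, seed = 1), rep(1L, 4))
  expect_error(hbgf_partition(matrix(0, 4, 4), 2, seed = 1), "degenerate")
  expect_error(hbgf_partition(rm_, 5, seed = 1), "exceed")
})

test_that("the full consensus pipeline recovers separable structure", {
  ds <- make_dataset(n = 60, d = 200, k = 3, informative_frac = 0.2,
                     separation = 6, noise_sd = 1, seed = 3)
  sol <- run_sscc(ds$expression, k = 3, m = 5, seed = 11)
  expect_equal(nmi(sol, ds$labels), 1)

  # determinism
  expect_identical(run_sscc(ds$expression, k = 3, m = 5, seed = 11), sol)

  # permutation invariance up to relabelling on separable data
  perm <- withr::with_seed(2, sample.int(60))
  sol_p <- run_sscc(ds$expression[perm, ], k = 3, m = 5, seed = 11)
  expect_equal(nmi(sol_p, sol[perm]), 1)

  # row-similarity final clustering variant agrees here
  sol_r <- run_sscc(ds$expression, k = 3, m = 5, seed = 11, final = "rowsim")
  expect_equal(nmi(sol_r, ds$labels), 1)

  # lce mode (k-means base, no constraints) also solves the easy case
  sol_l <- cluster_expression(ds$expression, "lce", k = 3, m = 5, seed = 13)
  expect_equal(nmi(sol_l, ds$labels), 1)
})
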