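test_that("contingency tables count joint memberships", {
  expect_equal(unname(contingency(c(1, 1, 2, 2), c(1, 1, 2, 2))),
               matrix(c(2L, 0L, 0L, 2L), 2))
  expect_equal(unname(contingency(c(1, 1, 2, 2), c(1, 2, 1, 2))),
               matrix(1L, 2, 2))
  ct <- contingency(c("x", "x", "y"), c(1, 2, 2))
  expect_equal(unname(rowSums(ct)), c(2L, 1L))
  expect_equal(unname(colSums(ct)), c(1L, 2L))
  expect_error(contingency(1:3, 1:4), "length")
})

test_that("NMI matches hand-computed and degenerate cases", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)      # relabelling
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)      # independent
  # I = 1 bit, H = 1 and 1.5 bits -> 1/sqrt(1.5)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 3)), 1 / sqrt(1.5))
  # zero-entropy conventions
  expect_equal(nmi(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(nmi(c(1, 1, 1), c(1, 1, 2)), 0)
})

test_that("ARI matches hand-computed and degenerate cases", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # index 1, expected 1/3, max 1.5 -> 4/7
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 3)), 4 / 7)
  # degenerate: single cluster vs single cluster / vs split
  expect_equal(ari(c(1, 1, 1), c(2, 2, 2)), 1)
  expect_equal(ari(c(1, 1, 1), c(1, 1, 2)), 0)
  expect_equal(ari(1:4, 1:4), 1)  # all singletons, identical
})

test_that("metrics agree with independent oracles on random partitions", {
  for (seed in 1:60) {
    withr::with_seed(seed, {
      n <- sample(5:50, 1)
      a <- sample.int(sample(2:6, 1), n, replace = TRUE)
      b <- sample.int(sample(2:6, 1), n, replace = TRUE)
    })
    expect_lt(abs(nmi(a, b) - oracle_nmi(a, b)), 1e-12)
    expect_lt(abs(ari(a, b) - oracle_ari_pairs(a, b)), 1e-12)
    # symmetry and permutation invariance
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
    expect_equal(ari(a, b), ari(b, a), tolerance = 1e-12)
  }
  # cross-check ARI against the reference implementation in mclust
  skip_if_not_installed("mclust")
  for (seed in 1:20) {
    withr::with_seed(seed, {
      a <- sample.int(4, 30, replace = TRUE)
      b <- sample.int(3, 30, replace = TRUE)
    })
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("ARI is centred at zero under random labelling", {
  withr::with_seed(99, {
    vals <- replicate(200, {
      a <- sample.int(3, 40, replace = TRUE)
      ari(a, sample(a))
    })
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("constraint percentages follow the n^2/2 truncation convention", {
  expect_equal(constraint_fraction(72, 20), 0.77)
  expect_equal(constraint_fraction(174, 100), 0.66)
  expect_equal(constraint_fraction(248, 100), 0.32)
  expect_equal(constraint_fraction(190, 100), 0.55)
  expect_equal(constraint_fraction(203, 100), 0.48)
  expect_equal(constraint_fraction(100, 0), 0)
  # truncation, not rounding: 2000/882 = 2.2675.. -> 2.26
  expect_equal(constraint_fraction(42, 20), 2.26)
  expect_error(constraint_fraction(1, 5), ">= 2")
})

test_that("stratified folds balance classes and cover all samples", {
  labs <- rep(c("A", "B", "C"), times = c(20, 15, 10))
  folds <- sscc:::stratified_folds(labs, 5, seed = 3)
  expect_setequal(unique(folds), 1:5)
  for (cls in unique(labs)) {
    sizes <- tabulate(folds[labs == cls], 5)
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  expect_warning(sscc:::stratified_folds(c("A", "A", "B"), 2, seed = 1),
                 "stratification relaxed")
})

test_that("cross-validation is constraint-aware and properly paired", {
  ds <- make_dataset(n = 40, d = 60, k = 2, informative_frac = 0.3,
                     separation = 1, noise_sd = 1, seed = 44)
  rep_ <- cross_validate(ds$expression, ds$labels, k = 2,
                         algorithms = c("ssc", "sc"), l = 0, h = 4, runs = 3,
                         seed = 5, keep_constraints = TRUE)
  # shape: runs x folds records per algorithm
  expect_equal(nrow(rep_$records), 3L * 4L * 2L)
  expect_equal(sum(rep_$records$algorithm == "ssc"), 12L)

  # with l = 0, ssc and sc are run-for-run identical
  r_ssc <- rep_$records[rep_$records$algorithm == "ssc", c("nmi", "ari")]
  r_sc <- rep_$records[rep_$records$algorithm == "sc", c("nmi", "ari")]
  expect_equal(unname(as.matrix(r_ssc)), unname(as.matrix(r_sc)))

  # constraints never touch a test-fold sample
  rep2 <- cross_validate(ds$expression, ds$labels, k = 2, algorithms = "ssc",
                         l = 20, h = 4, runs = 2, seed = 6,
                         keep_constraints = TRUE)
  for (entry in rep2$constraint_log) {
    expect_equal(n_constraints(entry$constraints), 20L)
    expect_length(intersect(as.vector(entry$constraints$must), entry$test), 0L)
  }

  # summary holds one row per algorithm with means inside the CI bounds
  expect_equal(sort(rep_$summary$algorithm), c("sc", "ssc"))
  expect_true(all(rep_$summary$nmi_lo <= rep_$summary$nmi_mean &
                  rep_$summary$nmi_mean <= rep_$summary$nmi_hi))
})

test_that("cross-validation attains perfect scores on separable data", {
  ds <- make_dataset(n = 30, d = 100, k = 2, informative_frac = 0.3,
                     separation = 6, noise_sd = 1, seed = 15)
  rep_ <- cross_validate(ds$expression, ds$labels, k = 2, algorithms = "ssc",
                         l = 10, h = 3, runs = 2, seed = 7)
  expect_true(all(rep_$records$nmi == 1))
  expect_true(all(rep_$records$ari == 1))
})

test_that("cv reports round-trip through TSV and JSON", {
  ds <- make_dataset(n = 24, d = 30, k = 2, informative_frac = 0.5,
                     separation = 4, noise_sd = 1, seed = 2)
  rep_ <- cross_validate(ds$expression, ds$labels, k = 2, algorithms = "kmeans",
                         l = 0, h = 3, runs = 2, seed = 8)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep_, tsv, js)
  back <- utils::read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(nrow(back), nrow(rep_$records))
  expect_equal(back$nmi, rep_$records$nmi)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$nmi_mean, rep_$summary$nmi_mean, tolerance = 1e-12)
})
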