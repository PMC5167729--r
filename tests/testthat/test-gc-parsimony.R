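test_that("rescaling maps the observed range onto [0, 65]", {
  v <- leaf_values(c("A", "B", "C"), c(40, 50, 60))
  r <- rescale_values(v)
  expect_equal(r$lo, c(0, 32.5, 65))
  already <- leaf_values(c("A", "B"), c(0, 65))
  expect_equal(rescale_values(already)$lo, c(0, 65))
  expect_error(rescale_values(leaf_values(c("A", "B"), c(40, 40))),
               "zero range")
  # a shared source range keeps two sets comparable
  w <- leaf_values(c("A", "B"), c(45, 55))
  rw <- rescale_values(w, from = c(40, 60))
  expect_equal(rw$lo, c(16.25, 48.75))
})

test_that("Farris scores match simple hand cases", {
  tr <- read_support_tree("((A,B),(C,D));")
  expect_equal(farris_score(tr, leaf_values(LETTERS[1:4],
                                            c(5, 5, 5, 5))), 0)
  expect_equal(farris_score(tr, leaf_values(LETTERS[1:4],
                                            c(0, 0, 10, 10))), 10)
  expect_equal(farris_score(read_support_tree("(A,B);"),
                            leaf_values(c("A", "B"), c(3, 7))), 4)
  expect_error(farris_score(read_support_tree("(A,B,C,D);"),
                            leaf_values(LETTERS[1:4], 1:4)),
               "non-binary")
  expect_error(farris_score(tr, leaf_values("A", 1)), "2 active tips")
})

test_that("Farris scores equal grid dynamic programming on random trees",
{
  mismatches <- 0
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    v <- leaf_values(tr$tip.label, sample(0:20, n, replace = TRUE))
    got <- farris_score(tr, v)
    want <- oracle_farris_grid(tr, v)
    if (!isTRUE(all.equal(got, want))) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("the grid oracle itself agrees with full enumeration when
           feasible", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- ape::rtree(4)
    v <- leaf_values(tr$tip.label, sample(0:10, 4, replace = TRUE))
    expect_equal(oracle_farris_grid(tr, v, grid = 0:10),
                 oracle_farris_enum(tr, v, grid = 0:10))
  }
})

test_that("Farris scores are rooting-invariant, translate and scale", {
  for (seed in 1:10) {
    set.seed(seed)
    tr <- ape::rtree(7)
    v <- leaf_values(tr$tip.label, stats::runif(7, 30, 70))
    s <- farris_score(tr, v)
    rerooted <- ape::root(ape::unroot(tr),
                          outgroup = sample(tr$tip.label, 1),
                          resolve.root = TRUE)
    expect_equal(farris_score(rerooted, v), s)
    shifted <- leaf_values(v$tip, v$lo + 13.7)
    expect_equal(farris_score(tr, shifted), s)
    scaled <- leaf_values(v$tip, v$lo * 2.5)
    expect_equal(farris_score(tr, scaled), 2.5 * s)
  }
})

test_that("interval leaves never score above any point selection", {
  for (seed in 1:10) {
    set.seed(seed)
    tr <- ape::rtree(6)
    lo <- stats::runif(6, 30, 60)
    hi <- lo + stats::runif(6, 0, 5)
    intervals <- leaf_values(tr$tip.label, lo, hi)
    si <- farris_score(tr, intervals)
    for (k in 1:5) {
      pick <- lo + stats::runif(6) * (hi - lo)
      expect_lte(si, farris_score(tr, leaf_values(tr$tip.label, pick)) +
                   1e-9)
    }
  }
})

test_that("deactivated tips are pruned before scoring", {
  tr <- read_support_tree("(((A,B),C),(D,E));")
  v <- leaf_values(c("A", "B", "D", "E"), c(0, 0, 10, 10))
  expect_equal(farris_score(tr, v), 10)  # C deactivated, tree re-binarized
})

test_that("identical value sets give zero differences and NA tests", {
  trees <- lapply(1:3, function(s) ape::rtree(6, tip.label = paste0("t", 1:6)))
  v <- leaf_values(paste0("t", 1:6), c(30, 35, 40, 45, 50, 55))
  fc <- compare_fit(trees, v, v)
  expect_true(all(fc$table$difference == 0))
  expect_true(is.na(fc$t_p) && is.na(fc$wilcoxon_p))
  expect_error(compare_fit(trees[1], v, v), "at least 2")
  mism <- lapply(1:2, function(s) ape::rtree(5))
  expect_error(compare_fit(c(trees[1], mism[1]), v, v), "leaf sets")
})

test_that("noisy published values score worse than the Brownian truth", {
  tr <- sim_tree(30, seed = 21)
  truth <- sim_gc(tr, seed = 22)
  set.seed(23)
  published <- leaf_values(truth$tip, truth$lo + stats::rnorm(30, 0, 2))
  h <- sim_hsp_table(tr, noise_sd = 0.01, jitter_sd = 0.05, seed = 24)
  boots <- bootstrap_matrices(h, replicates = 20, seed = 25)
  trees <- lapply(boots, gbdp_tree)
  fc <- compare_fit(trees, published, truth)
  expect_gt(fc$mean_difference, 0)
  expect_lt(fc$t_p, 0.05)
  expect_lt(fc$wilcoxon_p, 0.05)
})

test_that("range variants use lower, mid and upper published bounds", {
  trees <- lapply(1:2, function(s) {
    set.seed(s); ape::rtree(4, tip.label = LETTERS[1:4])
  })
  pub <- leaf_values(LETTERS[1:4], c(30, 40, 50, 60), c(34, 44, 54, 64))
  gen <- leaf_values(LETTERS[1:4], c(32, 42, 52, 62))
  scores <- vapply(c("pub-min", "pub-avg", "pub-max", "pub-as-range"),
                   function(v) compare_fit(trees, pub, gen,
                                           variant = v)$table$score_published[1],
                   numeric(1))
  # equal-width ranges shift all bounds equally: min/avg/max variants give
  # identical scores after the shared rescaling, the interval mode less
  expect_lte(scores["pub-as-range"], min(scores[1:3]) + 1e-9)
})

test_that("label-permuted values fit the tree worse than the truth", {
  wins <- 0
  for (seed in 1:20) {
    tr <- sim_tree(40, seed = 300 + seed)
    truth <- sim_gc(tr, seed = 400 + seed)
    s_true <- farris_score(tr, truth)
    set.seed(500 + seed)
    perm <- leaf_values(sample(truth$tip), truth$lo)
    if (s_true < farris_score(tr, perm)) wins <- wins + 1
  }
  expect_gte(wins, 19)
})
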