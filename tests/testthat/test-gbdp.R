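make_hsps <- function(qstart, qend, sstart = qstart, send = qend,
                      identities, length = qend - qstart + 1,
                      bitscore = 2 * identities, evalue = 1e-20,
                      query = "A", subject = "B") {
  hsp_table(data.frame(query = query, subject = subject,
                       qstart = qstart, qend = qend,
                       sstart = sstart, send = send,
                       identities = identities, length = length,
                       bitscore = bitscore, evalue = evalue,
                       stringsAsFactors = FALSE))
}

test_that("e-value filtering keeps hits at or below the threshold", {
  h <- make_hsps(c(1, 201), c(100, 300), identities = c(90, 80),
                 evalue = c(1e-10, 1e-5))
  expect_equal(nrow(filter_evalue(h)), 1)
  expect_equal(nrow(filter_evalue(h[0, ])), 0)
  expect_equal(nrow(filter_evalue(h, Inf)), 2)
  expect_error(filter_evalue(h, 0), "> 0")
})

test_that("greedy trimming reserves intervals and trims proportionally", {
  # disjoint HSPs pass through unchanged
  h <- make_hsps(c(1, 201), c(100, 300), identities = c(90, 80))
  expect_equal(sum(greedy_trim(h)$length), 200)

  # exact duplicates of an accepted HSP are dropped
  dup <- make_hsps(c(1, 1), c(100, 100), identities = c(100, 90),
                   bitscore = c(200, 150))
  expect_equal(nrow(greedy_trim(dup)), 1)
  expect_equal(greedy_trim(dup)$identities, 100)

  # half-overlapping HSP loses half its columns and identities
  ov <- make_hsps(c(1, 51), c(100, 150), sstart = c(1, 201),
                  send = c(100, 300), identities = c(100, 80),
                  bitscore = c(200, 150))
  out <- greedy_trim(ov)
  expect_equal(out$length, c(100, 50))
  expect_equal(out$identities, c(100, 40))
  expect_equal(out$qstart, c(1, 101))

  # overlap on the subject side alone also trims
  sov <- make_hsps(c(1, 201), c(100, 300), sstart = c(1, 51),
                   send = c(100, 150), identities = c(100, 80),
                   bitscore = c(200, 150))
  out2 <- greedy_trim(sov)
  expect_equal(out2$length, c(100, 50))

  mixed <- make_hsps(c(1, 201), c(100, 300), identities = c(90, 80),
                     subject = c("B", "C"))
  expect_error(greedy_trim(mixed), "single ordered")
})

test_that("trimming never increases summed length and reserves disjointly",
{
  for (seed in 1:10) {
    set.seed(seed)
    n <- 12
    qs <- sample(1:500, n); ql <- sample(20:120, n, replace = TRUE)
    ss <- sample(1:500, n)
    h <- make_hsps(qs, qs + ql - 1, sstart = ss, send = ss + ql - 1,
                   identities = pmax(1, round(ql * stats::runif(n, .5, 1))),
                   bitscore = sample(50:300, n))
    out <- greedy_trim(h)
    expect_lte(sum(out$length), sum(h$length))
    expect_true(all(out$identities <= out$length))
    expect_true(all(out$length >= 1))
  }
})

test_that("d5 relates identities to alignment length, averaged over
           directions", {
  ab <- make_hsps(1, 1000, identities = 900)
  ba <- make_hsps(1, 1000, identities = 850, query = "B", subject = "A")
  expect_equal(d5(ab, ba), 0.125)
  # identity-perfect hits give distance zero
  expect_equal(d5(make_hsps(1, 500, identities = 500),
                  make_hsps(1, 500, identities = 500, query = "B",
                            subject = "A")), 0)
  # one empty direction falls back to the other
  expect_equal(d5(ab, ab[0, ]), 0.1)
  expect_warning(v <- d5(ab[0, ], ab[0, ]), "no HSPs")
  expect_equal(v, 1)
  # log variant is -log of the ratio
  expect_equal(d5(ab, ba, formula = "logd5"),
               mean(-log(c(0.9, 0.85))))
})

test_that("distance matrices are symmetric with zero diagonal in [0,1]", {
  tr <- sim_tree(6, seed = 2)
  h <- sim_hsp_table(tr, noise_sd = 0.02, seed = 3)
  m <- gbdp_distance_matrix(h)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 6), rownames(m)))
  expect_true(all(m >= 0 & m <= 1))
  two <- h[h$query %in% c("t01", "t02") & h$subject %in% c("t01", "t02"), ]
  attr(two, "genome_lengths") <- NULL
  expect_error(gbdp_distance_matrix(two), "at least 3")
})

test_that("missing genome pairs get maximal distance with a warning", {
  h <- sim_hsp_table(sim_tree(4, seed = 1), seed = 1)
  drop <- !(h$query == "t01" & h$subject == "t02") &
    !(h$query == "t02" & h$subject == "t01")
  expect_warning(m <- gbdp_distance_matrix(h[drop, ]), "maximal distance")
  expect_equal(m["t01", "t02"], 1)
})

test_that("noise-free synthetic tables reproduce exp-transformed path
           distances", {
  tr <- sim_tree(8, seed = 9)
  m <- gbdp_distance_matrix(sim_hsp_table(tr, noise_sd = 0, seed = 2))
  D <- ape::cophenetic.phylo(tr)
  expect_lt(max(abs(m[rownames(D), colnames(D)] - (1 - exp(-D)))), 1e-3)
})

test_that("pseudo-bootstrap is seed-deterministic and degenerates with a
           single HSP per pair", {
  tr <- sim_tree(4, seed = 4)
  h1 <- sim_hsp_table(tr, k = 1, seed = 5)
  m <- gbdp_distance_matrix(h1)
  b <- bootstrap_matrices(h1, replicates = 5, seed = 99)
  for (x in b) expect_equal(x, m)

  h <- sim_hsp_table(tr, k = 8, noise_sd = 0.02, jitter_sd = 0.05,
                     seed = 6)
  b1 <- bootstrap_matrices(h, replicates = 4, seed = 42)
  b2 <- bootstrap_matrices(h, replicates = 4, seed = 42)
  expect_identical(b1, b2)
  expect_equal(length(bootstrap_matrices(h, replicates = 0, seed = 1)), 0)
  # resampling actually varies when HSPs are heterogeneous
  expect_false(isTRUE(all.equal(b1[[1]], b1[[2]])))
})

test_that("three-taxon trees solve the closed-form branch lengths", {
  m <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- gbdp_tree(m)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = .05, B = .15, C = .25))
})

test_that("additive matrices are recovered exactly, negative estimates
           clamped", {
  # ((A:1,B:2):1,(C:3,D:4)) as a distance table
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 3
  m["C", "D"] <- m["D", "C"] <- 7
  m["A", "C"] <- m["C", "A"] <- 5
  m["A", "D"] <- m["D", "A"] <- 6
  m["B", "C"] <- m["C", "B"] <- 6
  m["B", "D"] <- m["D", "B"] <- 7
  tr <- gbdp_tree(m)
  expect_identical(split_keys(tr), "A|B")
  got <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(got, m, tolerance = 1e-10)

  z <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_equal(sum(gbdp_tree(z)$edge.length), 0)

  bad <- m; bad["A", "B"] <- 2
  expect_error(gbdp_tree(bad), "symmetric")
  neg <- m; neg["A", "B"] <- neg["B", "A"] <- -1
  expect_error(gbdp_tree(neg), "negative")
})

test_that("BLAST tabular input round-trips through the writer", {
  tr <- sim_tree(4, seed = 8)
  h <- sim_hsp_table(tr, k = 3, seed = 8)
  path <- tempfile(fileext = ".tsv")
  write_blast_tab(h, path)
  back <- read_blast_tab(path)
  expect_equal(back$identities, h$identities)
  expect_equal(back$length, h$length)
  expect_equal(back$query, h$query)
  # without the nident column identities come from rounded pident
  tab12 <- utils::read.table(path, sep = "\t")[, 1:12]
  p2 <- tempfile(fileext = ".tsv")
  utils::write.table(tab12, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back12 <- read_blast_tab(p2)
  expect_true(all(abs(back12$identities - h$identities) <= 1))
})

test_that("PHYLIP output has the expected shape", {
  m <- gbdp_distance_matrix(sim_hsp_table(sim_tree(4, seed = 3),
                                          seed = 3))
  path <- tempfile(fileext = ".phy")
  write_phylip(m, path)
  lines <- readLines(path)
  expect_equal(as.integer(trimws(lines[1])), 4)
  expect_length(lines, 5)
  expect_equal(length(strsplit(trimws(lines[2]), "\\s+")[[1]]), 5)
})
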