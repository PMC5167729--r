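test_that("clades are monophyletic with the edge's support reported", {
  tr <- read_support_tree("((A,B)90,(C,D)80);")
  r <- classify_taxon(tr, c("A", "B"))
  expect_equal(r$status, "monophyletic")
  expect_equal(r$support_for, 90)
  expect_true(is.na(r$support_against))
})

test_that("paraphyly and polyphyly are separated by membership origins", {
  r <- classify_taxon(read_support_tree("(((A,C)70,B)90,D);"),
                      c("A", "B"))
  expect_equal(r$status, "paraphyletic")
  expect_equal(r$conflicting_edges$split, "A|C")
  expect_equal(r$support_against, 70)

  r2 <- classify_taxon(read_support_tree("((A,B)90,(C,D)80);"),
                       c("A", "D"))
  expect_equal(r2$status, "polyphyletic")
  expect_setequal(r2$conflicting_edges$split, c("A|B", "C|D"))
  expect_equal(r2$support_against, 90)
})

test_that("single-member and all-tip taxa are trivial; bad input errors", {
  tr <- read_support_tree("((A,B)90,(C,D)80);")
  expect_equal(classify_taxon(tr, "A")$status, "trivial")
  expect_equal(classify_taxon(tr, c("A", "B", "C", "D"))$status,
               "trivial")
  expect_error(classify_taxon(tr, character()), "empty")
  expect_error(classify_taxon(tr, c("A", "Z")), "unknown")
  expect_error(classify_taxon(ape::unroot(tr), c("A", "B")), "rooted")
})

test_that("edges without support never enter the support-against maximum",
{
  tr <- read_support_tree("(((A,C),B)90,D);")  # conflicting edge A|C bare
  r <- classify_taxon(tr, c("A", "B"))
  expect_equal(r$status, "paraphyletic")
  expect_true(is.na(r$support_against))
})

test_that("every subtree of random trees is monophyletic with its own
           support", {
  for (seed in 1:10) {
    tr <- rand_support_tree(10, seed)
    sets <- oracle_tip_sets(tr)
    ntip <- length(tr$tip.label)
    sup <- suppressWarnings(as.numeric(tr$node.label))
    for (nd in (ntip + 2):(ntip + tr$Nnode)) {
      r <- classify_taxon(tr, sets[[nd]])
      if (length(sets[[nd]]) == ntip || length(sets[[nd]]) == 1) next
      expect_equal(r$status, "monophyletic")
      expect_equal(r$support_for, sup[nd - ntip])
    }
  }
})

test_that("classification matches exhaustive enumeration on random trees",
{
  mismatches <- 0L
  for (seed in 1:30) {
    n <- 4 + (seed %% 5)
    tr <- rand_support_tree(n, seed)
    context <- taxaudit:::monophyly_context(tr)
    sets <- oracle_tip_sets(tr)
    free <- setdiff((n + 1):(n + tr$Nnode), n + 1L)
    assign <- as.matrix(expand.grid(rep(list(0:1), length(free))))
    tips <- tr$tip.label
    for (code in seq_len(2^n - 2)) {
      members <- tips[bitwAnd(code, 2^(seq_len(n) - 1)) > 0]
      got <- classify_taxon(tr, members, context = context)
      want <- oracle_classify(tr, members, tip_sets = sets,
                              assign = assign)
      ok <- identical(got$status, want$status) &&
        identical(sort(got$conflicting_edges$split), want$conflicting) &&
        identical(is.na(got$support_against), is.na(want$against)) &&
        isTRUE(all.equal(got$support_against, want$against))
      if (!ok) mismatches <- mismatches + 1L
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("support against grows when a conflicting edge's support grows",
{
  base <- "(((A,C)%d,B)90,(D,E)30);"
  vals <- vapply(c(10, 40, 70, 95), function(s)
    classify_taxon(read_support_tree(sprintf(base, s)),
                   c("A", "B"))$support_against, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("complement taxa share conflicting edges away from the root", {
  for (seed in 1:10) {
    tr <- rand_support_tree(8, seed + 100)
    tips <- tr$tip.label
    set.seed(seed)
    members <- sample(tips, 3)
    a <- classify_taxon(tr, members)
    b <- classify_taxon(tr, setdiff(tips, members))
    if (a$status == "monophyletic" || b$status == "monophyletic") next
    root_children <- tr$edge[tr$edge[, 1] == length(tips) + 1L, 2]
    sets <- oracle_tip_sets(tr)
    root_keys <- vapply(sets[root_children], function(s)
      paste(sort(s), collapse = "|"), character(1))
    ka <- setdiff(a$conflicting_edges$split, root_keys)
    kb <- setdiff(b$conflicting_edges$split, root_keys)
    expect_setequal(ka, kb)
  }
})

test_that("rank reports cover every named taxon in deterministic order", {
  tr <- sim_tree(16, seed = 5)
  tax <- sim_taxonomy(tr, n_genera = 4, n_families = 2)
  rep <- classify_taxa(tr, tax$map, rank = "genus")
  expect_equal(rep$taxon, sort(unique(tax$map$genus)))
  expect_true(all(rep$status == "monophyletic"))

  rep_all <- classify_taxa(tr, tax$map)
  expect_equal(rep_all$rank[1], "species")
  expect_true(all(rep_all$status[rep_all$rank == "species"] == "trivial"))
  expect_equal(sum(rep_all$rank == "family"), 2)

  expect_error(classify_taxa(tr, tax$map, rank = "tribe"), "unknown rank")
  empty <- classify_taxa(tr, data.frame(tip_label = character(),
                                        genus = character()))
  expect_equal(nrow(empty), 0)
})

test_that("tips without an assignment are non-members at that rank", {
  tr <- read_support_tree("(((A,B)90,C)80,D);")
  map <- data.frame(tip_label = c("A", "B", "C", "D"),
                    genus = c("G1", "G1", NA, NA))
  rep <- classify_taxa(tr, map, rank = "genus")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$status, "monophyletic")
  expect_equal(rep$signed_support, 90)
})

test_that("planted taxonomy violations are flagged and only they are", {
  tr <- sim_tree(24, seed = 11)
  for (type in c("paraphyly", "polyphyly")) {
    tax <- sim_taxonomy(tr, n_genera = 6, n_families = 2,
                        violation = list(type = type))
    rep <- classify_taxa(tr, tax$map, rank = "genus")
    bad <- rep$taxon[rep$status %in% c("paraphyletic", "polyphyletic")]
    expect_identical(bad, tax$truth$taxon)
    want <- if (type == "paraphyly") "paraphyletic" else "polyphyletic"
    expect_identical(rep$status[rep$taxon == tax$truth$taxon], want)
  }
})
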