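# Independent oracles and small generators used across the test files.
# The oracles deliberately use different algorithms from the package code:
# monophyly is checked by exhaustive enumeration over internal-node state
# assignments, Farris scores by discrete min-plus dynamic programming over
# the integer grid (and full enumeration on the tiniest trees).

# random rooted binary tree with supports on a random subset of internal
# edges
rand_support_tree <- function(n, seed, p_support = 0.8) {
  set.seed(seed)
  tr <- ape::rtree(n)
  lab <- ifelse(stats::runif(tr$Nnode) < p_support,
                as.character(round(stats::runif(tr$Nnode, 0, 100), 2)), "")
  lab[1] <- ""  # root carries no edge
  tr$node.label <- lab
  tr
}

# tip sets below every node, by plain recursion over the edge list
# (independent of the package's postorder accumulation)
oracle_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    unlist(lapply(kids[[as.character(nd)]], rec))
  }
  lapply(seq_len(ntip + tree$Nnode), rec)
}

# exhaustive-enumeration classification of a member set on a rooted tree:
# status, conflicting edge keys (sorted below-side labels) and support
# against
oracle_classify <- function(tree, members, tip_sets = NULL,
                            assign = NULL) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  if (is.null(tip_sets)) tip_sets <- oracle_tip_sets(tree)
  if (length(members) == 1 || length(members) == ntip)
    return(list(status = "trivial", conflicting = character(),
                against = NA_real_))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  below <- tip_sets[internal_children]
  is_clade <- vapply(below, function(b) setequal(b, members), logical(1))
  if (any(is_clade)) {
    nd <- internal_children[which(is_clade)[1]]
    return(list(status = "monophyletic", conflicting = character(),
                against = NA_real_, for_support = sup[nd - ntip]))
  }
  confl <- vapply(below, function(b) {
    inm <- sum(b %in% members)
    inm >= 1 && inm < length(members) && inm < length(b)
  }, logical(1))
  keys <- sort(vapply(below[confl], function(b)
    paste(sort(b), collapse = "|"), character(1)))
  s <- sup[internal_children[confl] - ntip]
  s <- s[!is.na(s)]
  against <- if (length(s)) max(s) else NA_real_
  # enumerate all assignments of {0,1} to non-root internal nodes, root
  # fixed to 0 (non-member)
  if (is.null(assign)) {
    free <- setdiff((ntip + 1):nn, ntip + 1L)
    assign <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  }
  free <- setdiff((ntip + 1):nn, ntip + 1L)
  S <- matrix(0L, nrow(assign), nn)
  S[, seq_len(ntip)] <- rep(as.integer(tree$tip.label %in% members),
                            each = nrow(assign))
  if (length(free)) S[, free] <- assign
  P <- S[, tree$edge[, 1], drop = FALSE]
  C <- S[, tree$edge[, 2], drop = FALSE]
  changes <- rowSums(abs(P - C))
  origins <- rowSums(P == 0L & C == 1L)
  k <- min(origins[changes == min(changes)])
  list(status = if (k <= 1) "paraphyletic" else "polyphyletic",
       conflicting = keys, against = against)
}

# exact Farris score by min-plus DP over the integer grid: for integer
# leaf values an optimal solution exists with all internal values on the
# grid, so the discrete DP is exact
oracle_farris_grid <- function(tree, values, grid = 0:20) {
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1],
                      resolve.root = TRUE)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  ns <- length(grid)
  cost <- matrix(Inf, nn, ns)
  i <- match(tree$tip.label, values$tip)
  for (t in seq_len(ntip))
    cost[t, ] <- ifelse(grid >= values$lo[i[t]] & grid <= values$hi[i[t]],
                        0, Inf)
  eo <- ape::reorder.phylo(tree, "postorder")
  started <- logical(nn)
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    # child contribution: min over child state of cost + |state diff|
    contrib <- vapply(seq_len(ns), function(s)
      min(cost[ch, ] + abs(grid[s] - grid)), numeric(1))
    if (!started[p]) { cost[p, ] <- contrib; started[p] <- TRUE }
    else cost[p, ] <- cost[p, ] + contrib
  }
  min(cost[ntip + 1L, ])
}

# full enumeration over internal-node grid assignments (tiny trees only)
oracle_farris_enum <- function(tree, values, grid = 0:20) {
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1],
                      resolve.root = TRUE)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  i <- match(tree$tip.label, values$tip)
  combos <- as.matrix(expand.grid(rep(list(grid), tree$Nnode)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    x <- numeric(nn)
    x[seq_len(ntip)] <- values$lo[i]  # point leaves expected here
    x[(ntip + 1):nn] <- combos[r, ]
    tot <- sum(abs(x[tree$edge[, 1]] - x[tree$edge[, 2]]))
    if (tot < best) best <- tot
  }
  best
}

# unrooted split keys of a tree, for Robinson-Foulds-zero checks
split_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  keys <- names(tree_bipartitions(tree))
  sizes <- lengths(tree_bipartitions(tree))
  sort(keys[sizes > 1 & sizes < ntip - 1])
}

expect_same_topology <- function(a, b) {
  expect_identical(split_keys(a), split_keys(b))
}
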