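#' Read a support-annotated Newick tree
#'
#' Parses a Newick string or file into an \code{ape} \code{phylo} object and
#' validates it for use in downstream taxonomy auditing: tip labels must be
#' unique and non-empty, and internal node labels that parse as numbers are
#' interpreted as bootstrap support percentages and must lie in \[0, 100\].
#' Non-numeric internal labels are kept as plain node names (the common
#' RAxML/FastME output dialects are therefore read as-is).
#'
#' @param x a Newick string (must contain \code{"("} and end in \code{";"})
#'   or the path of a file holding one or more Newick trees.
#' @return a \code{phylo} object, or a \code{multiPhylo} list when the file
#'   contains several trees.
#' @examples
#' tr <- read_support_tree("((A:1,B:1)95:1,C:1);")
#' @export
read_support_tree <- function(x) {
  is_text <- length(x) == 1L && grepl("\\(", x) && grepl(";", x)
  txt <- if (is_text) x else paste(readLines(x), collapse = "\n")
  no <- nchar(gsub("[^(]", "", txt))
  nc <- nchar(gsub("[^)]", "", txt))
  if (no != nc)
    stop("unbalanced parentheses in Newick input (", no, " '(' vs ", nc,
         " ')')", call. = FALSE)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick input", call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    for (t in tr) validate_support_tree(t)
  } else {
    validate_support_tree(tr)
  }
  tr
}

validate_support_tree <- function(tree) {
  stopifnot_phylo(tree)
  tl <- tree$tip.label
  if (anyDuplicated(tl))
    stop("duplicate tip label(s): ",
         paste(unique(tl[duplicated(tl)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(tl))) stop("empty tip label", call. = FALSE)
  s <- node_supports(tree)
  bad <- which(!is.na(s) & (s < 0 | s > 100))
  if (length(bad))
    stop("support value outside [0, 100]: ",
         paste(tree$node.label[bad], collapse = ", "), call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length in input tree", call. = FALSE)
  invisible(tree)
}

#' Write a tree to Newick with supports as internal node labels
#'
#' Branch lengths are written with 6 significant digits; support values (when
#' present as node labels) are serialized as internal node labels, the
#' convention read back by [read_support_tree()].
#'
#' @param tree a \code{phylo} object (or \code{multiPhylo}).
#' @param file output path; when \code{NULL} the Newick string is returned.
#' @return the Newick string(s), invisibly when written to a file.
#' @export
write_support_tree <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 6)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Root a tree with an outgroup
#'
#' Roots the tree so that the root separates the outgroup side from the
#' ingroup. When the outgroup is not a clade in the unrooted tree, the tree
#' is rooted on the edge above the smallest subtree containing all outgroup
#' tips and a warning is emitted. Support labels are treated as edge
#' (bipartition) annotations and follow their split through the rerooting.
#'
#' @param tree a \code{phylo} object.
#' @param outgroup character vector of tip labels; must be a nonempty proper
#'   subset of the tips.
#' @return a rooted \code{phylo} object.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot_phylo(tree)
  tips <- tree$tip.label
  if (length(outgroup) == 0) stop("empty outgroup", call. = FALSE)
  unknown <- setdiff(outgroup, tips)
  if (length(unknown))
    stop("unknown tip label(s) in outgroup: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (length(outgroup) >= length(tips))
    stop("outgroup must be a proper subset of the tips", call. = FALSE)
  res <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
              edgelabel = TRUE),
    error = function(e) NULL)
  if (!is.null(res)) return(res)
  # outgroup is not a clade: root above its most recent common ancestor
  anchor <- setdiff(tips, outgroup)[1]
  tmp <- ape::root(tree, outgroup = anchor, resolve.root = TRUE,
                   edgelabel = TRUE)
  mrca <- ape::getMRCA(tmp, outgroup)
  warning("outgroup is not monophyletic in the unrooted tree; ",
          "rooting above its most recent common ancestor", call. = FALSE)
  ape::root(tmp, node = mrca, resolve.root = TRUE, edgelabel = TRUE)
}

#' Nontrivial bipartitions (splits) of a tree
#'
#' One canonical bipartition per internal edge (edges whose child end is an
#' internal node); pendant edges are excluded. Each bipartition is
#' represented by the lexicographically smaller side, as a sorted character
#' vector of tip labels; duplicates arising from the root edge of an
#' unrooted representation are collapsed.
#'
#' @param tree a \code{phylo} object; polytomies are allowed.
#' @return a named list of character vectors; names are canonical split
#'   keys (sorted labels joined by \code{"|"}).
#' @export
tree_bipartitions <- function(tree) {
  stopifnot_phylo(tree)
  es <- edge_split_table(tree)
  out <- es$side[!duplicated(es$key)]
  names(out) <- es$key[!duplicated(es$key)]
  out
}

# per internal edge: child node id, canonical split key, canonical side,
# side tip count, support of that edge (child node label)
edge_split_table <- function(tree) {
  ntip <- length(tree$tip.label)
  tips <- tree$tip.label
  sets <- node_tip_sets(tree)
  sup <- node_supports(tree)
  child <- tree$edge[, 2]
  internal <- child[child > ntip]
  key <- character(length(internal))
  side <- vector("list", length(internal))
  supp <- numeric(length(internal))
  for (i in seq_along(internal)) {
    below <- sets[[internal[i]]]
    k1 <- paste(sort(below), collapse = "|")
    comp <- setdiff(tips, below)
    k2 <- paste(sort(comp), collapse = "|")
    if (k1 <= k2) { key[i] <- k1; side[[i]] <- sort(below) }
    else { key[i] <- k2; side[[i]] <- sort(comp) }
    supp[i] <- sup[internal[i] - ntip]
  }
  list(node = internal, key = key, side = side, support = supp,
       size = lengths(side), ntip = ntip)
}

# TRUE for splits that every tree on the same leaf set contains
is_trivial_split <- function(size, ntip) size <= 1 | size >= ntip - 1

#' Map pseudo-bootstrap support from replicate trees onto a main tree
#'
#' Each internal edge of \code{main} receives a support value equal to 100
#' times the fraction of replicate trees containing the same (unrooted)
#' bipartition, rounded to 2 decimals. Trivial splits (one tip on a side)
#' are present in every tree and receive support 100. The result is
#' invariant to the order of the replicates and to their rooting.
#'
#' @param main a \code{phylo} object.
#' @param replicates a list (or \code{multiPhylo}) of trees on the identical
#'   leaf set; must be nonempty.
#' @return \code{main} with supports written into its internal node labels.
#' @export
map_support <- function(main, replicates) {
  stopifnot_phylo(main)
  if (length(replicates) == 0) stop("empty replicate list", call. = FALSE)
  tips <- sort(main$tip.label)
  for (r in replicates) {
    if (!identical(sort(r$tip.label), tips))
      stop("replicate tree leaf set differs from the main tree",
           call. = FALSE)
  }
  rep_keys <- lapply(replicates, function(r) {
    es <- edge_split_table(r)
    unique(es$key[!is_trivial_split(es$size, es$ntip)])
  })
  es <- edge_split_table(main)
  nrep <- length(replicates)
  labels <- rep("", main$Nnode)
  for (i in seq_along(es$node)) {
    if (is_trivial_split(es$size[i], es$ntip)) {
      val <- 100
    } else {
      k <- es$key[i]
      val <- round(100 * sum(vapply(rep_keys, function(ks) k %in% ks,
                                    logical(1))) / nrep, 2)
    }
    labels[es$node[i] - length(main$tip.label)] <- format(val)
  }
  main$node.label <- labels
  main
}

#' Mean branch support of a tree
#'
#' Arithmetic mean over all internal edges carrying a numeric support value,
#' rounded to 2 decimals; edges without a support are ignored.
#'
#' @param tree a \code{phylo} object with supports as internal node labels.
#' @return the mean support (percent).
#' @export
mean_branch_support <- function(tree) {
  stopifnot_phylo(tree)
  es <- edge_split_table(tree)
  s <- es$support[!is.na(es$support)]
  if (length(s) == 0) stop("no internal edge carries a support value",
                           call. = FALSE)
  round(mean(s), 2)
}
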