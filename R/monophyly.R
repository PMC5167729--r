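#' Classify a taxon on a rooted tree as mono-, para- or polyphyletic
#'
#' A taxon is \emph{monophyletic} when some edge's subtree contains exactly
#' its members; the support of that edge is reported as support for the
#' taxon. Otherwise the \emph{conflicting edges} are those whose subtree
#' contains at least one member, misses at least one member, and contains at
#' least one non-member; the maximum support among them is reported as
#' support against the taxon (edges lacking a support value contribute
#' nothing to the maximum). Paraphyly is distinguished from polyphyly by the
#' minimum number of independent origins of membership: with the root state
#' fixed to non-member, the binary membership character is optimized over
#' all minimum-change reconstructions and the smallest attainable number of
#' non-member-to-member transitions is taken; one origin means paraphyletic,
#' two or more polyphyletic. Taxa with a single member, or containing every
#' tip, are reported as trivial.
#'
#' @param tree a rooted \code{phylo} object; polytomies are allowed.
#' @param members character vector of tip labels belonging to the taxon.
#' @param taxon,rank optional name and rank carried into the report.
#' @param context precomputed tree context from repeated calls on the same
#'   tree (internal use; see [classify_taxa()]).
#' @return an object of class \code{monophyly_report}: a list with elements
#'   \code{taxon}, \code{rank}, \code{status}, \code{n_members},
#'   \code{support_for}, \code{support_against} and
#'   \code{conflicting_edges} (a data frame of canonical splits and their
#'   supports).
#' @examples
#' tr <- read_support_tree("((A,B)90,(C,D)80);")
#' classify_taxon(tr, c("A", "B"))$status
#' @export
classify_taxon <- function(tree, members, taxon = NA_character_,
                           rank = NA_character_, context = NULL) {
  if (is.null(context)) context <- monophyly_context(tree)
  tips <- context$tips
  if (length(members) == 0) stop("empty member set", call. = FALSE)
  unknown <- setdiff(members, tips)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  members <- unique(members)
  rep0 <- list(taxon = taxon, rank = rank, n_members = length(members),
               support_for = NA_real_, support_against = NA_real_,
               conflicting_edges = .empty_conflicts)
  if (length(members) == 1L || length(members) == length(tips)) {
    rep0$status <- "trivial"
    return(structure(rep0, class = "monophyly_report"))
  }
  memb <- tips %in% members
  # member counts below each internal edge
  es <- context$edges
  inm <- vapply(es$below, function(b) sum(memb[b]), integer(1))
  size <- lengths(es$below)
  exact <- which(inm == length(members) & size == length(members))
  if (length(exact)) {
    rep0$status <- "monophyletic"
    rep0$support_for <- es$support[exact[1]]
    return(structure(rep0, class = "monophyly_report"))
  }
  confl <- which(inm >= 1 & inm < length(members) & inm < size)
  o <- confl[order(es$below_key[confl])]
  ce <- structure(list(split = es$below_key[o], support = es$support[o]),
                  class = "data.frame",
                  row.names = seq_along(o))
  rep0$conflicting_edges <- ce
  s <- ce$support[!is.na(ce$support)]
  rep0$support_against <- if (length(s)) max(s) else NA_real_
  k <- min_member_origins(context, memb)
  rep0$status <- if (k <= 1L) "paraphyletic" else "polyphyletic"
  structure(rep0, class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat(sprintf("taxon: %s (rank: %s)\n", x$taxon, x$rank))
  cat(sprintf("status: %s (%d members)\n", x$status, x$n_members))
  if (x$status == "monophyletic")
    cat(sprintf("support for: %s\n",
                ifelse(is.na(x$support_for), "unknown", x$support_for)))
  if (x$status %in% c("paraphyletic", "polyphyletic")) {
    cat(sprintf("support against: %s\n",
                ifelse(is.na(x$support_against), "unknown",
                       x$support_against)))
    cat(sprintf("conflicting edges: %d\n", nrow(x$conflicting_edges)))
  }
  invisible(x)
}

.empty_conflicts <- structure(list(split = character(),
                                   support = numeric()),
                              class = "data.frame", row.names = integer())

# precomputed structures reused across taxa on one tree
monophyly_context <- function(tree) {
  stopifnot_phylo(tree)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (use root_with_outgroup())", call. = FALSE)
  ntip <- length(tree$tip.label)
  sets <- node_tip_sets(tree)
  # tip index sets per node for fast membership counting
  idx <- lapply(sets, function(s) match(s, tree$tip.label))
  es <- edge_split_table(tree)
  below <- lapply(es$node, function(nd) idx[[nd]])
  below_key <- vapply(below, function(b)
    paste(sort(tree$tip.label[b]), collapse = "|"), character(1))
  eo <- ape::reorder.phylo(tree, "postorder")
  list(tree = tree, tips = tree$tip.label, ntip = ntip,
       postorder_edge = eo$edge,
       edges = list(node = es$node, key = es$key, below_key = below_key,
                    support = es$support, below = below))
}

# minimum number of non-member -> member origins over all minimum-change
# reconstructions of the binary membership character, root fixed to
# non-member; lexicographic (changes, origins) dynamic program
min_member_origins <- function(context, memb) {
  ntip <- context$ntip
  nn <- ntip + context$tree$Nnode
  INF <- .Machine$integer.max %/% 4L
  cost <- matrix(0L, nn, 2)           # columns: state 0 (non-member), 1
  orig <- matrix(0L, nn, 2)
  cost[seq_len(ntip), 1] <- ifelse(memb, INF, 0L)
  cost[seq_len(ntip), 2] <- ifelse(memb, 0L, INF)
  edge <- context$postorder_edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    for (s in 0:1) {
      # child contribution under parent state s, lexicographic minimum
      c0 <- cost[ch, 1] + (s != 0L); o0 <- orig[ch, 1]
      c1 <- cost[ch, 2] + (s != 1L); o1 <- orig[ch, 2] + (s == 0L)
      if (c0 < c1 || (c0 == c1 && o0 <= o1)) {
        cost[p, s + 1] <- cost[p, s + 1] + c0
        orig[p, s + 1] <- orig[p, s + 1] + o0
      } else {
        cost[p, s + 1] <- cost[p, s + 1] + c1
        orig[p, s + 1] <- orig[p, s + 1] + o1
      }
    }
  }
  root <- ntip + 1L
  orig[root, 1]
}

#' Monophyly reports for every taxon at one or all ranks
#'
#' Runs [classify_taxon()] for each distinct taxon name at the requested
#' rank(s) of a taxonomy table. Tips lacking an assignment at a rank are
#' treated as non-members of every taxon at that rank. Results are ordered
#' by rank (species, genus, family, order, class, phylum) and then taxon
#' name.
#'
#' @param tree a rooted \code{phylo} object.
#' @param taxon_map a data frame with column \code{tip_label} plus one
#'   column per rank (see [read_taxon_map()]); extra tips absent from the
#'   tree cause an error.
#' @param rank one rank name, or \code{"all"}.
#' @return a data frame with columns \code{taxon}, \code{rank},
#'   \code{status}, \code{signed_support} (positive = support for a
#'   monophyletic taxon, negative = support against a non-monophyletic
#'   one), \code{n_members} and \code{conflicting_edges}; the full
#'   \code{monophyly_report} objects are attached as attribute
#'   \code{"reports"}.
#' @export
classify_taxa <- function(tree, taxon_map, rank = "all") {
  ranks <- c("species", "genus", "family", "order", "class", "phylum")
  if (identical(rank, "all")) use <- ranks
  else {
    if (!all(rank %in% ranks))
      stop("unknown rank: ", paste(setdiff(rank, ranks), collapse = ", "),
           call. = FALSE)
    use <- rank
  }
  context <- monophyly_context(tree)
  mapped <- taxon_map$tip_label
  unknown <- setdiff(mapped, context$tips)
  if (length(unknown))
    stop("taxonomy refers to tip(s) absent from the tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  reports <- list()
  rows <- list()
  for (rk in use) {
    if (!rk %in% names(taxon_map)) next
    vals <- taxon_map[[rk]]
    ok <- !is.na(vals) & nzchar(vals)
    for (taxon in sort(unique(vals[ok]))) {
      mem <- mapped[ok & vals == taxon]
      rep <- classify_taxon(tree, mem, taxon = taxon, rank = rk,
                            context = context)
      reports[[length(reports) + 1L]] <- rep
      signed <- switch(rep$status,
        monophyletic = rep$support_for,
        paraphyletic = ,
        polyphyletic = -rep$support_against,
        NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = taxon, rank = rk, status = rep$status,
        signed_support = signed, n_members = rep$n_members,
        conflicting_edges = paste(rep$conflicting_edges$split,
                                  collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(taxon = character(), rank = character(),
                  status = character(), signed_support = numeric(),
                  n_members = integer(), conflicting_edges = character(),
                  stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Read a taxonomy table
#'
#' Tab-separated file with header columns \code{tip_label}, \code{species},
#' \code{genus}, \code{family}, \code{order}, \code{class}, \code{phylum};
#' empty cells mark missing assignments. Only \code{tip_label} is required.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_taxon_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = c("", "NA"))
  if (!"tip_label" %in% names(df))
    stop("taxonomy table must have a 'tip_label' column", call. = FALSE)
  df
}

#' Write a taxonomy table
#' @param taxon_map data frame as returned by [read_taxon_map()].
#' @param path file path.
#' @export
write_taxon_map <- function(taxon_map, path) {
  utils::write.table(taxon_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
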