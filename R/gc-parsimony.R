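#' Leaf value sets for continuous-character parsimony
#'
#' Associates tips with closed intervals of a continuous character (G+C
#' content here); point values are intervals of width zero. Tips absent
#' from the set are treated as deactivated and pruned before scoring.
#'
#' @param tip character vector of tip labels.
#' @param lo,hi numeric interval bounds (recycled \code{hi = lo} for point
#'   values).
#' @return an object of class \code{leaf_values} (a data frame with
#'   columns \code{tip}, \code{lo}, \code{hi}).
#' @export
leaf_values <- function(tip, lo, hi = lo) {
  if (anyDuplicated(tip)) stop("duplicate tip labels", call. = FALSE)
  if (any(!is.finite(lo)) || any(!is.finite(hi)))
    stop("leaf values must be finite", call. = FALSE)
  if (any(lo > hi)) stop("interval with lo > hi", call. = FALSE)
  structure(data.frame(tip = as.character(tip), lo = lo, hi = hi,
                       stringsAsFactors = FALSE),
            class = c("leaf_values", "data.frame"))
}

#' Rescale leaf values into a fixed range
#'
#' Applies the affine map sending the smallest observed bound to \code{lo}
#' and the largest to \code{hi} (default \[0, 65\], the range used when
#' exporting continuous characters to TNT-style programs) to every interval
#' bound. When comparing two value sets their scores must be computed under
#' one shared map: pass the pooled observed range via \code{from}.
#'
#' @param values a \code{leaf_values} object.
#' @param lo,hi target range (defaults 0 and 65).
#' @param from optional numeric \code{c(min, max)} giving the source range
#'   of the map; defaults to the observed range of \code{values}.
#' @return the rescaled \code{leaf_values}.
#' @examples
#' v <- leaf_values(c("A", "B", "C"), c(40, 50, 60))
#' rescale_values(v)  # 0, 32.5, 65
#' @export
rescale_values <- function(values, lo = 0, hi = 65, from = NULL) {
  if (is.null(from)) from <- c(min(values$lo), max(values$hi))
  if (diff(from) <= 0)
    stop("all values identical: rescaling undefined (zero range)",
         call. = FALSE)
  f <- function(x) lo + (x - from[1]) * (hi - lo) / (from[2] - from[1])
  out <- values
  out$lo <- f(values$lo)
  out$hi <- f(values$hi)
  out
}

#' Farris-interval parsimony score of a continuous character
#'
#' Minimum total change of a single continuous character over a tree under
#' linear (Wagner/Farris) parsimony. The down-pass assigns each internal
#' node the intersection of its children's state intervals when nonempty
#' (no cost), else the gap interval between them, adding the gap width to
#' the score. Deactivated tips (absent from \code{values}) are pruned first
#' and resulting degree-2 nodes suppressed; the tree must be binary after
#' pruning. The score does not depend on the rooting.
#'
#' @param tree a \code{phylo} object (rooted or unrooted).
#' @param values a \code{leaf_values} object covering at least two tips of
#'   the tree.
#' @return the minimum total change (same units as the character).
#' @export
farris_score <- function(tree, values) {
  stopifnot_phylo(tree)
  active <- intersect(tree$tip.label, values$tip)
  if (length(active) < 2)
    stop("fewer than 2 active tips", call. = FALSE)
  drop <- setdiff(tree$tip.label, active)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  if (length(tree$tip.label) == 2) {
    i <- match(tree$tip.label, values$tip)
    gap <- max(0, values$lo[i[2]] - values$hi[i[1]],
               values$lo[i[1]] - values$hi[i[2]])
    return(gap)
  }
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1],
                      resolve.root = TRUE)
  nchild <- tabulate(tree$edge[, 1], nbins = length(tree$tip.label) +
                       tree$Nnode)
  if (any(nchild[nchild > 0] != 2))
    stop("non-binary node encountered; resolve polytomies first",
         call. = FALSE)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  lo <- hi <- numeric(nn)
  i <- match(tree$tip.label, values$tip)
  lo[seq_len(ntip)] <- values$lo[i]
  hi[seq_len(ntip)] <- values$hi[i]
  eo <- ape::reorder.phylo(tree, "postorder")
  score <- 0
  children <- vector("list", nn)
  for (k in seq_len(nrow(eo$edge)))
    children[[eo$edge[k, 1]]] <- c(children[[eo$edge[k, 1]]],
                                   eo$edge[k, 2])
  done <- logical(nn)
  done[seq_len(ntip)] <- TRUE
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]
    if (done[p]) next
    ch <- children[[p]]
    if (!all(done[ch])) next  # postorder guarantees both children first
    a <- ch[1]; b <- ch[2]
    L <- max(lo[a], lo[b]); H <- min(hi[a], hi[b])
    if (L <= H) { lo[p] <- L; hi[p] <- H }
    else { score <- score + (L - H); lo[p] <- H; hi[p] <- L }
    done[p] <- TRUE
  }
  score
}

#' Compare the phylogenetic fit of published vs genomic character values
#'
#' Scores two leaf value sets (published G+C and genome-derived G+C) on
#' each of a set of pseudo-bootstrap replicate trees under Farris-interval
#' parsimony and tests the per-tree score differences (published minus
#' genomic) against zero with a two-sided one-sample t-test and a Wilcoxon
#' signed-rank test. A positive mean difference means the genomic values
#' fit the phylogeny better. Both sets are rescaled with one shared affine
#' map over the union of their bounds; tips lacking a published value are
#' deactivated in both sets.
#'
#' @param replicate_trees a list (or \code{multiPhylo}) of at least two
#'   trees on one common leaf set.
#' @param published a \code{leaf_values} object; ranges allowed.
#' @param genomic a \code{leaf_values} object of point values.
#' @param variant how range-valued published data enter the analysis:
#'   lower bounds (\code{"pub-min"}), midpoints (\code{"pub-avg"},
#'   default), upper bounds (\code{"pub-max"}), or as full intervals
#'   (\code{"pub-as-range"}).
#' @param rescale_to target range of the shared affine map.
#' @return an object of class \code{fit_comparison}: per-replicate score
#'   table, mean difference, and the two test statistics with p-values
#'   (\code{NA} when every difference is zero).
#' @export
compare_fit <- function(replicate_trees, published, genomic,
                        variant = c("pub-avg", "pub-min", "pub-max",
                                    "pub-as-range"),
                        rescale_to = c(0, 65)) {
  variant <- match.arg(variant)
  if (length(replicate_trees) < 2)
    stop("need at least 2 replicate trees", call. = FALSE)
  tips <- sort(replicate_trees[[1]]$tip.label)
  for (t in replicate_trees)
    if (!identical(sort(t$tip.label), tips))
      stop("replicate trees have differing leaf sets", call. = FALSE)
  pub <- published[published$tip %in% tips, , drop = FALSE]
  pub <- switch(variant,
    "pub-min" = leaf_values(pub$tip, pub$lo),
    "pub-avg" = leaf_values(pub$tip, (pub$lo + pub$hi) / 2),
    "pub-max" = leaf_values(pub$tip, pub$hi),
    "pub-as-range" = leaf_values(pub$tip, pub$lo, pub$hi))
  active <- intersect(pub$tip, genomic$tip)
  if (length(active) < 2)
    stop("fewer than 2 tips with both published and genomic values",
         call. = FALSE)
  pub <- pub[match(active, pub$tip), , drop = FALSE]
  gen <- genomic[match(active, genomic$tip), , drop = FALSE]
  from <- c(min(pub$lo, gen$lo), max(pub$hi, gen$hi))
  pub <- rescale_values(pub, rescale_to[1], rescale_to[2], from = from)
  gen <- rescale_values(gen, rescale_to[1], rescale_to[2], from = from)
  n <- length(replicate_trees)
  sp <- sg <- numeric(n)
  for (k in seq_len(n)) {
    sp[k] <- farris_score(replicate_trees[[k]], pub)
    sg[k] <- farris_score(replicate_trees[[k]], gen)
  }
  d <- sp - sg
  # degenerate difference vectors (all zero, or constant across
  # replicates) admit no distributional test
  na_test <- list(statistic = NA_real_, p.value = NA_real_)
  if (length(unique(d)) == 1) {
    tt <- wt <- na_test
  } else {
    tt <- tryCatch(stats::t.test(d), error = function(e) na_test)
    wt <- tryCatch(suppressWarnings(stats::wilcox.test(d)),
                   error = function(e) na_test)
  }
  structure(list(
    variant = variant,
    table = data.frame(replicate = seq_len(n), score_published = sp,
                       score_genomic = sg, difference = d),
    mean_difference = mean(d),
    t_statistic = unname(tt$statistic), t_p = tt$p.value,
    wilcoxon_statistic = unname(wt$statistic), wilcoxon_p = wt$p.value),
    class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat("continuous-character fit comparison (", x$variant, ", ",
      nrow(x$table), " replicate trees)\n", sep = "")
  cat(sprintf("mean score difference (published - genomic): %.4f\n",
              x$mean_difference))
  cat(sprintf("t-test: t = %s, p = %s\n", format(x$t_statistic),
              format(x$t_p)))
  cat(sprintf("Wilcoxon signed rank: V = %s, p = %s\n",
              format(x$wilcoxon_statistic), format(x$wilcoxon_p)))
  invisible(x)
}
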