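#' Simulate a Yule tree
#'
#' Pure-birth (Yule) tree with the requested number of tips, rescaled to
#' unit height so that downstream rates and distance transforms have a
#' stable meaning regardless of tip count. Deterministic for a given seed.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth birth rate of the Yule process.
#' @param seed integer seed.
#' @return a rooted binary \code{phylo} object with tips
#'   \code{t01, t02, ...}.
#' @export
sim_tree <- function(n_tips, birth = 1, seed = 1) {
  if (n_tips < 3) stop("n_tips must be >= 3", call. = FALSE)
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tr
}

# split a tree's tips into k clades: repeatedly replace the largest
# internal group by its children, starting from the root's children;
# returns a list with per-group tip labels and clade node ids
partition_clades <- function(tree, k) {
  ntip <- length(tree$tip.label)
  sets <- node_tip_sets(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  groups <- children[[as.character(ntip + 1L)]]
  while (length(groups) < k) {
    sizes <- vapply(groups, function(n) length(sets[[n]]), integer(1))
    cand <- which(groups > ntip)
    if (!length(cand))
      stop("tree has too few tips for ", k, " clades", call. = FALSE)
    pick <- cand[which.max(sizes[cand])]
    groups <- c(groups[-pick], children[[as.character(groups[pick])]])
  }
  ord <- order(vapply(groups, function(n) min(match(sets[[n]],
                                                    tree$tip.label)),
                      integer(1)))
  groups <- groups[ord]
  list(tips = lapply(groups, function(n) sets[[n]]), nodes = groups)
}

# internal descendants of a clade node (excluding the node itself)
internal_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer()
  stack <- children[[as.character(node)]]
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    if (nd > ntip) {
      out <- c(out, nd)
      stack <- c(stack, children[[as.character(nd)]])
    }
  }
  out
}

#' Simulate a clade-consistent taxonomy with optional planted violations
#'
#' Assigns family and genus labels by cutting the tree into nested clades,
#' so that without violations every taxon is monophyletic by construction.
#' A paraphyly violation relabels one subclade nested strictly inside a
#' genus (not a direct child of the genus root) to a new genus name,
#' leaving the original genus with a single origin but no exact clade. A
#' polyphyly violation relabels one whole non-sister genus clade to another
#' genus's name, giving that genus two independent origins. The ground
#' truth is returned alongside the map.
#'
#' @param tree a rooted binary \code{phylo} object (e.g. from
#'   [sim_tree()]).
#' @param n_genera,n_families taxon counts at the two ranks.
#' @param violation \code{NULL}, or a list with element \code{type}
#'   (\code{"paraphyly"} or \code{"polyphyly"}); planted at genus rank.
#' @return a list with \code{map} (taxonomy data frame as accepted by
#'   [classify_taxa()]) and \code{truth} (data frame of planted
#'   violations: taxon, rank, type).
#' @export
sim_taxonomy <- function(tree, n_genera = 5, n_families = 2,
                         violation = NULL) {
  ntip <- length(tree$tip.label)
  if (n_genera < n_families)
    stop("need at least as many genera as families", call. = FALSE)
  fams <- partition_clades(tree, n_families)
  fam_sizes <- lengths(fams$tips)
  # largest-remainder allocation of genera to families, each >= 1
  quota <- n_genera * fam_sizes / ntip
  alloc <- pmax(1L, floor(quota))
  while (sum(alloc) < n_genera) {
    i <- which.max(quota - alloc)
    alloc[i] <- alloc[i] + 1L
  }
  while (sum(alloc) > n_genera) {
    i <- which.max(ifelse(alloc > 1, alloc - quota, -Inf))
    alloc[i] <- alloc[i] - 1L
  }
  genus <- family <- setNames(rep(NA_character_, ntip), tree$tip.label)
  genus_nodes <- list()
  g <- 0L
  for (f in seq_along(fams$tips)) {
    fam_name <- sprintf("Fam%02d", f)
    family[fams$tips[[f]]] <- fam_name
    k <- min(alloc[f], length(fams$tips[[f]]))
    sub <- if (length(fams$tips[[f]]) > 1)
      ape::keep.tip(tree, fams$tips[[f]]) else NULL
    parts <- if (k == 1 || is.null(sub)) list(fams$tips[[f]])
             else partition_clades(sub, k)$tips
    for (p in parts) {
      g <- g + 1L
      genus[p] <- sprintf("Gen%02d", g)
    }
  }
  truth <- data.frame(taxon = character(), rank = character(),
                      type = character(), stringsAsFactors = FALSE)
  if (!is.null(violation)) {
    type <- match.arg(violation$type, c("paraphyly", "polyphyly"))
    gnames <- sort(unique(genus))
    if (type == "paraphyly") {
      planted <- FALSE
      sets <- node_tip_sets(tree)
      children <- split(tree$edge[, 2], tree$edge[, 1])
      for (gn in gnames) {
        mem <- names(genus)[genus == gn]
        if (length(mem) < 3) next
        nd <- ape::getMRCA(tree, mem)
        direct <- children[[as.character(nd)]]
        # any subclade (or single tip) strictly below a child of the genus
        # root leaves a non-clade remainder when relabelled
        desc <- internal_descendants(tree, nd)
        deep_tips <- setdiff(which(tree$tip.label %in% mem), direct)
        cand <- c(setdiff(desc, direct), deep_tips)
        cand <- cand[vapply(cand, function(x)
          all(sets[[x]] %in% mem) &&
            length(sets[[x]]) <= length(mem) - 2, logical(1))]
        if (!length(cand)) next
        # prefer a multi-tip subclade so the new genus is itself a clade
        sizes <- vapply(cand, function(x) length(sets[[x]]), integer(1))
        pick <- if (any(sizes > 1)) cand[sizes > 1][1] else cand[1]
        genus[sets[[pick]]] <- "GenNovel"
        truth <- rbind(truth, data.frame(taxon = gn, rank = "genus",
                                         type = "paraphyly"))
        planted <- TRUE
        break
      }
      if (!planted)
        stop("no genus admits a planted paraphyly on this tree",
             call. = FALSE)
    } else {
      planted <- FALSE
      for (a in gnames) for (b in gnames) {
        if (planted || a == b) next
        ma <- names(genus)[genus == a]; mb <- names(genus)[genus == b]
        un <- c(ma, mb)
        if (length(un) >= ntip - 1) next
        # clades on opposite sides of the root: with the root state fixed
        # to non-member, a single origin of membership is impossible
        if (ape::getMRCA(tree, un) != ntip + 1L) next
        genus[mb] <- a
        truth <- rbind(truth, data.frame(taxon = a, rank = "genus",
                                         type = "polyphyly"))
        planted <- TRUE
      }
      if (!planted)
        stop("no genus pair admits a planted polyphyly on this tree",
             call. = FALSE)
    }
  }
  map <- data.frame(tip_label = tree$tip.label,
                    species = tree$tip.label,
                    genus = unname(genus[tree$tip.label]),
                    family = unname(family[tree$tip.label]),
                    order = NA_character_, class = NA_character_,
                    phylum = "Phy01", stringsAsFactors = FALSE)
  list(map = map, truth = truth)
}

#' Simulate G+C content evolving along a tree
#'
#' Brownian motion from the root value along every branch (variance =
#' rate times branch length), with each node value clamped to a biological
#' interval. Deterministic for a given seed.
#'
#' @param tree a \code{phylo} object with branch lengths.
#' @param root_value ancestral G+C (percent).
#' @param rate Brownian rate (percent squared per unit branch length).
#' @param clamp numeric \code{c(lo, hi)} clamp interval in percent.
#' @param seed integer seed.
#' @return a \code{leaf_values} object of tip point values.
#' @export
sim_gc <- function(tree, root_value = 50, rate = 25, clamp = c(20, 80),
                   seed = 1) {
  stopifnot_phylo(tree)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  vals <- numeric(nn)
  vals[ntip + 1L] <- root_value
  eo <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    step <- stats::rnorm(1, 0, sqrt(rate * eo$edge.length[k]))
    vals[ch] <- min(clamp[2], max(clamp[1], vals[p] + step))
  }
  leaf_values(tree$tip.label, vals[seq_len(ntip)])
}

#' Simulate a genome of specified G+C content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/200 and
#' P(A) = P(T) = (100 - gc)/200.
#'
#' @param length genome length in bases.
#' @param gc target G+C content in percent.
#' @param seed integer seed.
#' @return a \code{DNAbin} object holding one sequence named
#'   \code{"genome"}.
#' @export
sim_genome <- function(length, gc = 50, seed = 1) {
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  if (gc < 0 || gc > 100) stop("gc must lie in [0, 100]", call. = FALSE)
  set.seed(seed)
  p <- c(a = (100 - gc) / 200, c = gc / 200, g = gc / 200,
         t = (100 - gc) / 200)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  ape::as.DNAbin(list(genome = bases))
}

#' Simulate an incomplete draft assembly
#'
#' Retains a fixed fraction of the genome as non-overlapping contigs at
#' uniformly random positions: the retained length is split into
#' \code{n_contigs} random parts and the remainder into random inter-contig
#' gaps.
#'
#' @param genome a \code{DNAbin} object with one sequence (or a character
#'   vector of bases).
#' @param completeness fraction of the genome retained, in (0, 1].
#' @param n_contigs number of contigs.
#' @param seed integer seed.
#' @return a \code{DNAbin} object of \code{n_contigs} contig sequences.
#' @export
sim_draft <- function(genome, completeness = 0.9, n_contigs = 200,
                      seed = 1) {
  if (inherits(genome, "DNAbin")) {
    x <- if (is.list(genome)) genome[[1]] else genome
  } else x <- genome
  L <- length(x)
  if (completeness <= 0 || completeness > 1)
    stop("completeness must lie in (0, 1]", call. = FALSE)
  R <- round(completeness * L)
  if (R < n_contigs)
    stop("retained length smaller than the number of contigs",
         call. = FALSE)
  set.seed(seed)
  lens <- if (n_contigs == 1) R
          else diff(c(0, sort(sample.int(R - 1, n_contigs - 1)), R))
  G <- L - R
  gaps <- diff(c(0, sort(sample.int(G + 1, n_contigs, replace = TRUE) - 1),
                 G))
  starts <- cumsum(gaps[seq_len(n_contigs)]) +
    c(0, cumsum(lens)[-n_contigs]) + 1
  contigs <- lapply(seq_len(n_contigs), function(i)
    x[starts[i]:(starts[i] + lens[i] - 1)])
  names(contigs) <- sprintf("contig%04d", seq_len(n_contigs))
  class(contigs) <- "DNAbin"
  contigs
}

#' Simulate a tree-consistent HSP table
#'
#' For every genome pair the target identity ratio is
#' \eqn{r = \exp(-d)} of the patristic distance \eqn{d}, optionally
#' perturbed by Gaussian noise truncated to (0, 1]. Each direction receives
#' \code{k} HSPs of equal length whose pooled identities/length ratio
#' equals the (perturbed) target up to rounding; per-HSP jitter (mean
#' centred) creates within-pair heterogeneity so that pseudo-bootstrap
#' resampling has variance. Coordinates are non-overlapping so trimming is
#' a no-op unless overlap injection is enabled, which adds a redundant
#' lower-scoring copy of the first HSP of each direction.
#'
#' @param tree a \code{phylo} object with branch lengths.
#' @param k HSPs per direction.
#' @param len alignment length per HSP.
#' @param noise_sd standard deviation of the pair-level ratio perturbation.
#' @param jitter_sd standard deviation of the per-HSP ratio jitter
#'   (defaults to \code{noise_sd}).
#' @param inject_overlaps add overlapping redundant HSPs (exercises
#'   [greedy_trim()]).
#' @param seed integer seed.
#' @return an \code{hsp_table} with a genome-length registry.
#' @export
sim_hsp_table <- function(tree, k = 10, len = 1000, noise_sd = 0,
                          jitter_sd = noise_sd, inject_overlaps = FALSE,
                          seed = 1) {
  stopifnot_phylo(tree)
  set.seed(seed)
  D <- ape::cophenetic.phylo(tree)
  tips <- sort(tree$tip.label)
  rows <- list()
  glen <- (k + 2) * (len + 100)
  for (i in seq_along(tips)) for (j in seq_along(tips)) {
    if (j <= i) next
    a <- tips[i]; b <- tips[j]
    r0 <- exp(-D[a, b])
    r <- r0
    if (noise_sd > 0) {
      repeat {
        r <- r0 + stats::rnorm(1, 0, noise_sd)
        if (r > 0 && r <= 1) break
      }
    }
    for (dir in 1:2) {
      q <- if (dir == 1) a else b
      s <- if (dir == 1) b else a
      eps <- if (jitter_sd > 0) {
        e <- stats::rnorm(k, 0, jitter_sd)
        e - mean(e)
      } else rep(0, k)
      ri <- pmin(1, pmax(0, r + eps))
      ids <- round(ri * len)
      starts <- (seq_len(k) - 1) * (len + 100) + 1
      df <- data.frame(query = q, subject = s,
                       qstart = starts, qend = starts + len - 1,
                       sstart = starts, send = starts + len - 1,
                       identities = ids, length = len,
                       bitscore = 2 * ids + k - seq_len(k),
                       evalue = 1e-30, stringsAsFactors = FALSE)
      if (inject_overlaps) {
        dup <- df[1, , drop = FALSE]
        dup$bitscore <- dup$bitscore / 2
        df <- rbind(df, dup)
      }
      rows[[length(rows) + 1L]] <- df
    }
  }
  hsp_table(do.call(rbind, rows),
            genome_lengths = setNames(rep(glen, length(tips)), tips))
}

#' Simulate published G+C values from a truth set
#'
#' Adds Gaussian observation noise to genome-derived (true) G+C values and
#' reports some species as ranges and some as missing, mimicking the
#' heterogeneity of literature species descriptions.
#'
#' @param values a \code{leaf_values} object of true (genomic) point
#'   values.
#' @param noise_sd standard deviation of the observation noise (percentage
#'   points).
#' @param p_range probability that a value is reported as a range.
#' @param range_width width of reported ranges (percentage points).
#' @param p_missing probability that no value is reported.
#' @param seed integer seed.
#' @return a list with \code{values} (a \code{leaf_values} object lacking
#'   the missing species) and \code{records} (a data frame with
#'   \code{species}, \code{published} strings and \code{genomic} values,
#'   ready for [audit_gc()]).
#' @export
sim_published_gc <- function(values, noise_sd = 2, p_range = 0.3,
                             range_width = 2, p_missing = 0.1, seed = 1) {
  set.seed(seed)
  n <- nrow(values)
  noisy <- values$lo + stats::rnorm(n, 0, noise_sd)
  as_range <- stats::runif(n) < p_range
  missing <- stats::runif(n) < p_missing
  lo <- ifelse(as_range, noisy - range_width / 2, noisy)
  hi <- ifelse(as_range, noisy + range_width / 2, noisy)
  lo <- round_half_up(pmax(0, lo), 1)
  hi <- round_half_up(pmin(100, hi), 1)
  published <- ifelse(missing, "",
                      ifelse(as_range,
                             paste0(format(lo, nsmall = 1), "-",
                                    format(hi, nsmall = 1)),
                             format(lo, nsmall = 1)))
  keep <- !missing
  list(values = leaf_values(values$tip[keep], lo[keep], hi[keep]),
       records = data.frame(species = values$tip,
                            published = trimws(published),
                            genomic = values$lo,
                            stringsAsFactors = FALSE))
}

#' Write an HSP table as BLAST tabular output
#'
#' Emits the 12-column outfmt-6 dialect read back by [read_blast_tab()]
#' (\code{pident} is reconstructed from identities and length;
#' \code{mismatch} = length - identities; \code{gapopen} = 0) plus a 13th
#' \code{nident} column so identity counts round-trip exactly.
#'
#' @param hsps an \code{hsp_table}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_blast_tab <- function(hsps, path) {
  df <- data.frame(hsps$query, hsps$subject,
                   sprintf("%.2f", 100 * hsps$identities / hsps$length),
                   hsps$length, hsps$length - hsps$identities, 0,
                   hsps$qstart, hsps$qend, hsps$sstart, hsps$send,
                   format(hsps$evalue), hsps$bitscore, hsps$identities)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Materialize a complete demo workspace
#'
#' Generates every input the pipeline consumes — a tree, a BLAST tabular
#' hit file consistent with it, per-species genome FASTA files, a taxonomy
#' table with a planted paraphyly, and a published-G+C table — under one
#' directory, all deterministically from one seed.
#'
#' @param dir output directory (created if needed).
#' @param n_tips number of tips/genomes.
#' @param genome_length length of the demo genomes (kept small; these are
#'   for exercising the pipeline, not for realism).
#' @param seed integer seed.
#' @return a named list of the written paths.
#' @export
make_fixtures <- function(dir, n_tips = 12, genome_length = 20000,
                          seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- sim_tree(n_tips, seed = seed)
  tax <- sim_taxonomy(tr, n_genera = max(3, min(5, n_tips %/% 3)),
                      n_families = 2,
                      violation = list(type = "paraphyly"))
  gc <- sim_gc(tr, seed = seed + 1)
  pub <- sim_published_gc(gc, seed = seed + 2)
  hsps <- sim_hsp_table(tr, noise_sd = 0.01, jitter_sd = 0.03,
                        seed = seed + 3)
  paths <- list(
    tree = file.path(dir, "true_tree.nwk"),
    hits = file.path(dir, "hits.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    gc_table = file.path(dir, "gc_values.tsv"),
    genomes_dir = file.path(dir, "genomes"))
  write_support_tree(tr, paths$tree)
  write_blast_tab(hsps, paths$hits)
  write_taxon_map(tax$map, paths$taxonomy)
  utils::write.table(
    data.frame(species = pub$records$species,
               published_gc = pub$records$published,
               genomic_gc = pub$records$genomic),
    paths$gc_table, sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(paths$genomes_dir, showWarnings = FALSE)
  for (i in seq_len(n_tips)) {
    g <- sim_genome(genome_length, gc = gc$lo[i], seed = seed + 10 + i)
    names(g) <- tr$tip.label[i]
    ape::write.FASTA(g, file.path(paths$genomes_dir,
                                  paste0(tr$tip.label[i], ".fasta")))
  }
  paths
}
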