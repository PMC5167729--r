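#' Construct an HSP table
#'
#' An HSP table holds local-alignment hits (high-scoring segment pairs)
#' between ordered genome pairs, the raw material of GBDP distance
#' computation. Subject coordinates with \code{sstart > send} encode a
#' reverse-strand hit (nucleotide searches); query coordinates must be
#' ascending.
#'
#' @param hsps a data frame with columns \code{query}, \code{subject},
#'   \code{qstart}, \code{qend}, \code{sstart}, \code{send},
#'   \code{identities}, \code{length}, \code{bitscore}, \code{evalue}.
#' @param genome_lengths optional named numeric vector registering genome
#'   lengths (used to include genomes that have no hits at all).
#' @return an object of class \code{hsp_table} (a data frame).
#' @export
hsp_table <- function(hsps, genome_lengths = NULL) {
  need <- c("query", "subject", "qstart", "qend", "sstart", "send",
            "identities", "length", "bitscore", "evalue")
  miss <- setdiff(need, names(hsps))
  if (length(miss))
    stop("missing HSP column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  hsps <- as.data.frame(hsps)[need]
  if (any(hsps$length < 1)) stop("HSP length must be >= 1", call. = FALSE)
  if (any(hsps$identities < 0) || any(hsps$identities > hsps$length))
    stop("identities must lie in [0, length]", call. = FALSE)
  if (any(hsps$qstart > hsps$qend))
    stop("query coordinates must be ascending (qstart <= qend)",
         call. = FALSE)
  if (any(hsps$evalue < 0) || any(hsps$bitscore < 0))
    stop("evalue and bitscore must be non-negative", call. = FALSE)
  structure(hsps, genome_lengths = genome_lengths,
            class = c("hsp_table", "data.frame"))
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Reads the default 12-column BLAST+ tabular format (\code{qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore}).
#' Identities are computed as \code{round(pident * length / 100)}; when a
#' 13th column is present it is taken as an explicit \code{nident} count
#' and used instead.
#'
#' @param path path to one or more tabular hit files (concatenated).
#' @param genome_lengths optional named vector, see [hsp_table()].
#' @return an \code{hsp_table}.
#' @export
read_blast_tab <- function(path, genome_lengths = NULL) {
  raw <- do.call(rbind, lapply(path, utils::read.table, sep = "\t",
                               header = FALSE, stringsAsFactors = FALSE,
                               quote = "", comment.char = "#"))
  if (ncol(raw) < 12)
    stop("expected at least 12 tab-separated columns (BLAST outfmt 6)",
         call. = FALSE)
  ident <- if (ncol(raw) >= 13) raw[[13]]
           else round_half_up(raw[[3]] * raw[[4]] / 100)
  hsp_table(data.frame(
    query = as.character(raw[[1]]), subject = as.character(raw[[2]]),
    qstart = raw[[7]], qend = raw[[8]], sstart = raw[[9]], send = raw[[10]],
    identities = pmin(ident, raw[[4]]), length = raw[[4]],
    bitscore = raw[[12]], evalue = raw[[11]],
    stringsAsFactors = FALSE), genome_lengths = genome_lengths)
}

#' Filter HSPs by e-value
#'
#' @param hsps an \code{hsp_table}.
#' @param threshold maximum e-value retained (default \code{1e-8}, the
#'   conventional GBDP proteome-search filter).
#' @return the filtered \code{hsp_table}.
#' @export
filter_evalue <- function(hsps, threshold = 1e-8) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  out <- hsps[hsps$evalue <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, genome_lengths = attr(hsps, "genome_lengths"),
            class = class(hsps))
}

# map a coordinate interval [a, b] on the query (or subject) back to the
# alignment-column range it covers, given the span and alignment length;
# linear correspondence between columns and span positions
interval_to_columns <- function(a, b, span_start, span_width, L) {
  j1 <- ceiling((a - span_start) * L / span_width + 0.5)
  j2 <- ceiling((b - span_start + 1) * L / span_width + 0.5) - 1
  c(max(1L, j1), min(L, j2))
}

# alignment columns j1..j2 mapped to coordinates on a span
columns_to_interval <- function(j1, j2, span_start, span_width, L) {
  p1 <- span_start + floor((j1 - 0.5) * span_width / L)
  p2 <- span_start + floor((j2 - 0.5) * span_width / L)
  c(p1, p2)
}

#' Greedy-with-trimming HSP selection
#'
#' Corrects for non-orthologous (paralogous or repeated) matches before
#' distance computation. HSPs of one ordered genome pair are processed in
#' decreasing bit score (ties: decreasing identities, then input order); an
#' accepted HSP reserves its query and subject intervals, and every later
#' HSP loses the alignment columns that fall into already-reserved regions
#' on either genome (columns are mapped linearly between the query and
#' subject spans, as per-column coordinates are unavailable in tabular
#' output). Identities are reduced proportionally to the retained columns
#' and rounded half-up; HSPs retaining less than one column are dropped.
#'
#' @param hsps an \code{hsp_table} (or plain data frame) whose rows all
#'   belong to one ordered genome pair.
#' @return the trimmed \code{hsp_table}; the summed length never increases
#'   and the reserved intervals of the output are pairwise disjoint on both
#'   genomes.
#' @export
greedy_trim <- function(hsps) {
  if (nrow(hsps) == 0) return(hsps)
  if (length(unique(hsps$query)) > 1 || length(unique(hsps$subject)) > 1)
    stop("greedy_trim() expects HSPs of a single ordered genome pair",
         call. = FALSE)
  ord <- order(-hsps$bitscore, -hsps$identities, seq_len(nrow(hsps)))
  h <- hsps[ord, , drop = FALSE]
  # fast path: with pairwise disjoint intervals on both genomes nothing is
  # ever reserved twice and trimming is a no-op
  overlaps <- function(a, b) {
    o <- order(a)
    n <- length(a)
    n > 1 && any(a[o][-1] <= cummax(b[o])[-n])
  }
  if (!overlaps(h$qstart, h$qend) &&
      !overlaps(pmin(h$sstart, h$send), pmax(h$sstart, h$send))) {
    rownames(h) <- NULL
    return(structure(h, genome_lengths = attr(hsps, "genome_lengths"),
                     trimmed = TRUE, class = c("hsp_table", "data.frame")))
  }
  res_q <- IRanges::IRanges()
  res_s <- IRanges::IRanges()
  keep <- list()
  for (i in seq_len(nrow(h))) {
    L <- h$length[i]
    qs <- h$qstart[i]; qe <- h$qend[i]
    rev_s <- h$sstart[i] > h$send[i]
    smin <- min(h$sstart[i], h$send[i]); smax <- max(h$sstart[i], h$send[i])
    wq <- qe - qs + 1
    ws <- smax - smin + 1
    killed <- IRanges::IRanges()
    # overlap with reserved query intervals -> killed columns
    ovq <- IRanges::intersect(IRanges::IRanges(qs, qe), res_q)
    if (length(ovq)) {
      cols <- t(vapply(seq_along(ovq), function(k)
        interval_to_columns(IRanges::start(ovq)[k], IRanges::end(ovq)[k],
                            qs, wq, L), numeric(2)))
      ok <- cols[, 1] <= cols[, 2]
      if (any(ok))
        killed <- IRanges::union(killed,
                                 IRanges::IRanges(cols[ok, 1], cols[ok, 2]))
    }
    # overlap with reserved subject intervals -> killed columns
    ovs <- IRanges::intersect(IRanges::IRanges(smin, smax), res_s)
    if (length(ovs)) {
      cols <- t(vapply(seq_along(ovs), function(k) {
        a <- IRanges::start(ovs)[k]; b <- IRanges::end(ovs)[k]
        if (rev_s) {
          # reverse strand: subject position p sits at column mapped from
          # the mirrored coordinate
          interval_to_columns(smin + (smax - b), smin + (smax - a),
                              smin, ws, L)
        } else interval_to_columns(a, b, smin, ws, L)
      }, numeric(2)))
      ok <- cols[, 1] <= cols[, 2]
      if (any(ok))
        killed <- IRanges::union(killed,
                                 IRanges::IRanges(cols[ok, 1], cols[ok, 2]))
    }
    retained <- IRanges::setdiff(IRanges::IRanges(1, L), killed)
    rl <- sum(IRanges::width(retained))
    if (rl < 1) next
    row <- h[i, , drop = FALSE]
    if (rl < L) {
      row$identities <- round_half_up(h$identities[i] * rl / L)
      row$length <- rl
    }
    # reserve the retained column ranges, mapped back to both genomes
    qiv <- siv <- NULL
    for (k in seq_along(retained)) {
      j1 <- IRanges::start(retained)[k]; j2 <- IRanges::end(retained)[k]
      qi <- columns_to_interval(j1, j2, qs, wq, L)
      qiv <- rbind(qiv, qi)
      if (rev_s) {
        m <- columns_to_interval(j1, j2, smin, ws, L)
        siv <- rbind(siv, c(smin + (smax - m[2]), smin + (smax - m[1])))
      } else siv <- rbind(siv, columns_to_interval(j1, j2, smin, ws, L))
    }
    res_q <- IRanges::union(res_q, IRanges::IRanges(qiv[, 1], qiv[, 2]))
    res_s <- IRanges::union(res_s, IRanges::IRanges(siv[, 1], siv[, 2]))
    if (rl < L) {
      row$qstart <- min(qiv[, 1]); row$qend <- max(qiv[, 2])
      if (rev_s) { row$sstart <- max(siv[, 2]); row$send <- min(siv[, 1]) }
      else { row$sstart <- min(siv[, 1]); row$send <- max(siv[, 2]) }
    }
    keep[[length(keep) + 1L]] <- row
  }
  out <- if (length(keep)) do.call(rbind, keep) else hsps[0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, genome_lengths = attr(hsps, "genome_lengths"),
            trimmed = TRUE, class = c("hsp_table", "data.frame"))
}

#' GBDP distance formula d5 for one genome pair
#'
#' For each direction the ratio \eqn{r} of summed identities to summed
#' alignment length over the (trimmed) HSPs is formed; the directed
#' distance is \eqn{1 - r} (or \eqn{-\log r} for the logarithmic variant)
#' and the two directions are averaged. Because only aligned regions enter
#' both numerator and denominator, the value is insensitive to incomplete
#' genome sequencing. When one direction has no HSPs the other is used
#' alone; when neither has HSPs the maximal distance 1 is returned with a
#' warning.
#'
#' @param hsps_ab,hsps_ba HSP sets for the two directions (data frames with
#'   at least \code{identities}, \code{length} and, if \code{trim = TRUE},
#'   the coordinate and score columns).
#' @param trim apply [greedy_trim()] to each direction first (set to
#'   \code{FALSE} for already-trimmed input).
#' @param formula \code{"d5"} (default, bounded in \[0, 1\]) or
#'   \code{"logd5"} (\eqn{-\log} of the ratio; additive for ratios decaying
#'   exponentially with evolutionary distance).
#' @return the intergenomic distance.
#' @examples
#' ab <- data.frame(query = "A", subject = "B", qstart = 1, qend = 1000,
#'                  sstart = 1, send = 1000, identities = 900,
#'                  length = 1000, bitscore = 1800, evalue = 0)
#' ba <- transform(ab, query = "B", subject = "A", identities = 850)
#' d5(ab, ba)  # (0.1 + 0.15) / 2
#' @export
d5 <- function(hsps_ab, hsps_ba, trim = TRUE, formula = c("d5", "logd5")) {
  formula <- match.arg(formula)
  if (trim) {
    if (nrow(hsps_ab)) hsps_ab <- greedy_trim(hsps_ab)
    if (nrow(hsps_ba)) hsps_ba <- greedy_trim(hsps_ba)
  }
  dir_dist <- function(h) {
    if (nrow(h) == 0) return(NA_real_)
    if (any(h$identities > h$length))
      stop("identities exceed length in an HSP", call. = FALSE)
    r <- sum(h$identities) / sum(h$length)
    if (formula == "d5") 1 - r else -log(r)
  }
  da <- dir_dist(hsps_ab)
  db <- dir_dist(hsps_ba)
  if (is.na(da) && is.na(db)) {
    warning("no HSPs in either direction; returning maximal distance",
            call. = FALSE)
    return(if (formula == "d5") 1 else Inf)
  }
  mean(c(da, db), na.rm = TRUE)
}

# rows of an hsp_table split by ordered pair, as a named list
split_by_pair <- function(hsps) {
  if (nrow(hsps) == 0) return(list())
  split(seq_len(nrow(hsps)), paste(hsps$query, hsps$subject, sep = "\r"))
}

#' Trim every ordered pair of an HSP table
#'
#' @param hsps an \code{hsp_table}.
#' @return the \code{hsp_table} with [greedy_trim()] applied per ordered
#'   genome pair (marked so that downstream functions skip re-trimming).
#' @export
trim_hsp_table <- function(hsps) {
  idx <- split_by_pair(hsps)
  parts <- lapply(idx, function(i) greedy_trim(hsps[i, , drop = FALSE]))
  out <- if (length(parts)) do.call(rbind, parts)
  else hsps[0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, genome_lengths = attr(hsps, "genome_lengths"),
            trimmed = TRUE, class = c("hsp_table", "data.frame"))
}

#' Pairwise GBDP distance matrix
#'
#' Applies [d5()] to every unordered genome pair of the table. Genome pairs
#' without any HSPs in either direction receive the maximal distance 1 with
#' a warning (never a silent \code{NA}). The genome set is the union of
#' query and subject identifiers plus any genomes registered via
#' \code{genome_lengths}.
#'
#' @param hsps an \code{hsp_table}.
#' @param trim trim per ordered pair first (skipped automatically for
#'   tables returned by [trim_hsp_table()]).
#' @param formula distance formula, see [d5()].
#' @return a symmetric numeric matrix with zero diagonal and the genome
#'   names as dimnames.
#' @export
gbdp_distance_matrix <- function(hsps, trim = TRUE,
                                 formula = c("d5", "logd5")) {
  formula <- match.arg(formula)
  if (trim && !isTRUE(attr(hsps, "trimmed"))) hsps <- trim_hsp_table(hsps)
  genomes <- sort(unique(c(hsps$query, hsps$subject,
                           names(attr(hsps, "genome_lengths")))))
  n <- length(genomes)
  if (n < 3) stop("need at least 3 genomes", call. = FALSE)
  idx <- split_by_pair(hsps)
  m <- matrix(0, n, n, dimnames = list(genomes, genomes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- genomes[i]; b <- genomes[j]
    ab <- idx[[paste(a, b, sep = "\r")]]
    ba <- idx[[paste(b, a, sep = "\r")]]
    if (is.null(ab) && is.null(ba)) {
      warning("no HSPs between ", a, " and ", b,
              "; using maximal distance 1", call. = FALSE)
      d <- 1
    } else {
      d <- d5(hsps[ab, , drop = FALSE], hsps[ba, , drop = FALSE],
              trim = FALSE, formula = formula)
    }
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Pseudo-bootstrap replicate distance matrices
#'
#' GBDP pseudo-bootstrapping resamples HSPs (not alignment columns): for
#' each replicate, the trimmed HSP list of every ordered genome pair is
#' independently resampled with replacement at its original cardinality and
#' the d5 distance recomputed. Deterministic for a given seed.
#'
#' @param hsps an \code{hsp_table}.
#' @param replicates number of replicates (default 100).
#' @param seed integer seed.
#' @param formula distance formula, see [d5()].
#' @return a list of distance matrices of length \code{replicates}.
#' @export
bootstrap_matrices <- function(hsps, replicates = 100, seed = 1,
                               formula = c("d5", "logd5")) {
  formula <- match.arg(formula)
  if (replicates < 0) stop("replicates must be >= 0", call. = FALSE)
  if (replicates == 0) return(list())
  if (!isTRUE(attr(hsps, "trimmed"))) hsps <- trim_hsp_table(hsps)
  genomes <- sort(unique(c(hsps$query, hsps$subject,
                           names(attr(hsps, "genome_lengths")))))
  n <- length(genomes)
  if (n < 3) stop("need at least 3 genomes", call. = FALSE)
  idx <- split_by_pair(hsps)
  id <- hsps$identities
  len <- hsps$length
  dist_from <- function(take_ab, take_ba) {
    # directed distances from resampled identity/length sums
    da <- if (length(take_ab)) {
      r <- sum(id[take_ab]) / sum(len[take_ab])
      if (formula == "d5") 1 - r else -log(r)
    } else NA_real_
    db <- if (length(take_ba)) {
      r <- sum(id[take_ba]) / sum(len[take_ba])
      if (formula == "d5") 1 - r else -log(r)
    } else NA_real_
    if (is.na(da) && is.na(db)) return(if (formula == "d5") 1 else Inf)
    mean(c(da, db), na.rm = TRUE)
  }
  set.seed(seed)
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    res <- lapply(idx, function(i)
      i[sample.int(length(i), length(i), replace = TRUE)])
    m <- matrix(0, n, n, dimnames = list(genomes, genomes))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ab <- res[[paste(genomes[i], genomes[j], sep = "\r")]]
      ba <- res[[paste(genomes[j], genomes[i], sep = "\r")]]
      m[i, j] <- m[j, i] <-
        if (is.null(ab) && is.null(ba)) 1
        else dist_from(ab %||% integer(), ba %||% integer())
    }
    out[[r]] <- m
  }
  out
}

#' Distance tree by neighbour joining
#'
#' Builds an unrooted binary tree from a symmetric distance matrix by NJ or
#' BIONJ. Negative estimated branch lengths are clamped to zero with a
#' warning. For three taxa the closed-form three-point branch lengths are
#' obtained.
#'
#' @param m symmetric numeric matrix with non-negative entries and zero
#'   diagonal (labels as dimnames).
#' @param method \code{"nj"} (default) or \code{"bionj"}.
#' @return an unrooted \code{phylo} object.
#' @export
gbdp_tree <- function(m, method = c("nj", "bionj")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need at least 3 labels", call. = FALSE)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(m < 0)) stop("distance matrix has negative entries",
                       call. = FALSE)
  tr <- if (method == "nj") ape::nj(m) else ape::bionj(m)
  if (any(tr$edge.length < 0)) {
    warning("negative branch length estimate(s) clamped to 0",
            call. = FALSE)
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write a distance matrix in PHYLIP format
#'
#' @param m symmetric matrix with dimnames.
#' @param file output path.
#' @param lower write the lower-triangle dialect instead of the square one.
#' @return the path, invisibly.
#' @export
write_phylip <- function(m, file, lower = FALSE) {
  m <- as.matrix(m)
  labs <- rownames(m)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    vals <- if (lower) m[i, seq_len(i - 1), drop = TRUE] else m[i, ]
    writeLines(paste(formatC(labs[i], width = -10),
                     paste(sprintf("%.6f", vals), collapse = " ")), con)
  }
  invisible(file)
}
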