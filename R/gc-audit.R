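#' Genomic G+C content (mol%)
#'
#' Computes 100 * (G + C + S) / (A + C + G + T + S + W) pooled over all
#' records, case-insensitively. The ambiguity code S (G or C) counts fully
#' towards G+C and W (A or T) fully towards A+T; every other IUPAC
#' ambiguity code, N and gap characters are excluded from both numerator
#' and denominator, so the estimate is unbiased under symmetric ambiguity.
#'
#' @param x a \code{DNAbin} object, a character vector of sequences (either
#'   one string per sequence or one base per element), or a list of such
#'   vectors.
#' @return the G+C content in percent, full precision (round for reporting
#'   with [round_gc()]).
#' @examples
#' gc_content("ATGC")      # 50
#' gc_content("ATGCNNNN")  # 50, N excluded
#' @export
gc_content <- function(x) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  if (!inherits(x, "DNAbin")) {
    if (is.character(x)) {
      if (all(nchar(x) == 1)) x <- list(x)
      else x <- lapply(x, function(s) strsplit(tolower(s), "")[[1]])
    }
    if (!is.list(x)) stop("cannot interpret input as sequences",
                          call. = FALSE)
    x <- ape::as.DNAbin(lapply(x, tolower))
  }
  if (length(x) == 0) stop("empty input", call. = FALSE)
  cnt <- ape::base.freq(x, freq = TRUE, all = TRUE)
  num <- sum(cnt[c("c", "g", "s")])
  den <- sum(cnt[c("a", "c", "g", "t", "s", "w")])
  if (den == 0) stop("no unambiguous bases in input", call. = FALSE)
  100 * num / den
}

#' G+C content from a FASTA file
#'
#' @param path path to a nucleotide FASTA file; all records are pooled.
#' @return the G+C content in percent (full precision).
#' @export
gc_from_fasta <- function(path) {
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0) stop("no sequences in ", path, call. = FALSE)
  gc_content(seqs)
}

#' Round a G+C value to one decimal place
#'
#' Reported and compared G+C values are rounded to a single decimal place
#' (half away from zero) to accommodate incompletely sequenced genomes.
#'
#' @param x numeric G+C value(s) in percent.
#' @return the rounded value(s).
#' @export
round_gc <- function(x) round_half_up(x, 1)

#' Parse published G+C values
#'
#' Accepts a point value (\code{"41"}, \code{"41.2"}), a range with hyphen
#' or en-dash (\code{"40-42"}, \code{"40–42"}, spaces allowed), or an
#' empty/missing entry.
#'
#' @param x character vector of published G+C strings.
#' @return a data frame with columns \code{lo} and \code{hi} (both
#'   \code{NA} when absent; equal for point values).
#' @export
parse_gc_published <- function(x) {
  x <- as.character(x)
  lo <- hi <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    s <- trimws(x[i])
    if (is.na(s) || !nzchar(s)) next
    s <- gsub("–", "-", s)
    if (grepl("^[0-9.]+$", s)) {
      lo[i] <- hi[i] <- as.numeric(s)
    } else if (grepl("^[0-9.]+\\s*-\\s*[0-9.]+$", s)) {
      parts <- as.numeric(strsplit(s, "\\s*-\\s*")[[1]])
      lo[i] <- parts[1]; hi[i] <- parts[2]
    } else {
      stop("malformed published G+C value: '", x[i], "'", call. = FALSE)
    }
    if (lo[i] > hi[i])
      stop("malformed range (lo > hi): '", x[i], "'", call. = FALSE)
    if (lo[i] < 0 || hi[i] > 100)
      stop("published G+C outside [0, 100]: '", x[i], "'", call. = FALSE)
  }
  data.frame(lo = lo, hi = hi)
}

#' Classify one species description against its genomic G+C
#'
#' Implements the 1 percent rule with four mutually exclusive categories,
#' checked in order of precedence: \code{missing} (no published value),
#' \code{deviating} (point value more than \code{tolerance} from the
#' genomic value, or genomic value more than \code{tolerance} outside the
#' published range), \code{restricted} (range wider than \code{max_range}),
#' else \code{confirmed}. Comparisons use the genomic value rounded to one
#' decimal place. A range that is both too broad and inaccurate is reported
#' as deviating.
#'
#' @param lo,hi published bounds (equal for a point value; \code{NA} when
#'   absent).
#' @param genomic genome-derived G+C (percent, full precision accepted).
#' @param tolerance maximal accepted deviation (percentage points,
#'   default 1).
#' @param max_range maximal realistic width of a published range
#'   (percentage points, default 1).
#' @return the category as a character scalar.
#' @export
classify_gc <- function(lo, hi, genomic, tolerance = 1, max_range = 1) {
  g <- round_gc(genomic)
  if (is.na(lo)) return("missing")
  if (is.na(hi) || lo > hi) stop("malformed range", call. = FALSE)
  if (lo - g > tolerance || g - hi > tolerance) return("deviating")
  if (hi - lo > max_range) return("restricted")
  "confirmed"
}

#' Audit a table of published G+C values against genomic values
#'
#' Applies [classify_gc()] to every species, tallies the four categories,
#' and emits machine-readable emendation stubs for every non-confirmed
#' species. Callers are expected to supply, per species, only the most
#' recent emendation that included a G+C value.
#'
#' @param records a data frame with columns \code{species},
#'   \code{published} (string, see [parse_gc_published()]) and
#'   \code{genomic} (percent); alternatively \code{lo}/\code{hi} columns in
#'   place of \code{published}. An optional \code{citation} column is
#'   carried through.
#' @param tolerance,max_range see [classify_gc()].
#' @return an object of class \code{gc_audit}: a list with \code{counts}
#'   (named vector over confirmed/restricted/deviating/missing) and
#'   \code{results} (per-species data frame, species-sorted, with category,
#'   deviation magnitude and emendation stub).
#' @export
audit_gc <- function(records, tolerance = 1, max_range = 1) {
  records <- as.data.frame(records)
  if (anyDuplicated(records$species))
    stop("duplicate species: ",
         paste(unique(records$species[duplicated(records$species)]),
               collapse = ", "), call. = FALSE)
  if (!all(c("lo", "hi") %in% names(records))) {
    pb <- parse_gc_published(records$published)
    records$lo <- pb$lo; records$hi <- pb$hi
  }
  records <- records[order(records$species), , drop = FALSE]
  n <- nrow(records)
  category <- character(n)
  deviation <- rep(NA_real_, n)
  stub <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    g <- round_gc(records$genomic[i])
    category[i] <- classify_gc(records$lo[i], records$hi[i],
                               records$genomic[i], tolerance, max_range)
    if (!is.na(records$lo[i]))
      deviation[i] <- max(0, records$lo[i] - g, g - records$hi[i])
    if (category[i] != "confirmed")
      stub[i] <- sprintf(
        "The genomic G+C content of the type strain is %s%%.",
        format(g, nsmall = 1))
  }
  published <- ifelse(is.na(records$lo), "",
                      ifelse(records$lo == records$hi,
                             format(records$lo),
                             paste0(format(records$lo), "-",
                                    format(records$hi))))
  results <- data.frame(
    species = records$species, category = category, published = published,
    genomic = records$genomic, genomic_rounded = round_gc(records$genomic),
    deviation = deviation, stub = stub, stringsAsFactors = FALSE)
  if ("citation" %in% names(records)) results$citation <- records$citation
  rownames(results) <- NULL
  counts <- vapply(c("confirmed", "restricted", "deviating", "missing"),
                   function(k) sum(category == k), integer(1))
  structure(list(counts = counts, results = results,
                 tolerance = tolerance, max_range = max_range),
            class = "gc_audit")
}

#' @export
print.gc_audit <- function(x, ...) {
  cat("G+C content audit (tolerance ", x$tolerance, ", max range ",
      x$max_range, " percentage points)\n", sep = "")
  cat(sprintf("  %-10s %d\n", names(x$counts), x$counts), sep = "")
  invisible(x)
}

#' Read a published-G+C table
#'
#' Tab-separated file with header columns \code{species},
#' \code{published_gc} (point, range, or empty) and optionally
#' \code{genomic_gc} and \code{citation}.
#'
#' @param path file path.
#' @return a data frame with columns \code{species}, \code{published},
#'   \code{genomic} (if present) and \code{citation} (if present).
#' @export
read_gc_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = "NA",
                          colClasses = NA)
  if (!all(c("species", "published_gc") %in% names(df)))
    stop("expected columns 'species' and 'published_gc'", call. = FALSE)
  out <- data.frame(species = df$species,
                    published = as.character(df$published_gc),
                    stringsAsFactors = FALSE)
  if ("genomic_gc" %in% names(df)) out$genomic <- as.numeric(df$genomic_gc)
  if ("citation" %in% names(df)) out$citation <- df$citation
  out
}
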