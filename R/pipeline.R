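#' Pipeline run configuration
#'
#' Collects the input paths and parameters of the audit pipeline stages.
#' Stages communicate only via files under \code{outdir}, so any stage can
#' also consume externally produced inputs (e.g. a tree from another
#' program).
#'
#' @param hits path to BLAST tabular hit file(s).
#' @param tree path to a Newick tree (defaults to the support-annotated
#'   tree written by [run_distances()]).
#' @param replicate_trees path to a multi-line Newick file of replicate
#'   trees (defaults to the file written by [run_distances()]).
#' @param taxonomy path to a taxonomy TSV (see [read_taxon_map()]).
#' @param gc_table path to a published/genomic G+C TSV (see
#'   [read_gc_table()]).
#' @param genomes_dir directory of per-species FASTA files
#'   (\code{<species>.fasta}), used when \code{gc_table} lacks a
#'   \code{genomic_gc} column.
#' @param evalue e-value filter threshold.
#' @param bootstraps number of pseudo-bootstrap replicates.
#' @param seed integer seed.
#' @param tolerance,max_range G+C audit parameters, see [classify_gc()].
#' @param variants range variants for the fit test: subset of
#'   \code{c("min", "avg", "max", "range")}.
#' @param method tree-building method, see [gbdp_tree()].
#' @param outdir output directory.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(hits = NULL, tree = NULL, replicate_trees = NULL,
                       taxonomy = NULL, gc_table = NULL,
                       genomes_dir = NULL, evalue = 1e-8,
                       bootstraps = 100, seed = 1, tolerance = 1,
                       max_range = 1, variants = c("min", "avg", "max"),
                       method = "nj", outdir = ".") {
  stopifnot(bootstraps >= 0)
  structure(list(hits = hits, tree = tree,
                 replicate_trees = replicate_trees, taxonomy = taxonomy,
                 gc_table = gc_table, genomes_dir = genomes_dir,
                 evalue = evalue, bootstraps = bootstraps, seed = seed,
                 tolerance = tolerance, max_range = max_range,
                 variants = variants, method = method, outdir = outdir),
            class = "run_config")
}

log_lines <- function(config, stage, lines) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$outdir, paste0(stage, ".log"))
  writeLines(lines, path)
  invisible(path)
}

# run an expression collecting every warning message once
collect_warnings <- function(expr) {
  msgs <- character()
  val <- withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = msgs)
}

#' Stage 1: distances, trees and support
#'
#' Reads the hit table, applies the e-value filter and greedy trimming,
#' computes the d5 distance matrix and its pseudo-bootstrap replicates,
#' builds the main and replicate trees, and maps replicate support onto the
#' main tree. Writes \code{gbdp_distances.phy}, per-replicate matrices are
#' not retained; \code{main_tree.nwk}, \code{replicate_trees.nwk} and a log
#' recording seed, counts and any data-downgrading warnings.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the support-annotated main tree, the
#'   replicate trees and the distance matrix.
#' @export
run_distances <- function(config) {
  if (is.null(config$hits) || !all(file.exists(config$hits)))
    stop("hit table not found: ", paste(config$hits, collapse = ", "),
         call. = FALSE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_blast_tab(config$hits)
  n_raw <- nrow(tab)
  tab <- filter_evalue(tab, config$evalue)
  tab <- trim_hsp_table(tab)
  res <- collect_warnings({
    m <- gbdp_distance_matrix(tab, trim = FALSE)
    boots <- bootstrap_matrices(tab, replicates = config$bootstraps,
                                seed = config$seed)
    main <- gbdp_tree(m, method = config$method)
    reps <- lapply(boots, gbdp_tree, method = config$method)
    list(m = m, main = main, reps = reps)
  })
  m <- res$value$m; main <- res$value$main; reps <- res$value$reps
  if (length(reps)) main <- map_support(main, reps)
  write_phylip(m, file.path(config$outdir, "gbdp_distances.phy"))
  write_support_tree(main, file.path(config$outdir, "main_tree.nwk"))
  if (length(reps))
    writeLines(vapply(reps, write_support_tree, character(1)),
               file.path(config$outdir, "replicate_trees.nwk"))
  log_lines(config, "distances", c(
    sprintf("seed: %d", config$seed),
    sprintf("hsps read: %d", n_raw),
    sprintf("hsps after e-value filter (%g): %d", config$evalue,
            nrow(tab)),
    sprintf("genomes: %d", nrow(m)),
    sprintf("bootstrap replicates: %d", config$bootstraps),
    if (length(res$warnings)) paste("warning:", unique(res$warnings))
    else "no warnings"))
  invisible(list(tree = main, replicates = reps, matrix = m))
}

#' Stage 2: per-taxon monophyly report
#'
#' Classifies every taxon of the taxonomy table on the (rooted) main tree
#' and writes a report TSV with one row per taxon: status and signed
#' support (negative values are support against a non-monophyletic taxon).
#'
#' @param config a [run_config()]; uses \code{config$tree} or the tree
#'   written by [run_distances()]. Unrooted input trees are rooted at
#'   their first tip with a warning.
#' @return (invisibly) the report data frame.
#' @export
run_taxonomy_report <- function(config) {
  tree_path <- config$tree %||% file.path(config$outdir, "main_tree.nwk")
  if (!file.exists(tree_path))
    stop("tree file not found: ", tree_path, call. = FALSE)
  if (is.null(config$taxonomy) || !file.exists(config$taxonomy))
    stop("taxonomy file not found: ", config$taxonomy %||% "<unset>",
         call. = FALSE)
  tr <- read_support_tree(tree_path)
  if (!ape::is.rooted(tr)) {
    warning("input tree is unrooted; rooting at its first tip",
            call. = FALSE)
    tr <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE,
                    edgelabel = TRUE)
  }
  tax <- read_taxon_map(config$taxonomy)
  report <- classify_taxa(tr, tax)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report,
                     file.path(config$outdir, "taxonomy_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  log_lines(config, "taxonomy", c(
    sprintf("tree: %s", tree_path),
    sprintf("taxa classified: %d", nrow(report)),
    sprintf("non-monophyletic: %d",
            sum(report$status %in% c("paraphyletic", "polyphyletic")))))
  invisible(report)
}

#' Stage 3: G+C content audit
#'
#' Audits published G+C values against genomic values under the 1 percent
#' rule and writes the per-species audit TSV (with emendation stubs) and a
#' category-count summary.
#'
#' @param config a [run_config()]; genomic values are taken from the
#'   \code{genomic_gc} column of the G+C table or computed from
#'   \code{genomes_dir}.
#' @return (invisibly) the [audit_gc()] result.
#' @export
run_gc_audit <- function(config) {
  if (is.null(config$gc_table) || !file.exists(config$gc_table))
    stop("G+C table not found: ", config$gc_table %||% "<unset>",
         call. = FALSE)
  records <- read_gc_table(config$gc_table)
  if (is.null(records$genomic)) {
    if (is.null(config$genomes_dir))
      stop("G+C table lacks genomic_gc and no genomes_dir given",
           call. = FALSE)
    records$genomic <- vapply(records$species, function(sp)
      gc_from_fasta(file.path(config$genomes_dir,
                              paste0(sp, ".fasta"))), numeric(1))
  }
  audit <- audit_gc(records, tolerance = config$tolerance,
                    max_range = config$max_range)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(audit$results,
                     file.path(config$outdir, "gc_audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  utils::write.table(
    data.frame(category = names(audit$counts), count = audit$counts),
    file.path(config$outdir, "gc_audit_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines(config, "gc_audit", c(
    sprintf("species audited: %d", nrow(audit$results)),
    sprintf("%s: %d", names(audit$counts), audit$counts)))
  invisible(audit)
}

#' Stage 4: continuous-character fit test
#'
#' Scores published and genomic G+C values on every replicate tree under
#' Farris-interval parsimony, for each requested range variant, and writes
#' the per-replicate score table plus a JSON summary of means and test
#' statistics.
#'
#' @param config a [run_config()]; uses \code{config$replicate_trees} or
#'   the file written by [run_distances()], and the G+C table (tips =
#'   species names).
#' @return (invisibly) a named list of [compare_fit()] results, one per
#'   variant.
#' @export
run_fit_test <- function(config) {
  rep_path <- config$replicate_trees %||%
    file.path(config$outdir, "replicate_trees.nwk")
  if (!file.exists(rep_path))
    stop("replicate tree file not found: ", rep_path, call. = FALSE)
  if (is.null(config$gc_table) || !file.exists(config$gc_table))
    stop("G+C table not found: ", config$gc_table %||% "<unset>",
         call. = FALSE)
  reps <- read_support_tree(rep_path)
  if (inherits(reps, "phylo")) reps <- list(reps)
  records <- read_gc_table(config$gc_table)
  if (is.null(records$genomic))
    stop("fit test needs a genomic_gc column in the G+C table",
         call. = FALSE)
  pb <- parse_gc_published(records$published)
  keep <- !is.na(pb$lo)
  published <- leaf_values(records$species[keep], pb$lo[keep],
                           pb$hi[keep])
  genomic <- leaf_values(records$species, records$genomic)
  out <- list()
  rows <- list()
  for (v in config$variants) {
    variant <- if (v == "range") "pub-as-range" else paste0("pub-", v)
    fc <- compare_fit(reps, published, genomic, variant = variant)
    out[[variant]] <- fc
    rows[[variant]] <- cbind(variant = variant, fc$table)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(do.call(rbind, rows),
                     file.path(config$outdir, "fit_test.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- lapply(out, function(fc) list(
    mean_difference = fc$mean_difference,
    mean_score_published = mean(fc$table$score_published),
    mean_score_genomic = mean(fc$table$score_genomic),
    t_statistic = fc$t_statistic, t_p = fc$t_p,
    wilcoxon_statistic = fc$wilcoxon_statistic,
    wilcoxon_p = fc$wilcoxon_p))
  jsonlite::write_json(summary,
                       file.path(config$outdir, "fit_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  log_lines(config, "fit_test", c(
    sprintf("replicate trees: %d", length(reps)),
    sprintf("variants: %s", paste(config$variants, collapse = ", "))))
  invisible(out)
}

#' Run every pipeline stage
#'
#' @param config a [run_config()] naming hits, taxonomy and G+C table.
#' @return (invisibly) a list of the stage results.
#' @export
run_all <- function(config) {
  d <- run_distances(config)
  t <- run_taxonomy_report(config)
  g <- run_gc_audit(config)
  f <- run_fit_test(config)
  invisible(list(distances = d, taxonomy = t, gc_audit = g,
                 fit_test = f))
}
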