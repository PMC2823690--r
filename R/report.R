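## Report building and the file-backed relational store. The store is a
## directory holding one TSV per schema table plus a manifest; foreign
## keys are checked on write and on load, and a persisted run reloads
## equal to the tables it was built from.

REL_TABLES <- c("ests", "contigs", "membership", "hits", "best_hits",
                "protein_ids", "go_terms", "go_edges",
                "annotations_direct", "annotations_propagated",
                "enrichment", "links", "expression")

#' Build the publication-style report bundle from run artifacts
#'
#' Emits whichever reports the completed stages support: the processing
#' flowchart counts, assembly redundancy statistics, the full-length
#' cumulative table, the gene-family abundance table (contigs grouped by
#' best-hit description), the taxon distribution, GO domain counts, the
#' enrichment table, the cross-species link summary and the expression
#' table. A preprocessing-only run yields only the flowchart.
#'
#' @param artifacts a named list of run artifacts, e.g. from
#'   \code{\link{runPipeline}}: any of \code{preprocess},
#'   \code{contigs}, \code{assembly_stats}, \code{best_hits},
#'   \code{full_length}, \code{taxa}, \code{go_summary},
#'   \code{enrichment}, \code{links}, \code{link_coverage},
#'   \code{expression}.
#' @return named list of \code{data.frame}s.
#' @export
buildReports <- function(artifacts) {
  out <- list()
  if (!is.null(artifacts$preprocess))
    out$flowchart <- artifacts$preprocess$counts
  if (!is.null(artifacts$assembly_stats))
    out$assembly <- artifacts$assembly_stats
  if (!is.null(artifacts$full_length))
    out$full_length <- artifacts$full_length$table
  if (!is.null(artifacts$best_hits) && !is.null(artifacts$contigs))
    out$abundance <- abundanceTable(artifacts$contigs,
                                    artifacts$best_hits)
  if (!is.null(artifacts$taxa)) out$taxa <- artifacts$taxa
  if (!is.null(artifacts$go_summary))
    out$go_domains <- artifacts$go_summary$domains
  if (!is.null(artifacts$enrichment)) out$enrichment <- artifacts$enrichment
  if (!is.null(artifacts$links)) {
    cov <- artifacts$link_coverage
    routes <- split(artifacts$links, artifacts$links$route)
    out$link_summary <- do.call(rbind, lapply(names(routes), function(r) {
      l <- routes[[r]]
      data.frame(route = r, n_links = nrow(l),
                 n_distinct_newt = length(unique(l$newt_id)),
                 n_distinct_comparator = length(unique(l$comparator_id)),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(cov)) {
      out$link_summary <- rbind(out$link_summary,
        data.frame(route = "union", n_links = NA_integer_,
                   n_distinct_newt = NA_integer_,
                   n_distinct_comparator = cov$n_covered))
    }
  }
  if (!is.null(artifacts$expression)) out$expression <- artifacts$expression
  out
}

#' Gene-family abundance table
#'
#' Groups contigs by the subject description of their best hit (contigs
#' sharing a description form one family row), aggregates their EST
#' counts, and reports the percentage of all assembled ESTs.
#'
#' @param contigs a \link{ContigSet}.
#' @param best_hits best-hit table (one row per contig with a hit).
#' @return \code{data.frame}: \code{family}, \code{n_ests},
#'   \code{n_contigs}, \code{abundance_pct}, sorted by decreasing EST
#'   count.
#' @export
abundanceTable <- function(contigs, best_hits) {
  counts <- estsPerContig(contigs)
  n_total <- sum(counts)
  fam <- best_hits$subject_description[
    match(names(counts), best_hits$qseqid)]
  keep <- !is.na(fam)
  agg <- tapply(counts[keep], fam[keep], sum)
  ncontig <- tapply(counts[keep], fam[keep], length)
  out <- data.frame(family = names(agg), n_ests = as.integer(agg),
                    n_contigs = as.integer(ncontig),
                    abundance_pct = 100 * as.numeric(agg) / n_total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_ests, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a report bundle as TSV files
#'
#' @param reports result of \code{\link{buildReports}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(reports), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(reports[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

## Relational view of run artifacts: a named list of data.frames in the
## fixed schema, with empty tables for stages that did not run.
relationalTables <- function(artifacts) {
  empty <- function(...) {
    cols <- list(...)
    as.data.frame(stats::setNames(lapply(cols, function(t)
      vector(t, 0L)), names(cols)), stringsAsFactors = FALSE)
  }
  tabs <- list(
    ests = empty(est_id = "character", sequence = "character",
                 clip_5 = "integer", clip_3 = "integer",
                 had_polya = "logical"),
    contigs = empty(contig_id = "character", consensus = "character"),
    membership = empty(contig_id = "character", est_id = "character",
                       offset = "integer", strand = "character",
                       width = "integer"),
    hits = emptyHitTable(), best_hits = emptyHitTable(),
    protein_ids = empty(query_id = "character", rank = "integer",
                        protein_id = "character"),
    go_terms = empty(id = "character", name = "character",
                     namespace = "character"),
    go_edges = empty(child = "character", parent = "character"),
    annotations_direct = empty(go_id = "character",
                               protein_id = "character"),
    annotations_propagated = empty(go_id = "character",
                                   protein_id = "character"),
    enrichment = empty(term = "character", k_ds = "integer",
                       N_ds = "integer", k_base = "integer",
                       N_base = "integer", fold = "numeric",
                       chi2 = "numeric", p_value = "numeric",
                       enriched = "logical"),
    links = empty(newt_id = "character", comparator_id = "character",
                  route = "character", evidence = "character"),
    expression = empty(gene = "character", timepoint = "numeric",
                       fold = "numeric", sd = "numeric",
                       p_value = "numeric", flagged_2fold = "logical",
                       significant = "logical"))
  if (!is.null(artifacts$preprocess)) {
    e <- artifacts$preprocess$ests
    mc <- S4Vectors::mcols(e)
    tabs$ests <- data.frame(est_id = names(e),
                            sequence = as.character(e),
                            clip_5 = mc$clip_5, clip_3 = mc$clip_3,
                            had_polya = mc$had_polya,
                            stringsAsFactors = FALSE)
  }
  if (!is.null(artifacts$contigs)) {
    cs <- artifacts$contigs
    tabs$contigs <- data.frame(contig_id = names(consensusSeqs(cs)),
                               consensus = as.character(consensusSeqs(cs)),
                               stringsAsFactors = FALSE)
    tabs$membership <- contigMembers(cs)
  }
  if (!is.null(artifacts$hits)) tabs$hits <- artifacts$hits[, HIT_COLUMNS]
  if (!is.null(artifacts$best_hits))
    tabs$best_hits <- artifacts$best_hits[, HIT_COLUMNS]
  if (!is.null(artifacts$protein_ids)) {
    pid <- artifacts$protein_ids
    tabs$protein_ids <- do.call(rbind, c(list(tabs$protein_ids),
      lapply(names(pid), function(q)
        data.frame(query_id = q, rank = seq_along(pid[[q]]),
                   protein_id = pid[[q]], stringsAsFactors = FALSE))))
  }
  if (!is.null(artifacts$dag)) {
    dag <- artifacts$dag
    tabs$go_terms <- goTerms(dag)
    ps <- goParents(dag)
    tabs$go_edges <- do.call(rbind, c(list(tabs$go_edges),
      lapply(names(ps), function(id) if (length(ps[[id]]))
        data.frame(child = id, parent = ps[[id]],
                   stringsAsFactors = FALSE))))
  }
  flat <- function(m) do.call(rbind, c(
    list(empty(go_id = "character", protein_id = "character")),
    lapply(names(m), function(t) if (length(m[[t]]))
      data.frame(go_id = t, protein_id = sort(m[[t]]),
                 stringsAsFactors = FALSE))))
  if (!is.null(artifacts$annotation)) {
    tabs$annotations_direct <- flat(artifacts$annotation@direct)
    tabs$annotations_propagated <- flat(artifacts$annotation@propagated)
  }
  if (!is.null(artifacts$enrichment)) {
    en <- artifacts$enrichment
    tabs$enrichment <- data.frame(term = en$term, k_ds = en$k_ds,
                                  N_ds = en$N_ds, k_base = en$k_base,
                                  N_base = en$N_base, fold = en$fold,
                                  chi2 = en$chi2, p_value = en$p_value,
                                  enriched = en$enriched,
                                  stringsAsFactors = FALSE)
  }
  if (!is.null(artifacts$links))
    tabs$links <- artifacts$links[, c("newt_id", "comparator_id",
                                      "route", "evidence")]
  if (!is.null(artifacts$expression)) {
    ex <- artifacts$expression
    tabs$expression <- data.frame(gene = ex$gene, timepoint = ex$timepoint,
                                  fold = ex$fold, sd = ex$sd,
                                  p_value = ex$p_value,
                                  flagged_2fold = ex$flagged_2fold,
                                  significant = ex$significant,
                                  stringsAsFactors = FALSE)
  }
  for (nm in names(tabs)) rownames(tabs[[nm]]) <- NULL
  tabs
}

checkIntegrity <- function(tabs) {
  fail <- function(msg, rows) {
    stop("relational integrity violation: ", msg, " (rows ",
         paste(utils::head(rows, 10), collapse = ", "), ")", call. = FALSE)
  }
  dup <- function(x) which(duplicated(x))
  if (length(d <- dup(tabs$ests$est_id))) fail("duplicate est_id", d)
  if (length(d <- dup(tabs$contigs$contig_id)))
    fail("duplicate contig_id", d)
  if (length(d <- dup(tabs$go_terms$id))) fail("duplicate go term id", d)
  m <- tabs$membership
  if (nrow(m)) {
    bad <- which(!m$contig_id %in% tabs$contigs$contig_id)
    if (length(bad)) fail("membership references unknown contig", bad)
    if (nrow(tabs$ests)) {
      bad <- which(!m$est_id %in% tabs$ests$est_id)
      if (length(bad)) fail("membership references unknown est", bad)
    }
    if (length(d <- dup(m$est_id))) fail("est assembled twice", d)
  }
  if (nrow(tabs$go_edges)) {
    bad <- which(!(tabs$go_edges$child %in% tabs$go_terms$id &
                   tabs$go_edges$parent %in% tabs$go_terms$id))
    if (length(bad)) fail("go edge references unknown term", bad)
  }
  for (nm in c("annotations_direct", "annotations_propagated")) {
    a <- tabs[[nm]]
    if (nrow(a) && nrow(tabs$go_terms)) {
      bad <- which(!a$go_id %in% tabs$go_terms$id)
      if (length(bad)) fail(paste(nm, "references unknown term"), bad)
    }
  }
  if (nrow(tabs$enrichment) && nrow(tabs$go_terms)) {
    bad <- which(!tabs$enrichment$term %in% tabs$go_terms$id)
    if (length(bad)) fail("enrichment references unknown term", bad)
  }
  invisible(TRUE)
}

#' Persist run artifacts in the file-backed relational store
#'
#' Writes one TSV per schema table into the store directory after
#' checking referential integrity; a constraint violation aborts with
#' the offending rows. The persisted store reloads (via
#' \code{\link{loadRelational}}) equal to the relational view of the
#' artifacts.
#'
#' @param artifacts run artifacts (see \code{\link{buildReports}}).
#' @param store path of the store directory.
#' @return invisibly, the list of tables written.
#' @export
persistRelational <- function(artifacts, store) {
  tabs <- relationalTables(artifacts)
  checkIntegrity(tabs)
  dir.create(store, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("regenEST-relational-store", "schema_version: 1"),
             file.path(store, "MANIFEST"))
  for (nm in REL_TABLES) {
    utils::write.table(tabs[[nm]], file.path(store, paste0(nm, ".tsv")),
                       sep = "\t", quote = TRUE, row.names = FALSE)
  }
  invisible(tabs)
}

#' Load a persisted relational store
#'
#' @param store path of the store directory.
#' @return named list of \code{data.frame}s (one per schema table),
#'   integrity-checked.
#' @export
loadRelational <- function(store) {
  mf <- file.path(store, "MANIFEST")
  if (!file.exists(mf) ||
      readLines(mf, n = 1L) != "regenEST-relational-store")
    stop("not a relational store: ", store, call. = FALSE)
  tabs <- stats::setNames(lapply(REL_TABLES, function(nm) {
    utils::read.table(file.path(store, paste0(nm, ".tsv")), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE,
                      quote = "\"", comment.char = "",
                      colClasses = NA)
  }), REL_TABLES)
  ## restore empty-table column types lost by read.table
  template <- relationalTables(list())
  for (nm in REL_TABLES) {
    if (!nrow(tabs[[nm]])) tabs[[nm]] <- template[[nm]]
    else {
      for (cl in names(template[[nm]])) {
        target <- class(template[[nm]][[cl]])[1]
        tabs[[nm]][[cl]] <- methods::as(tabs[[nm]][[cl]], target)
      }
    }
  }
  checkIntegrity(tabs)
  tabs
}
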