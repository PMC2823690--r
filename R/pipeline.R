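## End-to-end orchestration on synthetic data: every stage of the EST
## analysis exercised against a clone library with known ground truth.
## All thresholds live in one configuration object.

#' Pipeline configuration: every threshold in one place
#'
#' @param e_weak,e_sig similarity class cutoffs (weak: e <= e_weak,
#'   significant: e < e_sig).
#' @param go_e_cutoff,sigma_cutoff,top_k_hits identifier-assignment
#'   gates.
#' @param start_window_aa full-length alignment start window.
#' @param min_len_nt minimum insert length.
#' @param min_orf_aa,long_orf_aa ORF length thresholds.
#' @param fold_threshold,min_counts enrichment screen.
#' @param alpha,fold_cut expression significance level and fold flag.
#' @param timepoints RT-PCR sampling days.
#' @param seed master seed; all stage seeds derive from it.
#' @return a \code{list} of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(e_weak = 1e-05, e_sig = 1e-20,
                           go_e_cutoff = 1e-20, sigma_cutoff = 15,
                           start_window_aa = 10L, min_len_nt = 100L,
                           min_orf_aa = 22L, long_orf_aa = 150L,
                           top_k_hits = 50L, fold_threshold = 10,
                           min_counts = c(8L, 3L), alpha = 0.05,
                           fold_cut = 2.0,
                           timepoints = c(0L, 4L, 7L, 14L, 21L),
                           seed = 1L) {
  if (e_sig >= e_weak) stop("e_sig must be < e_weak", call. = FALSE)
  stopifnot(all(c(go_e_cutoff, sigma_cutoff, start_window_aa, min_len_nt,
                  min_orf_aa, long_orf_aa, top_k_hits, fold_threshold,
                  alpha, fold_cut) > 0))
  structure(list(e_weak = e_weak, e_sig = e_sig,
                 go_e_cutoff = go_e_cutoff, sigma_cutoff = sigma_cutoff,
                 start_window_aa = as.integer(start_window_aa),
                 min_len_nt = as.integer(min_len_nt),
                 min_orf_aa = as.integer(min_orf_aa),
                 long_orf_aa = as.integer(long_orf_aa),
                 top_k_hits = as.integer(top_k_hits),
                 fold_threshold = fold_threshold,
                 min_counts = as.integer(min_counts),
                 alpha = alpha, fold_cut = fold_cut,
                 timepoints = as.integer(timepoints),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full EST pipeline on a simulated clone library
#'
#' Simulates a transcript pool and clone reads, preprocesses and
#' assembles them, attaches truth-driven homology hit tables, assigns
#' protein identifiers and GO terms, computes fold-accumulation
#' enrichment against the synthetic baseline corpus, maps homologs to a
#' simulated comparator dataset, and analyses a planted densitometry
#' table. Deterministic for a fixed configuration seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param n_transcripts,n_reads library size of the simulation.
#' @param error_rate per-base substitution error rate of the reads.
#' @return a named list of artifacts: \code{truth},
#'   \code{preprocess}, \code{contigs}, \code{assembly_stats},
#'   \code{hits}, \code{best_hits}, \code{similarity}, \code{taxa},
#'   \code{protein_ids}, \code{dag}, \code{annotation},
#'   \code{go_summary}, \code{full_length}, \code{orfs},
#'   \code{enrichment}, \code{links}, \code{link_coverage},
#'   \code{expression}, \code{config}.
#' @export
runPipeline <- function(config = pipelineConfig(), n_transcripts = 60L,
                        n_reads = 500L, error_rate = 0.005) {
  seed <- config$seed
  ## 1) clone library
  tx <- makeTranscriptome(transcriptomeSpec(
    n_transcripts = n_transcripts, length_min = 300L, length_max = 900L,
    abundance_skew = 1.2, seed = childSeed(seed, 1L)))
  sim <- makeReads(tx, cloneSimSpec(
    n_reads = n_reads, error_rate = error_rate,
    insert_len_mean = 500, insert_len_sd = 120,
    seed = childSeed(seed, 2L)))
  ## 2) cleanup + assembly
  pre <- runPreprocess(sim$reads,
                       preprocessConfig(min_len = config$min_len_nt))
  contigs <- greedyAssemble(pre$ests)
  stats <- contigStats(contigs)
  ## 3) GO world and transcript -> protein truth
  world <- makeGoWorld(n_terms_per_ns = 40L, depth = 4L,
                       n_proteins = 400L, seed = childSeed(seed, 3L))
  prot_pool <- unique(world$mapping$protein_id)
  tx_protein <- withSeed(childSeed(seed, 4L),
    stats::setNames(sample(prot_pool, n_transcripts, replace = TRUE),
                    names(tx$sequences)))
  taxon_of <- tapply(world$mapping$taxon_class, world$mapping$protein_id,
                     `[[`, 1L)
  ## 4) contig -> source transcript (majority member, via truth)
  ctg_tx <- contigTranscript(contigs, sim$truth)
  ctg_protein <- stats::setNames(tx_protein[ctg_tx], names(ctg_tx))
  ## 5) truth-driven hit tables
  hits <- makeHitTable(names(consensusSeqs(contigs)),
                       p_hit = 0.65, p_significant = 0.75,
                       n_hits_mean = 4, protein_pool = prot_pool,
                       taxa = taxon_of, algorithm = "blastx",
                       best_subjects = ctg_protein,
                       seed = childSeed(seed, 5L))
  sel <- selectBestHits(hits, config$top_k_hits)
  best <- sel$best
  similarity <- data.frame(
    contig_id = names(consensusSeqs(contigs)),
    best_evalue = best$evalue[match(names(consensusSeqs(contigs)),
                                    best$qseqid)],
    stringsAsFactors = FALSE)
  similarity$class <- classifySimilarity(similarity$best_evalue,
                                         config$e_weak, config$e_sig)
  taxa <- taxonDistribution(best)
  ## 6) identifiers + GO annotation of the dataset
  pids <- assignProteinIds(hits, goAssignConfig(
    e_cutoff = config$go_e_cutoff, sigma_cutoff = config$sigma_cutoff,
    top_k = config$top_k_hits))
  direct <- contigDirectAnnotation(pids, world$mapping)
  annotation <- propagateAnnotations(world$dag, direct)
  go_summary <- summaryCounts(annotation, world$dag, taxon_of)
  ## 7) full-length calls and ORFs of no-hit contigs
  hit_ok <- best$qseqid[best$evalue <= config$e_weak]
  polya <- stats::setNames(
    detectPolya(as.character(consensusSeqs(contigs))),
    names(consensusSeqs(contigs)))
  fl <- classifyFullLength(best[best$evalue <= config$e_weak &
                                best$algorithm == "blastx", ],
                           polya, config$start_window_aa)
  nohit <- setdiff(names(consensusSeqs(contigs)), hit_ok)
  orfs <- findOrfs(consensusSeqs(contigs)[nohit], config$min_orf_aa,
                   config$long_orf_aa)
  ## 8) enrichment of the dataset against the baseline corpus
  enr <- goEnrichment(annotation, world$baseline, world$dag,
                      filter = enrichFilter(config$min_counts,
                                            config$fold_threshold))
  ## 9) comparator species: planted direct hits + shared identifiers
  xs <- simulateComparator(contigs, ctg_protein, prot_pool,
                           seed = childSeed(seed, 6L))
  dlinks <- directMatch(xs$hit_table, config$e_weak,
                        xs$comparator_proteins)
  ilinks <- identifierMatch(
    contigProteinTable(pids), xs$comparator_proteins_long,
    exclude = dlinks)
  cov <- unionCoverage(dlinks, ilinks,
                       nrow(xs$comparator_proteins))
  ## 10) expression analysis with planted effects
  dens <- makeDensitometry(
    genes = c("rnf7", "sfrp1", "txnl4b", "tctp1"),
    timepoints = config$timepoints, n_pools = 3L,
    effects = list(rnf7 = c(1, 1.4, 1.8, 2.6, 3.1),
                   sfrp1 = c(1, 1.2, 1.6, 2.4, 2.8),
                   txnl4b = c(1, 1.3, 2.2, 2.5, 1.6),
                   tctp1 = c(1, 0.45, 0.6, 1.1, 1.3)),
    noise_sd = 0.08, seed = childSeed(seed, 7L))
  expr <- pairedTTestFlag(dens$table, dens$control_gene,
                          config$alpha, config$fold_cut)
  list(truth = list(reads = sim$truth, transcriptome = tx,
                    tx_protein = tx_protein, densitometry = dens$truth,
                    comparator = xs$truth),
       preprocess = pre, contigs = contigs, assembly_stats = stats,
       hits = hits, best_hits = best, similarity = similarity,
       taxa = taxa, protein_ids = pids, dag = world$dag,
       annotation = annotation, go_summary = go_summary,
       full_length = fl, orfs = orfs, enrichment = enr,
       links = {
         common <- intersect(names(dlinks), names(ilinks))
         rbind(dlinks[, common, drop = FALSE],
               ilinks[, common, drop = FALSE])
       },
       link_coverage = cov, expression = expr, config = config)
}

## majority source transcript per contig, from the read truth table
contigTranscript <- function(contigs, read_truth) {
  m <- contigMembers(contigs)
  tx <- read_truth$transcript_id[match(m$est_id, read_truth$read_id)]
  vapply(split(tx, m$contig_id), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_character_)
    names(sort(table(v), decreasing = TRUE))[[1L]]
  }, character(1))
}

## flatten query -> identifier list into (newt_id, protein_id)
contigProteinTable <- function(pids) {
  if (!length(pids))
    return(data.frame(newt_id = character(0), protein_id = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(names(pids), function(q)
    data.frame(newt_id = q, protein_id = pids[[q]],
               stringsAsFactors = FALSE)))
}

## Simulated comparator dataset: deregulated comparator sequences with
## protein identifiers, some of which overlap the dataset's proteins
## (shared-identifier route), plus a direct cross-species hit table for
## a planted subset of contigs.
simulateComparator <- function(contigs, ctg_protein, prot_pool,
                               n_comparator = 80L, p_direct = 0.25,
                               seed = 1L) {
  withSeed(seed, {
    ids <- sprintf("Z%04d", seq_len(n_comparator))
    ## half the comparator proteins drawn from the contig proteins
    ## (orthologs), half from the rest of the pool
    have <- unique(stats::na.omit(unname(ctg_protein)))
    n_shared <- min(length(have), n_comparator %/% 2L)
    prot <- c(sample(have, n_shared),
              sample(setdiff(prot_pool, have),
                     n_comparator - n_shared, replace = TRUE))
    prot <- sample(prot)   # shuffle assignment to ids
    cp <- data.frame(comparator_id = ids, protein_id = prot,
                     stringsAsFactors = FALSE)
    ## direct hits: contigs whose protein is shared hit their ortholog's
    ## comparator sequence with probability p_direct
    rows <- list()
    for (cid in names(ctg_protein)) {
      p <- ctg_protein[[cid]]
      if (is.na(p) || !p %in% prot) next
      if (stats::runif(1L) > p_direct) next
      z <- cp$comparator_id[match(p, cp$protein_id)]
      e <- 10^stats::runif(1L, -60, -6)
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = cid, sseqid = z, pident = round(stats::runif(1L, 70, 95), 2),
        length = 200L, mismatch = 10L, gapopen = 0L, qstart = 1L,
        qend = 200L, sstart = 1L, send = 200L, evalue = e,
        bitscore = round(-log10(e) * 2, 1), algorithm = "blastn",
        subject_description = z, taxon_class = "fish",
        stringsAsFactors = FALSE)
    }
    ht <- if (length(rows)) do.call(rbind, rows) else emptyHitTable()
    list(comparator_proteins = cp,
         comparator_proteins_long = cp,
         hit_table = ht,
         truth = list(n_shared_proteins = n_shared,
                      n_direct_links = nrow(ht)))
  })
}

## contig direct GO annotation: union of the GO terms of all assigned
## identifiers; proteins (not contigs) are the annotation unit, so the
## GAF rows keep the protein id
contigDirectAnnotation <- function(pids, mapping) {
  prots <- unique(unlist(pids, use.names = FALSE))
  mapping[mapping$protein_id %in% prots, , drop = FALSE]
}
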