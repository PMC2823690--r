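## Synthetic clone-library generator with complete ground truth. Emulates
## the statistical structure of a non-normalized cDNA library sequenced
## from its 5' end: a skewed transcript abundance distribution (a few very
## abundant families, many singletons), reads of the form
## 5'flank + insert + polyA + 3'flank, substitution sequencing errors,
## and contaminating empty-vector / short-insert / low-quality clones.

## Default cloning-vector flank sequences (fixed, vector-like, AT/GC mixed).
DEFAULT_FLANK5 <- "TGCAGGTCGACTCTAGAGGATCCCCGGGTACCGAGCTCGAATT"
DEFAULT_FLANK3 <- "GGATCCACTAGTTCTAGAGCGGCCGCCACCGCGG"

#' Specification of a synthetic transcript pool
#'
#' @param n_transcripts number of distinct transcripts.
#' @param length_min,length_max transcript length bounds in nt
#'   (\code{length_min >= 200}).
#' @param length_law \code{"uniform"} or \code{"lognormal"} (truncated to
#'   the bounds).
#' @param abundance_skew exponent of the Zipf-like discrete power law used
#'   for copy-number weights; 0 = uniform library, larger = more skewed.
#'   Default 1.2 reproduces the few-huge-contigs / mostly-singletons shape
#'   of a non-normalized library.
#' @param gc_fraction GC content of simulated transcripts.
#' @param seed integer seed.
#' @return a \code{list} of class \code{"TranscriptomeSpec"}.
#' @export
transcriptomeSpec <- function(n_transcripts = 100L, length_min = 300L,
                              length_max = 1500L, length_law = "uniform",
                              abundance_skew = 1.2, gc_fraction = 0.45,
                              seed = 1L) {
  stopifnotScalarCount(n_transcripts, "n_transcripts")
  if (length_min < 200L) stop("length_min must be >= 200 nt", call. = FALSE)
  if (length_max < length_min) stop("length_max < length_min", call. = FALSE)
  if (!length_law %in% c("uniform", "lognormal"))
    stop("unknown length_law: ", length_law, call. = FALSE)
  if (abundance_skew < 0) stop("abundance_skew must be >= 0", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0,1]", call. = FALSE)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 length_law = length_law,
                 abundance_skew = abundance_skew,
                 gc_fraction = gc_fraction, seed = as.integer(seed)),
            class = "TranscriptomeSpec")
}

#' Generate a synthetic transcript pool with abundance weights
#'
#' Deterministic for a fixed spec (including its seed). Abundance weights
#' follow a discrete power law \eqn{w_i \propto i^{-s}} over transcripts
#' ranked 1..n, normalized to sum to one.
#'
#' @param spec a \code{\link{transcriptomeSpec}}.
#' @return list with \code{sequences} (a named
#'   \link[Biostrings]{DNAStringSet}, ids \code{T0001}...) and
#'   \code{weights} (named numeric, sums to 1).
#' @export
makeTranscriptome <- function(spec) {
  stopifnot(inherits(spec, "TranscriptomeSpec"))
  withSeed(spec$seed, {
    n <- spec$n_transcripts
    lens <- switch(spec$length_law,
      uniform = sample(spec$length_min:spec$length_max, n, replace = TRUE),
      lognormal = {
        mu <- log(sqrt(as.numeric(spec$length_min) * spec$length_max))
        l <- round(stats::rlnorm(n, meanlog = mu, sdlog = 0.35))
        pmin(pmax(l, spec$length_min), spec$length_max)
      })
    seqs <- vapply(lens, randomDna, character(1), gc = spec$gc_fraction)
    ids <- sprintf("T%04d", seq_len(n))
    w <- seq_len(n)^(-spec$abundance_skew)
    w <- w / sum(w)
    list(sequences = stats::setNames(Biostrings::DNAStringSet(seqs), ids),
         weights = stats::setNames(w, ids))
  })
}

#' Specification of a synthetic clone / read simulation
#'
#' Reads are built as 5' flank + insert + polyA tail + 3' flank, with
#' per-base substitution errors; a configurable fraction of clones are
#' empty vectors (no insert), carry a short (<100 nt) insert, or produce a
#' low-quality trace. Inserts are 3'-anchored fragments of their source
#' transcript, as produced by oligo-dT primed cDNA synthesis.
#'
#' @param five_prime_flank,three_prime_flank vector flank sequences.
#' @param insert_len_mean,insert_len_sd normal law for good insert length
#'   (nt), truncated below at 120 nt and at the transcript length.
#' @param polya_min,polya_max uniform bounds of the polyA tail length.
#' @param error_rate per-base substitution probability, in [0, 0.2].
#' @param empty_vector_fraction,short_insert_fraction,low_quality_fraction
#'   clone category proportions; must sum to at most 1.
#' @param n_reads number of reads to simulate.
#' @param q_high,q_low Phred scores of the two-level quality model
#'   (high-quality and low-quality traces).
#' @param seed integer seed.
#' @return a \code{list} of class \code{"CloneSimSpec"}.
#' @export
cloneSimSpec <- function(five_prime_flank = DEFAULT_FLANK5,
                         three_prime_flank = DEFAULT_FLANK3,
                         insert_len_mean = 500, insert_len_sd = 120,
                         polya_min = 15L, polya_max = 30L,
                         error_rate = 0.01,
                         empty_vector_fraction = 0.10,
                         short_insert_fraction = 0.02,
                         low_quality_fraction = 0.03,
                         n_reads = 1000L,
                         q_high = 40L, q_low = 10L, seed = 1L) {
  fr <- c(empty_vector_fraction, short_insert_fraction, low_quality_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("category fractions must lie in [0,1] and sum to <= 1",
         call. = FALSE)
  if (error_rate < 0 || error_rate > 0.2)
    stop("error_rate must be in [0, 0.2]", call. = FALSE)
  if (!nzchar(five_prime_flank) || !nzchar(three_prime_flank))
    stop("vector flanks must be non-empty", call. = FALSE)
  if (polya_min < 1L || polya_max < polya_min)
    stop("invalid polyA length law", call. = FALSE)
  if (n_reads < 0L) stop("n_reads must be >= 0", call. = FALSE)
  structure(list(five_prime_flank = five_prime_flank,
                 three_prime_flank = three_prime_flank,
                 insert_len_mean = insert_len_mean,
                 insert_len_sd = insert_len_sd,
                 polya_min = as.integer(polya_min),
                 polya_max = as.integer(polya_max),
                 error_rate = error_rate,
                 empty_vector_fraction = empty_vector_fraction,
                 short_insert_fraction = short_insert_fraction,
                 low_quality_fraction = low_quality_fraction,
                 n_reads = as.integer(n_reads),
                 q_high = as.integer(q_high), q_low = as.integer(q_low),
                 seed = as.integer(seed)),
            class = "CloneSimSpec")
}

#' Simulate EST reads from a transcript pool, with ground truth
#'
#' Because the insert / polyA boundary is not identifiable when the
#' transcript itself ends in adenines, the truth table records the
#' canonical boundary: trailing A's of the insert are folded into the
#' tail, so the recorded insert end is the base before the maximal
#' terminal A-run.
#'
#' @param transcriptome result of \code{\link{makeTranscriptome}}.
#' @param spec a \code{\link{cloneSimSpec}}.
#' @return list with \code{reads} (a
#'   \link[Biostrings]{QualityScaledDNAStringSet}, Sanger Phred+33) and
#'   \code{truth}, a \code{data.frame} with one row per read: columns
#'   \code{read_id}, \code{category} (\code{good}/\code{empty}/
#'   \code{short}/\code{low_quality}), \code{transcript_id},
#'   \code{insert_start}/\code{insert_end} (1-based read coordinates of
#'   the insert, \code{NA} for empty clones), \code{t_start}/\code{t_end}
#'   (transcript coordinates) and \code{polya_len}.
#' @export
makeReads <- function(transcriptome, spec) {
  stopifnot(inherits(spec, "CloneSimSpec"))
  tseq <- as.character(transcriptome$sequences)
  w <- transcriptome$weights
  n <- spec$n_reads
  empty_truth <- data.frame(read_id = character(0), category = character(0),
                            transcript_id = character(0),
                            insert_start = integer(0), insert_end = integer(0),
                            t_start = integer(0), t_end = integer(0),
                            polya_len = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    qs <- Biostrings::PhredQuality(character(0))
    return(list(reads = Biostrings::QualityScaledDNAStringSet(
                  Biostrings::DNAStringSet(character(0)), qs),
                truth = empty_truth))
  }
  withSeed(spec$seed, {
    cat_p <- c(empty = spec$empty_vector_fraction,
               short = spec$short_insert_fraction,
               low_quality = spec$low_quality_fraction)
    cat_p <- c(cat_p, good = 1 - sum(cat_p))
    categories <- sample(names(cat_p), n, replace = TRUE, prob = cat_p)
    seqs <- character(n); quals <- character(n)
    truth <- vector("list", n)
    f5 <- spec$five_prime_flank; f3 <- spec$three_prime_flank
    for (i in seq_len(n)) {
      cat_i <- categories[[i]]
      rid <- sprintf("R%05d", i)
      if (cat_i == "empty") {
        raw <- paste0(f5, f3)
        truth[[i]] <- data.frame(read_id = rid, category = cat_i,
                                 transcript_id = NA_character_,
                                 insert_start = NA_integer_,
                                 insert_end = NA_integer_,
                                 t_start = NA_integer_, t_end = NA_integer_,
                                 polya_len = 0L, stringsAsFactors = FALSE)
      } else {
        tid <- sample(names(w), 1L, prob = w)
        tlen <- nchar(tseq[[tid]])
        ins_len <- if (cat_i == "short") {
          sample(20:95, 1L)
        } else {
          max(120L, min(tlen,
              as.integer(round(stats::rnorm(1L, spec$insert_len_mean,
                                            spec$insert_len_sd)))))
        }
        ins_len <- min(ins_len, tlen)
        t_end <- tlen
        t_start <- tlen - ins_len + 1L
        insert <- substr(tseq[[tid]], t_start, t_end)
        ## canonical boundary: fold trailing insert A's into the tail
        ins_chars <- strsplit(insert, "", fixed = TRUE)[[1L]]
        trail_a <- 0L
        while (ins_len - trail_a >= 1L &&
               ins_chars[ins_len - trail_a] == "A") trail_a <- trail_a + 1L
        t_end <- t_end - trail_a
        ins_len_c <- ins_len - trail_a
        polya <- sample(spec$polya_min:spec$polya_max, 1L) + trail_a
        raw <- paste0(f5, insert,
                      strrep("A", polya - trail_a), f3)
        truth[[i]] <- data.frame(read_id = rid, category = cat_i,
                                 transcript_id = tid,
                                 insert_start = nchar(f5) + 1L,
                                 insert_end = nchar(f5) + ins_len_c,
                                 t_start = t_start, t_end = t_end,
                                 polya_len = polya, stringsAsFactors = FALSE)
      }
      raw <- mutateDna(raw, spec$error_rate)
      seqs[[i]] <- raw
      q <- if (cat_i == "low_quality") spec$q_low else spec$q_high
      quals[[i]] <- strrep(rawToChar(as.raw(q + 33L)), nchar(raw))
    }
    truth <- do.call(rbind, truth)
    truth$read_id <- sprintf("R%05d", seq_len(n))
    reads <- Biostrings::QualityScaledDNAStringSet(
      stats::setNames(Biostrings::DNAStringSet(seqs), truth$read_id),
      Biostrings::PhredQuality(quals))
    list(reads = reads, truth = truth)
  })
}

#' Write simulated reads as Sanger FASTQ
#'
#' @param reads a \link[Biostrings]{QualityScaledDNAStringSet}.
#' @param path output file.
#' @export
writeReadsFastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Read ESTs from FASTQ (with qualities) or FASTA (without)
#'
#' @param path input file.
#' @param format \code{"fastq"} or \code{"fasta"}.
#' @return a \link[Biostrings]{QualityScaledDNAStringSet} (fastq) or
#'   \link[Biostrings]{DNAStringSet} (fasta).
#' @export
readReads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "fastq")
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  else
    Biostrings::readDNAStringSet(path)
}

#' Generate a toy Gene Ontology world
#'
#' Builds a random, layered is_a DAG with the three GO namespaces (one
#' root each), a protein-to-GO mapping in which every protein is directly
#' annotated to at least one leaf term, and a baseline annotation corpus
#' usable as the unbiased reference of enrichment analysis.
#'
#' @param n_terms_per_ns terms per namespace (including the root).
#' @param depth number of layers below each root; must be >= 2 for a
#'   non-trivial hierarchy (1 gives a star).
#' @param n_proteins number of baseline proteins.
#' @param terms_per_protein mean number of distinct leaf terms a protein
#'   is directly annotated to (Poisson, minimum 1).
#' @param p_second_parent probability that a non-root term gets a second
#'   parent (making the graph a DAG rather than a tree).
#' @param seed integer seed.
#' @return list with \code{dag} (a \link{GODag}), \code{mapping} (a
#'   GAF-like \code{data.frame}: \code{protein_id}, \code{go_id},
#'   \code{namespace}, \code{taxon_class}) and \code{baseline} (an
#'   \link{AnnotationSet} propagated from the mapping).
#' @export
makeGoWorld <- function(n_terms_per_ns = 40L, depth = 4L,
                        n_proteins = 500L, terms_per_protein = 2,
                        p_second_parent = 0.25, seed = 1L) {
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  stopifnotScalarCount(n_proteins, "n_proteins")
  withSeed(seed, {
    terms <- list(); parents <- list()
    for (k in seq_along(GO_NAMESPACES)) {
      ns <- GO_NAMESPACES[[k]]
      nt <- n_terms_per_ns
      ids <- sprintf("GO:%07d", (k - 1L) * 1000000L + seq_len(nt))
      root <- ids[[1L]]
      layer <- rep(NA_integer_, nt); layer[1L] <- 0L
      ## spread remaining terms over layers 1..depth
      if (nt > 1L)
        layer[2:nt] <- sort(sample(seq_len(depth), nt - 1L, replace = TRUE))
      for (i in seq_len(nt)) {
        id <- ids[[i]]
        if (i == 1L) { parents[[id]] <- character(0); next }
        cand <- ids[!is.na(layer) & layer < layer[[i]] &
                    seq_len(nt) < i]
        p1 <- sample(cand, 1L)
        ps <- p1
        if (length(cand) > 1L && stats::runif(1L) < p_second_parent)
          ps <- unique(c(ps, sample(setdiff(cand, p1), 1L)))
        parents[[id]] <- ps
      }
      terms[[ns]] <- data.frame(id = ids,
                                name = paste0(ns, " term ", seq_len(nt)),
                                namespace = ns, stringsAsFactors = FALSE)
      terms[[ns]]$name[[1L]] <- ns
    }
    term_df <- do.call(rbind, terms)
    rownames(term_df) <- NULL
    dag <- methods::new("GODag", terms = term_df, parents = parents)
    ## leaves per namespace
    has_child <- unique(unlist(parents, use.names = FALSE))
    leaves <- setdiff(term_df$id, has_child)
    taxa <- c("mammalian", "amphibian", "avian", "fish", "insect",
              "prokaryote_virus", "unicellular_eukaryote", "reptile",
              "other_invertebrate", "plant")
    prot_ids <- sprintf("P%05d", seq_len(n_proteins))
    rows <- vector("list", n_proteins)
    for (j in seq_len(n_proteins)) {
      k <- max(1L, stats::rpois(1L, terms_per_protein))
      tsel <- sample(leaves, min(k, length(leaves)))
      rows[[j]] <- data.frame(protein_id = prot_ids[[j]], go_id = tsel,
                              namespace = term_df$namespace[
                                match(tsel, term_df$id)],
                              taxon_class = sample(taxa, 1L),
                              stringsAsFactors = FALSE)
    }
    mapping <- do.call(rbind, rows)
    rownames(mapping) <- NULL
    baseline <- propagateAnnotations(dag, mapping)
    list(dag = dag, mapping = mapping, baseline = baseline)
  })
}

#' Plant a GO enrichment scenario with known fold accumulation
#'
#' Draws a dataset of \code{n_dataset_proteins} annotation profiles from
#' the baseline protein pool with importance weights chosen so that the
#' expected fold accumulation of each planted term equals the requested
#' fold; non-planted terms have expected fold about 1. Dataset proteins
#' get fresh identifiers so distinct-protein counting is well defined.
#'
#' @param world result of \code{\link{makeGoWorld}}.
#' @param planted named numeric vector: term id -> desired fold (>= 1).
#' @param n_dataset_proteins dataset size.
#' @param seed integer seed.
#' @return list with \code{annotation} (GAF-like \code{data.frame} of the
#'   dataset), \code{annotation_set} (propagated \link{AnnotationSet}) and
#'   \code{truth} (\code{data.frame}: \code{go_id}, \code{planted_fold},
#'   \code{baseline_ratio}, \code{target_ratio}).
#' @export
makeEnrichmentScenario <- function(world, planted = numeric(0),
                                   n_dataset_proteins = 600L, seed = 1L) {
  stopifnotScalarCount(n_dataset_proteins, "n_dataset_proteins")
  if (length(planted)) {
    if (is.null(names(planted)) || !all(names(planted) %in%
                                        goTerms(world$dag)$id))
      stop("planted terms must exist in the world", call. = FALSE)
    if (any(planted < 1)) stop("planted folds must be >= 1", call. = FALSE)
  }
  base <- world$baseline
  root_bp <- goRoots(world$dag)[["biological_process"]]
  pool <- propagatedProteins(base, root_bp)
  N_base <- length(pool)
  ratios <- vapply(names(planted), function(t)
    length(propagatedProteins(base, t)) / N_base, numeric(1))
  targets <- unname(planted) * ratios
  if (any(targets > 1))
    stop("requested fold makes the dataset ratio exceed 1 for: ",
         paste(names(planted)[targets > 1], collapse = ", "), call. = FALSE)
  withSeed(seed, {
    wts <- rep(1, N_base); names(wts) <- pool
    for (j in seq_along(planted)) {
      t <- names(planted)[[j]]
      inset <- pool %in% propagatedProteins(base, t)
      r <- ratios[[j]]; p <- targets[[j]]
      if (r > 0 && r < 1)
        wts <- wts * ifelse(inset, p / r, (1 - p) / (1 - r))
    }
    src <- sample(pool, n_dataset_proteins, replace = TRUE,
                  prob = wts / sum(wts))
    map <- world$mapping
    ann <- do.call(rbind, lapply(seq_len(n_dataset_proteins), function(i) {
      sub <- map[map$protein_id == src[[i]], , drop = FALSE]
      sub$protein_id <- sprintf("DSP%05d", i)
      sub
    }))
    rownames(ann) <- NULL
    aset <- propagateAnnotations(world$dag, ann)
    truth <- data.frame(go_id = names(planted),
                        planted_fold = unname(planted),
                        baseline_ratio = unname(ratios),
                        target_ratio = unname(targets),
                        stringsAsFactors = FALSE)
    list(annotation = ann, annotation_set = aset, truth = truth)
  })
}

#' Simulate a truth-driven homology hit table
#'
#' Emits a BLAST-tabular-style hit table for a set of query ids without
#' running an aligner: each query either receives no hit or a ranked list
#' of hits to synthetic protein subjects, with e-values drawn from the
#' requested similarity class, subject alignment starts concentrated near
#' position 1 (so full-length calling has signal), and sidecar columns for
#' algorithm, subject description and taxon class.
#'
#' @param query_ids character vector of query (contig) ids.
#' @param p_hit probability a query has any hit.
#' @param p_significant among hit-bearing queries, probability the best
#'   hit is in the significant class (\code{e < 1e-20}); the rest are
#'   weak (\code{1e-20 <= e <= 1e-05}).
#' @param n_hits_mean mean number of hits per hit-bearing query (Poisson,
#'   minimum 1).
#' @param protein_pool character vector of subject ids to draw from.
#' @param descriptions optional named character vector subject id ->
#'   description (defaults to the subject id).
#' @param taxa optional named character vector subject id -> taxon class.
#' @param algorithm algorithm tag for the emitted rows.
#' @param best_subjects optional named character vector query id ->
#'   subject id forced as the rank-1 hit (ground-truth homolog); lower
#'   ranks are still drawn from the pool.
#' @param seed integer seed.
#' @return a hit table \code{data.frame} in the 15-column dialect of
#'   \code{\link{readHitTable}}.
#' @export
makeHitTable <- function(query_ids, p_hit = 0.6, p_significant = 0.75,
                         n_hits_mean = 3, protein_pool = sprintf("P%05d", 1:500),
                         descriptions = NULL, taxa = NULL,
                         algorithm = "blastx", best_subjects = NULL,
                         seed = 1L) {
  withSeed(seed, {
    rows <- list()
    taxa_lvls <- c("amphibian", "mammalian", "avian", "fish", "insect",
                   "prokaryote_virus", "unicellular_eukaryote", "reptile",
                   "other_invertebrate", "plant", "other")
    for (q in query_ids) {
      if (stats::runif(1L) > p_hit) next
      nh <- max(1L, stats::rpois(1L, n_hits_mean))
      best_sig <- stats::runif(1L) < p_significant
      ## best e-value, then monotonically worse ranks
      e_best <- if (best_sig) 10^stats::runif(1L, -80, -21)
                else 10^stats::runif(1L, -19, -5)
      evs <- sort(e_best * 10^cumsum(c(0, stats::runif(nh - 1L, 0, 6))))
      evs <- pmin(evs, 1)
      subj <- sample(protein_pool, nh, replace = length(protein_pool) < nh)
      if (!is.null(best_subjects) && !is.na(best_subjects[q]))
        subj[[1L]] <- unname(best_subjects[[q]])
      alen <- sample(80:400, nh, replace = TRUE)
      sstart <- ifelse(stats::runif(nh) < 0.6, 1L,
                       sample(2:40, nh, replace = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = q, sseqid = subj,
        pident = round(stats::runif(nh, 35, 99), 2),
        length = alen, mismatch = sample(0:40, nh, replace = TRUE),
        gapopen = 0L,
        qstart = sample(1:60, nh, replace = TRUE), qend = 0L,
        sstart = as.integer(sstart), send = 0L,
        evalue = evs, bitscore = round(pmax(30, -log10(evs) * 2.2 +
                                            stats::rnorm(nh, 0, 3)), 1),
        algorithm = algorithm,
        subject_description = if (is.null(descriptions)) subj
                              else unname(descriptions[subj]),
        taxon_class = if (is.null(taxa)) sample(taxa_lvls, nh, replace = TRUE)
                      else unname(taxa[subj]),
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(emptyHitTable())
    out <- do.call(rbind, rows)
    out$qend <- out$qstart + out$length - 1L
    out$send <- out$sstart + as.integer(ceiling(out$length / 3)) - 1L
    rownames(out) <- NULL
    out
  })
}

#' Simulate an RT-PCR densitometry table with planted fold changes
#'
#' Intensities follow \code{base * fold(gene, t) * (1 + noise)} with the
#' control gene held at fold 1 across all timepoints; every (gene,
#' timepoint) cell has the same number of biological pools.
#'
#' @param genes character vector of gene names (the control is added
#'   automatically if absent).
#' @param timepoints integer days; must include day 0.
#' @param n_pools biological pools per timepoint (>= 2).
#' @param effects named list gene -> numeric vector of folds per
#'   timepoint (same order as \code{timepoints}); missing genes get fold 1
#'   everywhere.
#' @param noise_sd relative (multiplicative) noise standard deviation.
#' @param control_gene name of the non-modulated control.
#' @param seed integer seed.
#' @return list with \code{table} (\code{data.frame}: \code{gene},
#'   \code{timepoint}, \code{pool}, \code{intensity}), \code{control_gene}
#'   and \code{truth} (\code{data.frame} of planted folds).
#' @export
makeDensitometry <- function(genes, timepoints = c(0L, 4L, 7L, 14L, 21L),
                             n_pools = 3L, effects = list(),
                             noise_sd = 0.1, control_gene = "rps21",
                             seed = 1L) {
  if (!0 %in% timepoints)
    stop("timepoints must include day 0", call. = FALSE)
  if (n_pools < 2L) stop("n_pools must be >= 2", call. = FALSE)
  genes <- union(genes, control_gene)
  withSeed(seed, {
    rows <- list(); truth <- list()
    for (g in genes) {
      fold <- effects[[g]] %||% rep(1, length(timepoints))
      if (g == control_gene) fold <- rep(1, length(timepoints))
      if (length(fold) != length(timepoints))
        stop("effects for ", g, " must match timepoints", call. = FALSE)
      base <- if (g == control_gene) 1000 else stats::runif(1L, 200, 2000)
      for (ti in seq_along(timepoints)) {
        noise <- stats::rnorm(n_pools, 0, noise_sd)
        noise <- pmax(noise, -0.9)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, timepoint = timepoints[[ti]], pool = seq_len(n_pools),
          intensity = base * fold[[ti]] * (1 + noise),
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        gene = g, timepoint = timepoints, planted_fold = fold,
        stringsAsFactors = FALSE)
    }
    list(table = do.call(rbind, rows), control_gene = control_gene,
         truth = do.call(rbind, truth))
  })
}
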