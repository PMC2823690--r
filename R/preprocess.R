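## Read cleanup with full flowchart accounting: quality filter -> vector
## clip -> polyA trim -> empty/short filter, in that fixed order. All
## coordinates are 1-based inclusive positions on the raw read.

#' Preprocessing configuration
#'
#' @param min_mean_quality reads whose mean Phred score falls below this
#'   are removed as low quality; reads without qualities are kept.
#' @param min_len minimum insert length (nt) after clipping and trimming;
#'   shorter inserts are discarded as short.
#' @param five_prime_flank,three_prime_flank cloning-vector flanks.
#' @param seed_k exact k-mer seed size for vector detection; 12 keeps a
#'   clean seed available even when two substitution errors fall in one
#'   flank.
#' @param max_flank_mismatch maximum mismatch fraction tolerated when a
#'   seeded flank match is extended across the full flank.
#' @param polya_window,polya_min_run,polya_min_frac polyA rule: within the
#'   last \code{polya_window} nt, the leftmost suffix of at least
#'   \code{polya_min_run} nt with at least \code{polya_min_frac} adenine
#'   is trimmed.
#' @return a \code{list} of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(min_mean_quality = 20,
                             min_len = 100L,
                             five_prime_flank = DEFAULT_FLANK5,
                             three_prime_flank = DEFAULT_FLANK3,
                             seed_k = 12L,
                             max_flank_mismatch = 0.10,
                             polya_window = 50L, polya_min_run = 10L,
                             polya_min_frac = 0.9) {
  if (min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  structure(list(min_mean_quality = min_mean_quality,
                 min_len = as.integer(min_len),
                 five_prime_flank = five_prime_flank,
                 three_prime_flank = three_prime_flank,
                 seed_k = as.integer(seed_k),
                 max_flank_mismatch = max_flank_mismatch,
                 polya_window = as.integer(polya_window),
                 polya_min_run = as.integer(polya_min_run),
                 polya_min_frac = polya_min_frac),
            class = "PreprocessConfig")
}

#' Remove low-quality reads by mean Phred score
#'
#' Reads without quality strings are always kept; \code{kept} and
#' \code{removed} partition the input.
#'
#' @param reads a \link[Biostrings]{QualityScaledDNAStringSet} or plain
#'   \link[Biostrings]{DNAStringSet}.
#' @param min_mean_quality Phred threshold (default 20).
#' @return list with elements \code{kept} and \code{removed}.
#' @export
qualityFilter <- function(reads, min_mean_quality = 20) {
  if (!methods::is(reads, "QualityScaledXStringSet"))
    return(list(kept = reads, removed = reads[integer(0)]))
  qm <- meanPhred(reads)
  low <- qm < min_mean_quality
  list(kept = reads[!low], removed = reads[low])
}

meanPhred <- function(reads) {
  qs <- as(Biostrings::quality(reads), "IntegerList")
  vapply(qs, function(v) if (length(v)) mean(v) else Inf, numeric(1))
}

#' Locate the cDNA insert between cloning-vector flanks
#'
#' Detects each flank by exact k-mer seeding followed by full-flank
#' ungapped extension at the seeded offset, tolerating up to
#' \code{max_flank_mismatch} mismatches. The returned interval excludes
#' every base matched to a flank; if neither flank is found the interval
#' is the whole read. An empty insert is reported as an interval with
#' \code{end == start - 1}.
#'
#' @param sequence a single DNA string.
#' @param config a \code{\link{preprocessConfig}} (flanks and tolerances).
#' @return list(\code{start}, \code{end}, \code{found_5}, \code{found_3}).
#' @export
clipVector <- function(sequence, config = preprocessConfig()) {
  n <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m5 <- matchFlank(ch, config$five_prime_flank, config)
  m3 <- matchFlank(ch, config$three_prime_flank, config)
  ## resolve overlaps deterministically: the 5' flank wins the left end
  start <- 1L; end <- n
  found5 <- !is.null(m5); found3 <- !is.null(m3)
  if (found5) start <- m5$to + 1L
  if (found3 && m3$from > (if (found5) m5$to else 0L)) {
    end <- m3$from - 1L
  } else if (found3 && found5) {
    ## 3' flank match lies inside/before the 5' match: empty insert
    end <- start - 1L
  }
  if (end < start - 1L) end <- start - 1L
  list(start = start, end = end, found_5 = found5, found_3 = found3)
}

## Best full-flank ungapped placement of `flank` in the read `ch`
## (character vector), or NULL. Seeds with exact k-mers, scores every
## candidate offset by identity over the aligned span, requires
## identity >= 1 - max_flank_mismatch over a span >= seed_k.
matchFlank <- function(ch, flank, config) {
  k <- config$seed_k
  fch <- strsplit(flank, "", fixed = TRUE)[[1L]]
  if (length(fch) < k || length(ch) < k) return(NULL)
  seq_str <- paste(ch, collapse = "")
  fpos <- kmerPositions(flank, k)
  rpos <- kmerPositions(seq_str, k)
  shared <- intersect(names(fpos), names(rpos))
  if (!length(shared)) return(NULL)
  offsets <- unique(unlist(lapply(shared, function(km)
    as.vector(outer(rpos[[km]], fpos[[km]], `-`)))))
  best <- NULL
  for (d in sort(offsets)) {
    ov <- offsetOverlap(fch, ch, d, min_overlap = k)
    if (is.null(ov)) next
    if (ov$identity >= 1 - config$max_flank_mismatch) {
      score <- ov$identity * ov$overlap
      if (is.null(best) || score > best$score)
        best <- list(from = ov$from + d, to = ov$to + d, score = score)
    }
  }
  best
}

#' Trim a 3' polyA tail
#'
#' Applies the shared polyA rule (see \code{\link{preprocessConfig}}):
#' a maximal terminal adenine run of at least \code{polya_min_run} nt is
#' removed exactly; otherwise, within the last \code{polya_window} nt,
#' the leftmost suffix of at least \code{polya_min_run} nt that is at
#' least \code{polya_min_frac} adenine is removed. The rule is applied
#' repeatedly until no tail remains, so trimming is idempotent even when
#' sequencing errors fragment the tail.
#'
#' @param sequence a single DNA string.
#' @param config a \code{\link{preprocessConfig}}.
#' @return list(\code{sequence} trimmed prefix, \code{had_polya}).
#' @export
trimPolya <- function(sequence, config = preprocessConfig()) {
  had <- FALSE
  ## iterate to fixed point: a sequencing error inside the tail can
  ## split it into segments that are only removable one at a time
  repeat {
    s <- polyaStart(sequence, config$polya_window, config$polya_min_run,
                    config$polya_min_frac)
    if (is.na(s)) break
    had <- TRUE
    sequence <- substr(sequence, 1L, s - 1L)
  }
  list(sequence = sequence, had_polya = had)
}

#' Run the full read-cleanup pipeline with accounting
#'
#' Fixed stage order: quality filter, vector clipping, polyA trimming,
#' then removal of empty and short (< \code{min_len}) inserts. The counts
#' table satisfies \code{input = low_quality + empty + short + kept}.
#'
#' @param reads a \link[Biostrings]{QualityScaledDNAStringSet} (or plain
#'   \code{DNAStringSet}; then no read is low quality).
#' @param config a \code{\link{preprocessConfig}}.
#' @return list with \code{ests}: a \link[Biostrings]{DNAStringSet} of
#'   cleaned inserts whose \code{mcols} carry \code{clip_5}, \code{clip_3}
#'   (1-based inclusive insert coordinates on the raw read) and
#'   \code{had_polya}; and \code{counts}: a \code{data.frame}
#'   (\code{category}, \code{count}) reproducing the processing flowchart.
#' @export
runPreprocess <- function(reads, config = preprocessConfig()) {
  n_in <- length(reads)
  qf <- qualityFilter(reads, config$min_mean_quality)
  ## qualities (and any metadata columns) are intentionally dropped here
  kept <- suppressWarnings(Biostrings::DNAStringSet(qf$kept))
  n_low <- length(qf$removed)
  ids <- names(kept) %||% as.character(seq_along(kept))
  seqs <- as.character(kept)
  out_seq <- character(0); out_id <- character(0)
  clip5 <- integer(0); clip3 <- integer(0); had_pa <- logical(0)
  n_empty <- 0L; n_short <- 0L
  for (i in seq_along(seqs)) {
    cl <- clipVector(seqs[[i]], config)
    if (cl$end < cl$start) { n_empty <- n_empty + 1L; next }
    insert <- substr(seqs[[i]], cl$start, cl$end)
    tp <- trimPolya(insert, config)
    if (nchar(tp$sequence) == 0L) { n_empty <- n_empty + 1L; next }
    if (nchar(tp$sequence) < config$min_len) { n_short <- n_short + 1L; next }
    out_seq <- c(out_seq, tp$sequence)
    out_id <- c(out_id, ids[[i]])
    clip5 <- c(clip5, cl$start)
    clip3 <- c(clip3, cl$start + nchar(tp$sequence) - 1L)
    had_pa <- c(had_pa, tp$had_polya)
  }
  ests <- stats::setNames(Biostrings::DNAStringSet(out_seq), out_id)
  S4Vectors::mcols(ests) <- S4Vectors::DataFrame(
    clip_5 = clip5, clip_3 = clip3, had_polya = had_pa)
  counts <- data.frame(
    category = c("input", "low_quality", "empty", "short", "kept"),
    count = c(n_in, n_low, n_empty, n_short, length(ests)),
    stringsAsFactors = FALSE)
  list(ests = ests, counts = counts)
}

#' Write cleaned ESTs and the accounting table
#'
#' @param pre result of \code{\link{runPreprocess}}.
#' @param fasta_path,counts_path output paths (FASTA and TSV).
#' @export
writePreprocess <- function(pre, fasta_path, counts_path) {
  Biostrings::writeXStringSet(pre$ests, fasta_path)
  utils::write.table(pre$counts, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
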