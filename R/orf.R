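## Full-length contig calling and six-frame ORF scanning for contigs
## without database hits. A contig is called full length when its best
## protein alignment starts within the first `window` amino acids of the
## homolog AND the consensus carries a 3' polyA tail.

#' Detect a 3' polyA tail on a contig consensus
#'
#' Applies the identical polyA rule used by read preprocessing (see
#' \code{\link{preprocessConfig}}).
#'
#' @param sequence one or more DNA strings.
#' @param config a \code{\link{preprocessConfig}}.
#' @return logical vector.
#' @export
detectPolya <- function(sequence, config = preprocessConfig()) {
  vapply(as.character(sequence), function(s)
    !is.na(polyaStart(s, config$polya_window, config$polya_min_run,
                      config$polya_min_frac)),
    logical(1), USE.NAMES = FALSE)
}

#' Full-length classification from protein-alignment starts and polyA
#'
#' A contig's start is covered when its best protein alignment begins
#' before amino-acid position \code{window} of the homolog (positions
#' 1..\code{window - 1}); later starts are excluded from the cumulative
#' table. \code{full_length} requires both start coverage and a polyA
#' tail.
#'
#' @param best_protein_hits \code{data.frame} with one row per contig:
#'   columns \code{qseqid} (contig id) and \code{sstart} (subject
#'   alignment start, amino acids, 1-based) of its best protein hit with
#'   \code{e <= 1e-05}.
#' @param polya named logical vector: contig id -> has polyA tail.
#' @param window amino-acid start window (default 10).
#' @return list with \code{calls} (per contig: \code{contig_id},
#'   \code{s_start_aa}, \code{has_polya}, \code{start_covered},
#'   \code{full_length}) and \code{table}, the cumulative per-position
#'   table (\code{position}, \code{n_contigs}, \code{contigs_total},
#'   \code{n_full_length}, \code{full_length_total}) for positions
#'   1..\code{window - 1} within the window.
#' @export
classifyFullLength <- function(best_protein_hits, polya, window = 10L) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  calls <- data.frame(contig_id = best_protein_hits$qseqid,
                      s_start_aa = best_protein_hits$sstart,
                      stringsAsFactors = FALSE)
  calls$has_polya <- unname(polya[calls$contig_id])
  calls$has_polya[is.na(calls$has_polya)] <- FALSE
  calls$start_covered <- calls$s_start_aa < window
  calls$full_length <- calls$start_covered & calls$has_polya
  pos <- seq_len(window - 1L)
  inw <- calls[calls$s_start_aa < window, , drop = FALSE]
  n_pos <- vapply(pos, function(p) sum(inw$s_start_aa == p), integer(1))
  n_fl <- vapply(pos, function(p)
    sum(inw$s_start_aa == p & inw$has_polya), integer(1))
  tab <- data.frame(position = pos, n_contigs = n_pos,
                    contigs_total = cumsum(n_pos),
                    n_full_length = n_fl,
                    full_length_total = cumsum(n_fl))
  list(calls = calls, table = tab)
}

GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

## all ORFs (M..stop) of one frame's amino-acid string; returns
## data.frame(aa_start, aa_len, truncated)
frameOrfs <- function(aa) {
  out <- list()
  m <- gregexpr("M[^*]*\\*", aa)[[1L]]
  if (m[1L] != -1L) {
    len <- attr(m, "match.length")
    out[[1L]] <- data.frame(aa_start = as.integer(m),
                            aa_len = as.integer(len) - 1L,
                            truncated = FALSE)
  }
  t <- regexpr("M[^*]*$", aa)
  if (t[1L] != -1L && attr(t, "match.length") > 0L) {
    out[[length(out) + 1L]] <- data.frame(
      aa_start = as.integer(t),
      aa_len = as.integer(attr(t, "match.length")),
      truncated = TRUE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Six-frame ORF scan of no-hit contigs
#'
#' An ORF is ATG-to-stop in one of the six reading frames; its length is
#' counted in amino acids excluding the stop. ORFs truncated by the
#' contig end (no stop codon reached) are reported with
#' \code{truncated = TRUE} and excluded from the long-ORF fraction by
#' default. The longest ORF per contig is reported.
#'
#' @param contigs a named \link[Biostrings]{DNAStringSet} (or character
#'   vector) of contigs without database hits.
#' @param min_orf_aa minimum ORF length in amino acids (default 22:
#'   shorter ORFs are not called).
#' @param long_orf_aa threshold of the long-ORF bucket (default 150).
#' @param include_truncated count truncated ORFs in calls and summary.
#' @return list with \code{calls} (\code{contig_id}, \code{frame} in
#'   +1..+3/-1..-3, \code{start_nt}, \code{end_nt} 1-based inclusive on
#'   the input strand including the stop codon, \code{aa_length},
#'   \code{truncated}; longest ORF per contig) and \code{summary}
#'   (\code{n_scanned}, \code{n_with_orf}, \code{fraction_long}).
#' @export
findOrfs <- function(contigs, min_orf_aa = 22L, long_orf_aa = 150L,
                     include_truncated = FALSE) {
  seqs <- as.character(contigs)
  ids <- names(seqs) %||% sprintf("C%04d", seq_along(seqs))
  calls <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    L <- nchar(s)
    best <- NULL
    for (dir in c(1L, -1L)) {
      str <- if (dir == 1L) s else revcompChar(s)
      for (f in 1:3) {
        n_cod <- (nchar(str) - f + 1L) %/% 3L
        if (n_cod < 1L) next
        sub <- substr(str, f, f + 3L * n_cod - 1L)
        aa <- as.character(suppressWarnings(
          Biostrings::translate(Biostrings::DNAString(sub),
                                if.fuzzy.codon = "X")))
        orfs <- frameOrfs(aa)
        if (is.null(orfs)) next
        orfs <- orfs[orfs$aa_len >= min_orf_aa, , drop = FALSE]
        if (!include_truncated)
          orfs <- orfs[!orfs$truncated, , drop = FALSE]
        if (!nrow(orfs)) next
        orfs <- orfs[order(-orfs$aa_len, orfs$aa_start), , drop = FALSE]
        top <- orfs[1L, ]
        ## nt coordinates on the scanned strand (stop codon included)
        nt_s <- f + 3L * (top$aa_start - 1L)
        nt_e <- nt_s + 3L * top$aa_len + (if (top$truncated) -1L else 2L)
        if (dir == -1L) {   # map back to the input strand
          tmp <- nt_s
          nt_s <- L - nt_e + 1L
          nt_e <- L - tmp + 1L
        }
        cand <- data.frame(contig_id = ids[[i]],
                           frame = dir * f,
                           start_nt = nt_s, end_nt = nt_e,
                           aa_length = top$aa_len,
                           truncated = top$truncated,
                           stringsAsFactors = FALSE)
        if (is.null(best) || cand$aa_length > best$aa_length)
          best <- cand
      }
    }
    if (!is.null(best)) calls[[length(calls) + 1L]] <- best
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(contig_id = character(0), frame = integer(0),
               start_nt = integer(0), end_nt = integer(0),
               aa_length = integer(0), truncated = logical(0),
               stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  n_with <- nrow(calls)
  long <- calls[!calls$truncated, , drop = FALSE]
  summary <- data.frame(
    n_scanned = length(seqs),
    n_with_orf = n_with,
    fraction_long = if (n_with) sum(long$aa_length >= long_orf_aa) / n_with
                    else NA_real_)
  list(calls = calls, summary = summary)
}
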