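## Hit-table handling: 12 standard BLAST tabular columns plus three
## sidecar columns (algorithm, subject_description, taxon_class), best-hit
## selection and the weak/significant similarity classes.

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore", "algorithm", "subject_description",
                 "taxon_class")

HIT_ALGORITHMS <- c("blastn", "blastx", "tblastx", "est_blastn",
                    "est_tblastx")

TAXON_CLASSES <- c("amphibian", "mammalian", "avian", "fish", "insect",
                   "prokaryote_virus", "unicellular_eukaryote", "reptile",
                   "other_invertebrate", "plant", "other")

emptyHitTable <- function() {
  out <- data.frame(qseqid = character(0), sseqid = character(0),
                    pident = numeric(0), length = integer(0),
                    mismatch = integer(0), gapopen = integer(0),
                    qstart = integer(0), qend = integer(0),
                    sstart = integer(0), send = integer(0),
                    evalue = numeric(0), bitscore = numeric(0),
                    algorithm = character(0),
                    subject_description = character(0),
                    taxon_class = character(0), stringsAsFactors = FALSE)
  out
}

#' Read a homology hit table
#'
#' Tab-separated, no header: the 12 standard BLAST tabular (outfmt 6)
#' columns followed by \code{algorithm}, \code{subject_description} and
#' \code{taxon_class}. Malformed lines are rejected with their line
#' numbers; an unknown algorithm tag or invalid coordinates are parse
#' errors.
#'
#' @param path input TSV file.
#' @return a validated hit-table \code{data.frame}.
#' @export
readHitTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(emptyHitTable())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(HIT_COLUMNS))
  if (length(bad))
    stop("malformed hit lines (expected ", length(HIT_COLUMNS),
         " columns) at line(s): ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  m <- do.call(rbind, parts)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    pident = as.numeric(m[, 3]),
                    length = as.integer(m[, 4]),
                    mismatch = as.integer(m[, 5]),
                    gapopen = as.integer(m[, 6]),
                    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]),
                    bitscore = as.numeric(m[, 12]),
                    algorithm = m[, 13], subject_description = m[, 14],
                    taxon_class = m[, 15], stringsAsFactors = FALSE)
  validateHitTable(out)
  out
}

validateHitTable <- function(hits) {
  bad_alg <- !hits$algorithm %in% HIT_ALGORITHMS
  if (any(bad_alg))
    stop("unknown algorithm tag(s): ",
         paste(unique(hits$algorithm[bad_alg]), collapse = ", "),
         " at line(s): ", paste(utils::head(which(bad_alg), 10),
                                collapse = ", "), call. = FALSE)
  bad_e <- is.na(hits$evalue) | hits$evalue < 0
  if (any(bad_e))
    stop("invalid e-value at line(s): ",
         paste(utils::head(which(bad_e), 10), collapse = ", "),
         call. = FALSE)
  bad_co <- is.na(hits$qstart) | is.na(hits$qend) | is.na(hits$sstart) |
    is.na(hits$send) | hits$qstart < 1 | hits$sstart < 1 |
    hits$qstart > hits$qend | hits$sstart > hits$send
  if (any(bad_co))
    stop("invalid alignment coordinates at line(s): ",
         paste(utils::head(which(bad_co), 10), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Write a hit table in the package's 15-column TSV dialect
#'
#' @param hits a hit-table \code{data.frame}.
#' @param path output file.
#' @export
writeHitTable <- function(hits, path) {
  utils::write.table(hits[, HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Similarity class of a best e-value
#'
#' \code{e < 1e-20} is \code{"significant"}; \code{1e-20 <= e <= 1e-05}
#' is \code{"weak"}; anything larger (or a missing e-value) is
#' \code{"none"}. Boundary values follow the printed inequalities: both
#' \code{1e-20} and \code{1e-05} fall in the weak class.
#'
#' @param e_value numeric vector of best e-values (\code{NA} = no hit).
#' @param e_weak,e_sig the two class cutoffs.
#' @return factor with levels \code{none}, \code{weak},
#'   \code{significant}.
#' @export
classifySimilarity <- function(e_value, e_weak = 1e-05, e_sig = 1e-20) {
  if (any(!is.na(e_value) & e_value < 0))
    stop("e-values must be >= 0", call. = FALSE)
  cls <- ifelse(is.na(e_value), "none",
                ifelse(e_value < e_sig, "significant",
                       ifelse(e_value <= e_weak, "weak", "none")))
  factor(cls, levels = c("none", "weak", "significant"))
}

## canonical hit ordering: ascending e-value, then descending bitscore,
## then lexicographic subject id (documented tie-break)
orderHits <- function(hits) {
  order(hits$evalue, -hits$bitscore, hits$sseqid)
}

#' Select per-query top-k hits and the single global best hit
#'
#' Hits from all algorithms are ranked together per query by ascending
#' e-value (ties: higher bitscore, then lexicographic subject id). The
#' global best hit of a query is its rank-1 hit across all algorithms.
#'
#' @param hits a hit-table \code{data.frame}.
#' @param k number of top hits to retain per query (default 50).
#' @return list with \code{top} (hit table plus a \code{rank} column,
#'   at most \code{k} rows per query) and \code{best} (one row per query).
#' @export
selectBestHits <- function(hits, k = 50L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (!nrow(hits)) {
    top <- cbind(emptyHitTable(), rank = integer(0))
    return(list(top = top, best = emptyHitTable()))
  }
  hits <- hits[orderHits(hits), , drop = FALSE]
  spl <- split(seq_len(nrow(hits)), hits$qseqid)
  keep <- unlist(lapply(spl, function(ix) utils::head(ix, k)),
                 use.names = FALSE)
  rank <- unlist(lapply(spl, function(ix) seq_len(min(length(ix), k))),
                 use.names = FALSE)
  ## unsplit in original sorted order
  keep_ord <- order(keep)
  top <- hits[keep[keep_ord], , drop = FALSE]
  top$rank <- rank[keep_ord]
  best <- top[top$rank == 1L, , drop = FALSE]
  best$rank <- NULL
  rownames(top) <- rownames(best) <- NULL
  list(top = top, best = best)
}

#' Taxon-class distribution of best hits
#'
#' @param best_hits one best hit per query (e.g.
#'   \code{selectBestHits(hits)$best}).
#' @return \code{data.frame} (\code{taxon_class}, \code{count},
#'   \code{percentage}) sorted by decreasing count, with an
#'   \code{"All Organisms"} total row first. Percentages are of all
#'   queries with a best hit and sum to 100 up to rounding.
#' @export
taxonDistribution <- function(best_hits) {
  n <- nrow(best_hits)
  tab <- sort(table(best_hits$taxon_class), decreasing = TRUE)
  out <- data.frame(taxon_class = c("All Organisms", names(tab)),
                    count = c(n, as.integer(tab)),
                    stringsAsFactors = FALSE)
  out$percentage <- if (n) 100 * out$count / n else NA_real_
  out
}
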