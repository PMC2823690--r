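## Greedy overlap-layout-consensus assembly for desk-scale EST sets.
## Ungapped overlaps only (the error model downstream of trace processing
## is substitution-dominated), exact k-mer prefilter to propose candidate
## contigs and placements, column-majority consensus over a per-contig
## base-count matrix. Deterministic: reads are processed longest first
## (ties by id), then contigs are merged best-overlap first to fixed
## point.

#' Assembly parameters
#'
#' @param min_overlap minimum ungapped overlap in nt (>= 10).
#' @param min_identity minimum identity over the overlap, in [0.5, 1].
#' @param allow_revcomp also try the reverse complement of each read /
#'   contig (cloning orientation is not guaranteed).
#' @param seed_k k-mer size of the exact-match prefilter.
#' @return a \code{list} of class \code{"AssemblyParams"}.
#' @export
assemblyParams <- function(min_overlap = 40L, min_identity = 0.95,
                           allow_revcomp = TRUE, seed_k = 16L) {
  if (min_overlap < 10L) stop("min_overlap must be >= 10", call. = FALSE)
  if (min_identity < 0.5 || min_identity > 1)
    stop("min_identity must be in [0.5, 1]", call. = FALSE)
  structure(list(min_overlap = as.integer(min_overlap),
                 min_identity = min_identity,
                 allow_revcomp = isTRUE(allow_revcomp),
                 seed_k = as.integer(seed_k)),
            class = "AssemblyParams")
}

chComplement <- function(ch) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch])
}

## internal contig state: counts = 4 x L integer matrix (A,C,G,T rows),
## members = data.frame(est_id, offset, strand, width)
newContigState <- function(ch, est_id, strand = "+") {
  counts <- matrix(0L, nrow = 4L, ncol = length(ch),
                   dimnames = list(DNA_BASES4, NULL))
  idx <- match(ch, DNA_BASES4)
  ok <- !is.na(idx)
  counts[cbind(idx[ok], which(ok))] <- 1L
  list(counts = counts,
       members = data.frame(est_id = est_id, offset = 1L, strand = strand,
                            width = length(ch), stringsAsFactors = FALSE))
}

## column majority; ties resolved deterministically by fixed base order
## A < C < G < T (which.max takes the first maximum)
consensusFromCounts <- function(counts) {
  DNA_BASES4[apply(counts, 2L, which.max)]
}

padState <- function(st, d, L_other) {
  L <- ncol(st$counts)
  left_pad <- max(0L, -d)
  right_pad <- max(0L, d + L_other - L)
  if (left_pad > 0L) {
    st$counts <- cbind(matrix(0L, 4L, left_pad), st$counts)
    st$members$offset <- st$members$offset + left_pad
    d <- d + left_pad
  }
  if (right_pad > 0L)
    st$counts <- cbind(st$counts, matrix(0L, 4L, right_pad))
  list(st = st, d = d)
}

## add a read (char vector, already oriented) at offset d
## (read pos i -> consensus pos i + d)
addToContigState <- function(st, ch, est_id, strand, d) {
  p <- padState(st, d, length(ch)); st <- p$st; d <- p$d
  idx <- match(ch, DNA_BASES4)
  ok <- !is.na(idx)
  cells <- cbind(idx[ok], which(ok) + d)
  st$counts[cells] <- st$counts[cells] + 1L
  st$members <- rbind(st$members,
                      data.frame(est_id = est_id, offset = d + 1L,
                                 strand = strand, width = length(ch),
                                 stringsAsFactors = FALSE))
  st
}

## merge contig state y into x at offset d (y pos i -> x pos i + d);
## y is reverse-complemented first when strand == "-".
mergeStates <- function(x, y, d, strand) {
  Ly <- ncol(y$counts)
  if (strand == "-") {
    y$counts <- y$counts[c("T", "G", "C", "A"), rev(seq_len(Ly)),
                         drop = FALSE]
    rownames(y$counts) <- DNA_BASES4
    y$members$offset <- Ly - (y$members$offset + y$members$width - 1L) + 1L
    y$members$strand <- ifelse(y$members$strand == "+", "-", "+")
  }
  p <- padState(x, d, Ly); x <- p$st; d <- p$d
  x$counts[, d + seq_len(Ly)] <- x$counts[, d + seq_len(Ly)] + y$counts
  y$members$offset <- y$members$offset + d
  x$members <- rbind(x$members, y$members)
  x
}

## best ungapped placement of oriented char vector `ch` (with kmer
## positions rp) on a consensus with cached chars cc / kmer positions cp
bestPlacement <- function(cc, cp, ch, rp, params) {
  shared <- intersect(names(rp), names(cp))
  if (!length(shared)) return(NULL)
  offs <- unlist(lapply(shared, function(km)
    as.vector(outer(rp[[km]], cp[[km]], function(r, co) co - r))))
  tab <- sort(table(offs), decreasing = TRUE)
  cand <- as.integer(names(tab))[seq_len(min(5L, length(tab)))]
  best <- NULL
  for (d in cand) {
    ov <- offsetOverlap(ch, cc, d, params$min_overlap)
    if (is.null(ov) || ov$identity < params$min_identity) next
    if (is.null(best) || ov$identity > best$identity ||
        (ov$identity == best$identity && ov$overlap > best$overlap))
      best <- list(d = d, overlap = ov$overlap, identity = ov$identity)
  }
  best
}

## assembler working set: contig states plus per-contig caches and a
## global kmer -> contig-index map (may contain stale entries; callers
## check `alive` and recompute caches on demand)
newWorkspace <- function(k) {
  list(states = list(), alive = logical(0),
       cc = list(), kpos = list(),
       index = new.env(parent = emptyenv(), hash = TRUE), k = k)
}

wsRefresh <- function(ws, j) {
  if (!is.null(ws$cc[[j]])) return(ws)
  cc <- consensusFromCounts(ws$states[[j]]$counts)
  kp <- kmerPositions(paste(cc, collapse = ""), ws$k)
  ws$cc[[j]] <- cc
  ws$kpos[[j]] <- kp
  for (km in names(kp)) {
    cur <- ws$index[[km]]
    ws$index[[km]] <- c(cur, j)
  }
  ws
}

wsAddContig <- function(ws, st) {
  j <- length(ws$states) + 1L
  ws$states[[j]] <- st
  ws$alive[j] <- TRUE
  ws$cc[j] <- list(NULL)
  ws$kpos[j] <- list(NULL)
  wsRefresh(ws, j)
}

wsInvalidate <- function(ws, j) {
  ws$cc[j] <- list(NULL)
  ws$kpos[j] <- list(NULL)
  ws
}

## candidate contig indices whose consensus shares a kmer with `kms`
wsCandidates <- function(ws, kms) {
  hits <- unlist(lapply(kms, function(km) ws$index[[km]]),
                 use.names = FALSE)
  if (is.null(hits)) return(integer(0))
  js <- unique(hits)
  js[ws$alive[js]]
}

#' Greedy overlap assembly of cleaned ESTs into contigs
#'
#' Every EST ends up in exactly one contig (singletons are contigs of
#' one). Consensus is the column-majority base over all member reads,
#' ties resolved by fixed base order. Contig ids \code{CTG...} are
#' assigned after assembly in decreasing (EST count, consensus length)
#' order with ties broken by first member id, so the result is
#' deterministic for a given input.
#'
#' @param ests a named \link[Biostrings]{DNAStringSet} of cleaned ESTs.
#' @param params an \code{\link{assemblyParams}}.
#' @return a \link{ContigSet}.
#' @export
greedyAssemble <- function(ests, params = assemblyParams()) {
  ids <- names(ests) %||% sprintf("E%05d", seq_along(ests))
  if (anyDuplicated(ids)) stop("EST ids must be unique", call. = FALSE)
  seqs <- as.character(ests)
  if (!length(seqs)) return(finalizeContigSet(list()))
  ord <- order(-nchar(seqs), ids)
  ws <- newWorkspace(params$seed_k)
  for (i in ord) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    orientations <- list(list(strand = "+", ch = ch))
    if (params$allow_revcomp)
      orientations[[2L]] <- list(strand = "-", ch = rev(chComplement(ch)))
    best <- NULL
    for (o in orientations) {
      rp <- kmerPositions(paste(o$ch, collapse = ""), params$seed_k)
      for (j in wsCandidates(ws, names(rp))) {
        ws <- wsRefresh(ws, j)
        cand <- bestPlacement(ws$cc[[j]], ws$kpos[[j]], o$ch, rp, params)
        if (!is.null(cand) &&
            (is.null(best) || cand$identity > best$identity ||
             (cand$identity == best$identity &&
              cand$overlap > best$overlap)))
          best <- list(j = j, d = cand$d, strand = o$strand,
                       ch = o$ch, identity = cand$identity,
                       overlap = cand$overlap)
      }
    }
    if (!is.null(best)) {
      ws$states[[best$j]] <- addToContigState(ws$states[[best$j]], best$ch,
                                              ids[[i]], best$strand, best$d)
      ws <- wsInvalidate(ws, best$j)
      ws <- wsRefresh(ws, best$j)
    } else {
      ws <- wsAddContig(ws, newContigState(ch, ids[[i]]))
    }
  }
  ws <- mergeToFixedPoint(ws, params)
  finalizeContigSet(ws$states[ws$alive])
}

## contig-contig merge rounds, best overlap (longest, then identity)
## first, until no candidate pair passes the thresholds
mergeToFixedPoint <- function(ws, params) {
  repeat {
    live <- which(ws$alive)
    if (length(live) < 2L) return(ws)
    for (j in live) ws <- wsRefresh(ws, j)
    best <- NULL
    for (a in live) {
      pa <- ws$kpos[[a]]
      cand_b <- wsCandidates(ws, names(pa))
      for (b in cand_b) {
        if (b <= a) next
        for (strand in c("+", if (params$allow_revcomp) "-")) {
          chb <- if (strand == "-") rev(chComplement(ws$cc[[b]]))
                 else ws$cc[[b]]
          rp <- if (strand == "-")
                  kmerPositions(paste(chb, collapse = ""), ws$k)
                else ws$kpos[[b]]
          cand <- bestPlacement(ws$cc[[a]], ws$kpos[[a]], chb, rp, params)
          if (!is.null(cand) &&
              (is.null(best) || cand$overlap > best$overlap ||
               (cand$overlap == best$overlap &&
                cand$identity > best$identity)))
            best <- list(a = a, b = b, d = cand$d, strand = strand,
                         overlap = cand$overlap, identity = cand$identity)
        }
      }
    }
    if (is.null(best)) return(ws)
    ws$states[[best$a]] <- mergeStates(ws$states[[best$a]],
                                       ws$states[[best$b]],
                                       best$d, best$strand)
    ws$alive[best$b] <- FALSE
    ws <- wsInvalidate(ws, best$a)
  }
}

finalizeContigSet <- function(states) {
  n <- length(states)
  if (!n) {
    return(methods::new("ContigSet",
      consensus = Biostrings::DNAStringSet(character(0)),
      members = data.frame(contig_id = character(0), est_id = character(0),
                           offset = integer(0), strand = character(0),
                           width = integer(0), stringsAsFactors = FALSE)))
  }
  cons <- vapply(states, function(st)
    paste(consensusFromCounts(st$counts), collapse = ""), character(1))
  nm <- vapply(states, function(st) nrow(st$members), integer(1))
  first <- vapply(states, function(st) min(st$members$est_id), character(1))
  ord <- order(-nm, -nchar(cons), first)
  ids <- sprintf("CTG%05d", seq_len(n))
  members <- do.call(rbind, lapply(seq_len(n), function(r) {
    st <- states[[ord[[r]]]]
    cbind(data.frame(contig_id = ids[[r]], stringsAsFactors = FALSE),
          st$members)
  }))
  rownames(members) <- NULL
  methods::new("ContigSet",
               consensus = stats::setNames(
                 Biostrings::DNAStringSet(cons[ord]), ids),
               members = members)
}

#' Redundancy statistics of an assembly
#'
#' @param contigs a \link{ContigSet}, or an integer vector of per-contig
#'   EST counts.
#' @param n_ests_total total number of assembled ESTs; must equal the sum
#'   of per-contig counts (integrity check).
#' @param contig_lengths optional consensus lengths (taken from the
#'   \code{ContigSet} when available).
#' @return a one-row \code{data.frame}: \code{n_contigs},
#'   \code{n_singletons}, \code{singleton_fraction} (singleton contigs /
#'   all contigs), \code{two_member_fraction}, \code{mean_ests_per_contig},
#'   \code{median_contig_len}, \code{n_contigs_gt20} (contigs with more
#'   than 20 ESTs) and \code{ests_in_gt20}.
#' @export
contigStats <- function(contigs, n_ests_total = NULL,
                        contig_lengths = NULL) {
  if (methods::is(contigs, "ContigSet")) {
    counts <- estsPerContig(contigs)
    contig_lengths <- Biostrings::width(consensusSeqs(contigs))
  } else {
    counts <- as.integer(contigs)
  }
  if (is.null(n_ests_total)) n_ests_total <- sum(counts)
  if (sum(counts) != n_ests_total)
    stop("integrity error: per-contig EST counts sum to ", sum(counts),
         ", not n_ests_total = ", n_ests_total, call. = FALSE)
  n <- length(counts)
  data.frame(
    n_contigs = n,
    n_singletons = sum(counts == 1L),
    singleton_fraction = if (n) sum(counts == 1L) / n else NA_real_,
    two_member_fraction = if (n) sum(counts == 2L) / n else NA_real_,
    mean_ests_per_contig = if (n) n_ests_total / n else NA_real_,
    median_contig_len = if (!is.null(contig_lengths) && length(contig_lengths))
      stats::median(contig_lengths) else NA_real_,
    n_contigs_gt20 = sum(counts > 20L),
    ests_in_gt20 = sum(counts[counts > 20L]))
}

#' Write contigs (FASTA) and membership (TSV)
#'
#' @param contigs a \link{ContigSet}.
#' @param fasta_path,members_path output paths.
#' @export
writeContigs <- function(contigs, fasta_path, members_path) {
  Biostrings::writeXStringSet(consensusSeqs(contigs), fasta_path)
  utils::write.table(contigMembers(contigs), members_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
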