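## Two-route mapping between a dataset's contigs and a comparator
## species' deregulated sequences: direct nucleotide hits plus shared
## protein identifiers, with union coverage over comparator proteins.

#' Direct-hit links between datasets
#'
#' One link per distinct (contig, comparator sequence) pair with a hit
#' passing the e-value cutoff; the evidence is the pair's smallest
#' e-value.
#'
#' @param hit_table cross-dataset hit table (\code{qseqid} = contig,
#'   \code{sseqid} = comparator id).
#' @param e_cutoff e-value cutoff (default 1e-05; hits with
#'   \code{e < e_cutoff} qualify).
#' @param comparator_proteins optional \code{data.frame}
#'   (\code{comparator_id}, \code{protein_id}) attaching the comparator's
#'   protein identifier to each link.
#' @return \code{data.frame}: \code{newt_id}, \code{comparator_id},
#'   \code{route = "direct_hit"}, \code{evidence} (e-value as character),
#'   and \code{comparator_protein} when a mapping was given.
#' @export
directMatch <- function(hit_table, e_cutoff = 1e-05,
                        comparator_proteins = NULL) {
  h <- hit_table[hit_table$evalue < e_cutoff, , drop = FALSE]
  if (!nrow(h)) {
    out <- data.frame(newt_id = character(0), comparator_id = character(0),
                      route = character(0), evidence = character(0),
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(h$qseqid, h$sseqid, sep = "\r")
    best <- tapply(h$evalue, key, min)
    parts <- strsplit(names(best), "\r", fixed = TRUE)
    out <- data.frame(newt_id = vapply(parts, `[[`, character(1), 1L),
                      comparator_id = vapply(parts, `[[`, character(1), 2L),
                      route = "direct_hit",
                      evidence = format(unname(best), digits = 3),
                      stringsAsFactors = FALSE)
    out <- out[order(out$newt_id, out$comparator_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(comparator_proteins))
    out$comparator_protein <- comparator_proteins$protein_id[
      match(out$comparator_id, comparator_proteins$comparator_id)]
  out
}

#' Shared-protein-identifier links between datasets
#'
#' Links every (contig, comparator sequence) pair whose assigned protein
#' identifiers intersect; pairs already covered by direct hits are
#' excluded when \code{exclude} is given.
#'
#' @param ids_a \code{data.frame} (\code{newt_id}, \code{protein_id}).
#' @param ids_b \code{data.frame} (\code{comparator_id},
#'   \code{protein_id}).
#' @param exclude optional \code{data.frame} of links (with
#'   \code{newt_id}, \code{comparator_id}) to omit, typically the
#'   \code{\link{directMatch}} output.
#' @return \code{data.frame}: \code{newt_id}, \code{comparator_id},
#'   \code{route = "shared_identifier"}, \code{evidence} (the shared
#'   protein identifier), \code{comparator_protein}.
#' @export
identifierMatch <- function(ids_a, ids_b, exclude = NULL) {
  m <- merge(ids_a, ids_b, by = "protein_id")
  if (!nrow(m)) {
    return(data.frame(newt_id = character(0), comparator_id = character(0),
                      route = character(0), evidence = character(0),
                      comparator_protein = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(newt_id = m$newt_id, comparator_id = m$comparator_id,
                    route = "shared_identifier", evidence = m$protein_id,
                    comparator_protein = m$protein_id,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- paste(out$newt_id, out$comparator_id) %in%
      paste(exclude$newt_id, exclude$comparator_id)
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[order(out$newt_id, out$comparator_id, out$evidence), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union coverage of comparator proteins over both routes
#'
#' Counts the distinct comparator proteins covered by either link route.
#' Links carry their comparator protein in \code{comparator_protein}
#' where known; links without one are counted by \code{comparator_id}.
#'
#' @param direct_links,identifier_links link \code{data.frame}s.
#' @param n_comparator_proteins denominator: comparator proteins with an
#'   identifier.
#' @return \code{data.frame}: \code{n_direct}, \code{n_identifier},
#'   \code{n_covered}, \code{fraction}.
#' @export
unionCoverage <- function(direct_links, identifier_links,
                          n_comparator_proteins) {
  keyOf <- function(links) {
    if (!nrow(links)) return(character(0))
    if ("comparator_protein" %in% names(links)) {
      k <- links$comparator_protein
      k[is.na(k)] <- links$comparator_id[is.na(k)]
      unique(k)
    } else unique(links$comparator_id)
  }
  kd <- keyOf(direct_links); ki <- keyOf(identifier_links)
  covered <- union(kd, ki)
  data.frame(n_direct = length(kd), n_identifier = length(ki),
             n_covered = length(covered),
             fraction = length(covered) / n_comparator_proteins)
}
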