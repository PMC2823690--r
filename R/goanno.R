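## GO annotation: OBO parsing, protein-identifier assignment from protein
## hits, true-path propagation to ancestors, and the domain / taxon
## summaries.

#' Parse an OBO file into a GODag
#'
#' Supports the format-version 1.2 subset used throughout the package:
#' \code{[Term]} stanzas with \code{id}, \code{name}, \code{namespace}
#' and \code{is_a} (trailing \code{! comments} stripped). Obsolete terms
#' are dropped. A cycle is a format error naming the terms involved.
#'
#' @param path OBO file.
#' @return a \link{GODag}.
#' @export
readObo <- function(path) {
  lines <- readLines(path)
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || isTRUE(cur$obsolete)) return()
    if (is.null(cur$id) || is.null(cur$namespace))
      stop("OBO term stanza missing id or namespace", call. = FALSE)
    ids <<- c(ids, cur$id)
    nms <<- c(nms, cur$name %||% cur$id)
    nss <<- c(nss, cur$namespace)
    parents[[cur$id]] <<- cur$is_a %||% character(0)
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", trimws(ln))
    if (ln == "[Term]") { flush(); cur <- list(); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) next
    key <- kv[[2L]]; val <- trimws(kv[[3L]])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
  }
  flush()
  ## drop is_a references to dropped (obsolete/unknown) terms
  parents <- lapply(parents, function(p) p[p %in% ids])
  dag <- methods::new("GODag",
                      terms = data.frame(id = ids, name = nms,
                                         namespace = nss,
                                         stringsAsFactors = FALSE),
                      parents = parents[ids])
  dag
}

#' Write a GODag as OBO (format-version 1.2 subset)
#'
#' Deterministic: terms in their table order. Round-trips through
#' \code{\link{readObo}}.
#'
#' @param dag a \link{GODag}.
#' @param path output file.
#' @export
writeObo <- function(dag, path) {
  t <- goTerms(dag)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(t))) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t$id[[i]]), con)
    writeLines(paste0("name: ", t$name[[i]]), con)
    writeLines(paste0("namespace: ", t$namespace[[i]]), con)
    for (p in goParents(dag)[[t$id[[i]]]])
      writeLines(paste0("is_a: ", p), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Length-normalized alignment significance score (sigma units)
#'
#' A z-like heuristic: the bitscore is compared against a
#' log2-length-scaled background expectation and expressed in units of 4
#' bits. Used as the alternative gate for protein-identifier assignment;
#' the primary gate is the e-value cutoff.
#'
#' @param bitscore alignment bitscore.
#' @param q_len,s_len query and subject aligned lengths.
#' @return numeric score in sigma units.
#' @export
abagyanScore <- function(bitscore, q_len, s_len) {
  (bitscore - log2(pmax(1, as.numeric(q_len) * as.numeric(s_len)))) / 4
}

#' GO-assignment configuration
#'
#' @param e_cutoff e-value gate (a hit qualifies when
#'   \code{e <= e_cutoff}).
#' @param sigma_cutoff alternative gate on the normalized score.
#' @param top_k at most this many identifiers per query, in hit-rank
#'   order.
#' @param score_fun function \code{(bitscore, q_len, s_len) -> sigma};
#'   defaults to \code{\link{abagyanScore}}.
#' @return a \code{list} of class \code{"GoAssignConfig"}.
#' @export
goAssignConfig <- function(e_cutoff = 1e-20, sigma_cutoff = 15,
                           top_k = 50L, score_fun = abagyanScore) {
  if (e_cutoff <= 0) stop("e_cutoff must be > 0", call. = FALSE)
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  structure(list(e_cutoff = e_cutoff, sigma_cutoff = sigma_cutoff,
                 top_k = as.integer(top_k), score_fun = score_fun),
            class = "GoAssignConfig")
}

#' Assign ranked protein identifiers to queries from protein hits
#'
#' A hit qualifies when its e-value passes the cutoff OR its normalized
#' score reaches the sigma threshold. Qualifying subject identifiers are
#' kept per query in hit-rank order (ascending e-value, ties by higher
#' bitscore then subject id), deduplicated, at most \code{top_k}.
#'
#' @param protein_hits a hit table of protein-database searches.
#' @param config a \code{\link{goAssignConfig}}.
#' @return named list: query id -> character vector of protein ids.
#' @export
assignProteinIds <- function(protein_hits, config = goAssignConfig()) {
  if (!nrow(protein_hits)) return(stats::setNames(list(), character(0)))
  h <- protein_hits
  qlen <- h$qend - h$qstart + 1L
  slen <- h$send - h$sstart + 1L
  sigma <- config$score_fun(h$bitscore, qlen, slen)
  ok <- h$evalue <= config$e_cutoff | sigma >= config$sigma_cutoff
  h <- h[ok, , drop = FALSE]
  if (!nrow(h)) return(stats::setNames(list(), character(0)))
  h <- h[orderHits(h), , drop = FALSE]
  lapply(split(h$sseqid, h$qseqid), function(s)
    utils::head(unique(s), config$top_k))
}

#' Propagate direct annotations to all ancestors (true-path rule)
#'
#' Every protein directly annotated to a term is implicitly annotated to
#' all of the term's ancestors, up to its namespace root. Counts are of
#' distinct proteins: a protein reached through several descendants is
#' counted once per term.
#'
#' @param dag a \link{GODag}.
#' @param direct either a GAF-like \code{data.frame} with columns
#'   \code{protein_id} and \code{go_id}, or a named list term id ->
#'   character vector of protein ids.
#' @return an \link{AnnotationSet}.
#' @export
propagateAnnotations <- function(dag, direct) {
  if (is.data.frame(direct)) {
    direct <- lapply(split(direct$protein_id, direct$go_id), unique)
  }
  ids <- goTerms(dag)$id
  unknown <- setdiff(names(direct), ids)
  if (length(unknown))
    stop("direct annotations reference unknown term id(s): ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  dmap <- stats::setNames(vector("list", length(ids)), ids)
  for (t in names(direct)) dmap[[t]] <- unique(direct[[t]])
  ## children before parents: reverse topological order
  ord <- rev(topoSortTerms(dag))
  children <- goChildrenList(dag)
  pmap <- stats::setNames(vector("list", length(ids)), ids)
  for (t in ord) {
    acc <- dmap[[t]]
    for (c in children[[t]] %||% character(0))
      acc <- c(acc, pmap[[c]])
    pmap[[t]] <- unique(acc) %||% character(0)
  }
  dmap <- lapply(dmap, function(x) x %||% character(0))
  methods::new("AnnotationSet", direct = dmap, propagated = pmap,
               roots = goRoots(dag))
}

#' Domain and taxon summaries of an annotation set
#'
#' @param annotation an \link{AnnotationSet}.
#' @param dag the \link{GODag} it was built on.
#' @param taxon_classes optional named character vector protein id ->
#'   taxon class, to tabulate the GO-annotated proteins by taxon.
#' @return list with \code{domains} (\code{data.frame}: namespace,
#'   \code{n_terms} with direct annotations, \code{n_proteins} under the
#'   root) and \code{taxa} (\code{data.frame} taxon_class / count /
#'   percentage of the GO-annotated total, or \code{NULL}).
#' @export
summaryCounts <- function(annotation, dag, taxon_classes = NULL) {
  t <- goTerms(dag)
  nd <- lengths(annotation@direct)
  domains <- do.call(rbind, lapply(GO_NAMESPACES, function(ns) {
    in_ns <- t$id[t$namespace == ns]
    data.frame(namespace = ns,
               n_terms = sum(nd[in_ns] > 0L),
               n_proteins = length(
                 annotation@propagated[[annotation@roots[[ns]]]] %||%
                   character(0)),
               stringsAsFactors = FALSE)
  }))
  taxa <- NULL
  if (!is.null(taxon_classes)) {
    prots <- unique(unlist(annotation@direct, use.names = FALSE))
    cls <- taxon_classes[prots]
    cls[is.na(cls)] <- "other"
    n <- length(prots)
    tab <- sort(table(cls), decreasing = TRUE)
    taxa <- data.frame(taxon_class = c("All Organisms", names(tab)),
                       count = c(n, as.integer(tab)),
                       stringsAsFactors = FALSE)
    taxa$percentage <- if (n) 100 * taxa$count / n else NA_real_
  }
  list(domains = domains, taxa = taxa)
}
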