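#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' ContigSet: assembled contigs with EST membership
#'
#' Container for the output of \code{\link{greedyAssemble}}: a consensus
#' sequence per contig plus a membership table recording, for every EST,
#' the contig it was placed in, its 1-based offset on the consensus, its
#' strand and its length.
#'
#' @slot consensus a \link[Biostrings]{DNAStringSet} of contig consensus
#'   sequences, named by contig id.
#' @slot members a \code{data.frame} with columns \code{contig_id},
#'   \code{est_id}, \code{offset}, \code{strand} (\code{"+"}/\code{"-"})
#'   and \code{width}.
#' @exportClass ContigSet
setClass("ContigSet",
  representation(consensus = "DNAStringSet", members = "data.frame"))

setValidity("ContigSet", function(object) {
  m <- object@members
  need <- c("contig_id", "est_id", "offset", "strand", "width")
  if (!all(need %in% names(m)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  ids <- names(object@consensus)
  if (anyDuplicated(ids)) return("duplicate contig ids")
  if (nrow(m)) {
    if (!all(m$contig_id %in% ids))
      return("membership references unknown contig ids")
    if (anyDuplicated(m$est_id))
      return("an EST may belong to exactly one contig")
    lens <- Biostrings::width(object@consensus)[match(m$contig_id, ids)]
    if (any(m$offset < 1L) || any(m$offset + m$width - 1L > lens))
      return("member aligned span must lie within its consensus")
  }
  if (length(setdiff(ids, m$contig_id)))
    return("every contig must have at least one member")
  TRUE
})

#' @describeIn ContigSet number of contigs
#' @param x,object a \code{ContigSet}
#' @export
setMethod("length", "ContigSet", function(x) length(x@consensus))

#' Accessors for ContigSet
#'
#' @param x a \code{ContigSet}.
#' @return \code{consensusSeqs} returns the consensus
#'   \link[Biostrings]{DNAStringSet}; \code{contigMembers} the membership
#'   \code{data.frame}; \code{estsPerContig} a named integer vector of EST
#'   counts per contig.
#' @export
consensusSeqs <- function(x) x@consensus

#' @rdname consensusSeqs
#' @export
contigMembers <- function(x) x@members

#' @rdname consensusSeqs
#' @export
estsPerContig <- function(x) {
  tab <- table(factor(x@members$contig_id, levels = names(x@consensus)))
  stats::setNames(as.integer(tab), names(tab))
}

setMethod("show", "ContigSet", function(object) {
  n <- length(object)
  ne <- nrow(object@members)
  cat(sprintf("ContigSet with %d contig%s from %d EST%s\n",
              n, if (n == 1) "" else "s", ne, if (ne == 1) "" else "s"))
  if (n) {
    w <- Biostrings::width(object@consensus)
    cat(sprintf("  consensus length: median %d nt [%d-%d]\n",
                as.integer(stats::median(w)), min(w), max(w)))
    cat(sprintf("  singletons: %d\n", sum(estsPerContig(object) == 1L)))
  }
})

#' GODag: a Gene Ontology directed acyclic graph (is_a edges)
#'
#' Terms from the three GO namespaces (biological_process,
#' molecular_function, cellular_component) linked by \code{is_a} edges.
#' Each namespace has a single root; every non-root term has at least one
#' parent in the same namespace and the graph is acyclic.
#'
#' @slot terms \code{data.frame} with columns \code{id}, \code{name},
#'   \code{namespace}.
#' @slot parents named \code{list}: term id -> character vector of parent
#'   ids (empty for roots).
#' @exportClass GODag
setClass("GODag", representation(terms = "data.frame", parents = "list"))

GO_NAMESPACES <- c("biological_process", "molecular_function",
                   "cellular_component")

setValidity("GODag", function(object) {
  t <- object@terms
  if (!all(c("id", "name", "namespace") %in% names(t)))
    return("terms must have columns id, name, namespace")
  if (anyDuplicated(t$id)) return("duplicate term ids")
  if (!all(t$namespace %in% GO_NAMESPACES))
    return("unknown namespace")
  if (!setequal(names(object@parents), t$id))
    return("parents list must cover exactly the term ids")
  allp <- unlist(object@parents, use.names = FALSE)
  if (length(allp) && !all(allp %in% t$id))
    return("parent ids must be known terms")
  ns <- stats::setNames(t$namespace, t$id)
  for (id in t$id) {
    p <- object@parents[[id]]
    if (length(p) && any(ns[p] != ns[[id]]))
      return("parents must share the term's namespace")
  }
  ## acyclicity via Kahn's algorithm
  if (is.character(topoSortTerms(object, check_only = TRUE)))
    return(topoSortTerms(object, check_only = TRUE))
  TRUE
})

## topological order (parents after children is NOT guaranteed here; this
## returns an order in which every term appears after all its parents).
## With check_only=TRUE returns a message string when a cycle exists.
topoSortTerms <- function(dag, check_only = FALSE) {
  ids <- dag@terms$id
  indeg <- stats::setNames(lengths(dag@parents[ids]), ids)
  children <- goChildrenList(dag)
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (c in children[[v]] %||% character(0)) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) != length(ids)) {
    bad <- setdiff(ids, out)
    msg <- paste("cycle detected involving terms:",
                 paste(utils::head(bad, 10L), collapse = ", "))
    return(if (check_only) msg else stop(msg, call. = FALSE))
  }
  if (check_only) TRUE else out
}

goChildrenList <- function(dag) {
  ch <- vector("list", nrow(dag@terms))
  names(ch) <- dag@terms$id
  for (id in names(dag@parents)) {
    for (p in dag@parents[[id]]) ch[[p]] <- c(ch[[p]], id)
  }
  ch
}

#' Accessors for GODag
#'
#' @param dag a \code{GODag}.
#' @return \code{goTerms}: the term \code{data.frame}; \code{goParents}:
#'   the named parent list; \code{goRoots}: named character vector mapping
#'   namespace to its root term id.
#' @export
goTerms <- function(dag) dag@terms

#' @rdname goTerms
#' @export
goParents <- function(dag) dag@parents

#' @rdname goTerms
#' @export
goRoots <- function(dag) {
  t <- dag@terms
  r <- t$id[lengths(dag@parents[t$id]) == 0L]
  stats::setNames(r, t$namespace[match(r, t$id)])
}

#' All ancestors of GO terms (true-path closure)
#'
#' @param dag a \code{GODag}.
#' @param ids term ids; default all terms.
#' @param include_self include the term itself in its ancestor set.
#' @return named list: term id -> character vector of ancestor ids.
#' @export
goAncestors <- function(dag, ids = goTerms(dag)$id, include_self = FALSE) {
  ord <- topoSortTerms(dag)   # parents before children
  anc <- vector("list", length(ord)); names(anc) <- ord
  for (id in ord) {
    ps <- dag@parents[[id]]
    anc[[id]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  res <- anc[ids]
  if (include_self) res <- mapply(function(a, i) unique(c(i, a)),
                                  res, ids, SIMPLIFY = FALSE)
  res
}

setMethod("show", "GODag", function(object) {
  t <- object@terms
  cat(sprintf("GODag with %d terms, %d is_a edges\n",
              nrow(t), sum(lengths(object@parents))))
  for (ns in GO_NAMESPACES)
    cat(sprintf("  %s: %d terms\n", ns, sum(t$namespace == ns)))
})

#' AnnotationSet: direct and true-path-propagated GO annotations
#'
#' Maps each GO term to the set of distinct protein identifiers annotated
#' to it, both directly and after propagation to all ancestors (the
#' true-path rule). Built by \code{\link{propagateAnnotations}}.
#'
#' @slot direct named list: term id -> character vector of protein ids.
#' @slot propagated named list: term id -> character vector of protein ids
#'   (superset of \code{direct}).
#' @slot roots named character vector: namespace -> root term id.
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(direct = "list", propagated = "list", roots = "character"))

setValidity("AnnotationSet", function(object) {
  if (!setequal(names(object@direct), names(object@propagated)))
    return("direct and propagated must cover the same terms")
  for (id in names(object@direct)) {
    if (!all(object@direct[[id]] %in% object@propagated[[id]]))
      return("direct annotations must be contained in propagated")
  }
  TRUE
})

#' Accessors for AnnotationSet
#'
#' @param x an \code{AnnotationSet}.
#' @param term a term id.
#' @return \code{directProteins}/\code{propagatedProteins}: character
#'   vector of protein ids at \code{term}; \code{annotatedProteinCount}:
#'   distinct proteins under the given namespace root (defaults to
#'   biological_process), i.e. the denominator N of fold accumulation.
#' @export
directProteins <- function(x, term) x@direct[[term]] %||% character(0)

#' @rdname directProteins
#' @export
propagatedProteins <- function(x, term) x@propagated[[term]] %||% character(0)

#' @rdname directProteins
#' @param namespace one of the three GO namespaces.
#' @export
annotatedProteinCount <- function(x, namespace = "biological_process") {
  root <- x@roots[[namespace]]
  if (is.null(root)) stop("no root recorded for namespace ", namespace)
  length(x@propagated[[root]] %||% character(0))
}

setMethod("show", "AnnotationSet", function(object) {
  nd <- sum(lengths(object@direct) > 0L)
  cat(sprintf("AnnotationSet: %d terms with direct annotations (of %d)\n",
              nd, length(object@direct)))
  for (ns in names(object@roots))
    cat(sprintf("  proteins under %s root: %d\n", ns,
                length(object@propagated[[object@roots[[ns]]]])))
})
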