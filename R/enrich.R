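## Fold-accumulation GO enrichment against a baseline annotation corpus,
## with Pearson chi-square significance (df = 1, no continuity
## correction) and minimum-count screening.

#' Fold accumulation of a GO term: dataset vs baseline
#'
#' fold = (k_ds / N_ds) / (k_base / N_base), where k counts distinct
#' proteins under the term (true-path propagated) and N counts proteins
#' under the namespace root (biological_process by default).
#' \code{k_base = 0} yields an infinite fold with \code{defined = FALSE}.
#'
#' @param annotation_ds,annotation_base \link{AnnotationSet}s of the
#'   dataset and the baseline.
#' @param term a GO term id (vectorized).
#' @param namespace root namespace used for the denominators.
#' @return \code{data.frame}: \code{term}, \code{k_ds}, \code{N_ds},
#'   \code{k_base}, \code{N_base}, \code{fold}, \code{defined}.
#' @export
foldAccumulation <- function(annotation_ds, annotation_base, term,
                             namespace = "biological_process") {
  N_ds <- annotatedProteinCount(annotation_ds, namespace)
  N_base <- annotatedProteinCount(annotation_base, namespace)
  if (N_ds == 0L || N_base == 0L)
    stop("undefined ratio: no proteins under the ", namespace, " root",
         call. = FALSE)
  k_ds <- vapply(term, function(t)
    length(propagatedProteins(annotation_ds, t)), integer(1))
  k_base <- vapply(term, function(t)
    length(propagatedProteins(annotation_base, t)), integer(1))
  fold <- ifelse(k_base > 0, (k_ds / N_ds) / (k_base / N_base), Inf)
  data.frame(term = term, k_ds = k_ds, N_ds = N_ds, k_base = k_base,
             N_base = N_base, fold = fold, defined = k_base > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson chi-square test on the 2x2 in-term / dataset table
#'
#' The table is (k, N - k) for dataset and baseline; the statistic is the
#' plain Pearson chi-square without continuity correction, df = 1, with
#' the p-value from the upper chi-square tail. Degenerate margins (an
#' all-zero row or column) give \code{computable = FALSE} rather than an
#' error.
#'
#' @param k_ds,N_ds,k_base,N_base counts (vectorized).
#' @return \code{data.frame}: \code{chi2}, \code{p_value}, \code{df},
#'   \code{computable}.
#' @export
chiSquare2x2 <- function(k_ds, N_ds, k_base, N_base) {
  if (any(k_ds > N_ds) || any(k_base > N_base) ||
      any(c(k_ds, N_ds, k_base, N_base) < 0))
    stop("counts must satisfy 0 <= k <= N", call. = FALSE)
  a <- as.numeric(k_ds); b <- as.numeric(N_ds) - a
  c <- as.numeric(k_base); d <- as.numeric(N_base) - c
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  chi2 <- rep(NA_real_, length(a))
  ## closed form for 2x2: n (ad - bc)^2 / (r1 r2 c1 c2)
  chi2[ok] <- (n[ok] * (a[ok] * d[ok] - b[ok] * c[ok])^2) /
    (r1[ok] * r2[ok] * c1[ok] * c2[ok])
  p <- ifelse(ok, stats::pchisq(chi2, df = 1, lower.tail = FALSE), NA_real_)
  data.frame(chi2 = chi2, p_value = p, df = 1L, computable = ok)
}

#' Enrichment filter: minimum counts and fold threshold
#'
#' @param min_counts integer vector of per-dataset minimum protein
#'   counts; the first applies to \code{k_ds}, an optional second to a
#'   \code{k_ds2} column when two datasets are screened jointly. The
#'   defaults (8, 3) keep terms with at least 8 dataset-A and 3
#'   dataset-B proteins.
#' @param fold_threshold minimum fold accumulation (default 10).
#' @return a \code{list} of class \code{"EnrichFilter"}.
#' @export
enrichFilter <- function(min_counts = c(8L, 3L), fold_threshold = 10) {
  if (any(min_counts < 0)) stop("min_counts must be >= 0", call. = FALSE)
  if (fold_threshold <= 0) stop("fold_threshold must be > 0", call. = FALSE)
  structure(list(min_counts = as.integer(min_counts),
                 fold_threshold = fold_threshold),
            class = "EnrichFilter")
}

#' Flag enriched terms
#'
#' \code{enriched = passes_counts AND fold >= fold_threshold}, where
#' \code{passes_counts} applies the per-dataset minimum-count rule to
#' \code{k_ds} (and to \code{k_ds2} when that column is present and a
#' second minimum is configured).
#'
#' @param results a \code{data.frame} with at least \code{k_ds} and
#'   \code{fold} (e.g. from \code{\link{goEnrichment}}).
#' @param filter an \code{\link{enrichFilter}}.
#' @return \code{results} with added \code{passes_counts} and
#'   \code{enriched} columns.
#' @export
selectEnriched <- function(results, filter = enrichFilter()) {
  pc <- results$k_ds >= filter$min_counts[[1L]]
  if (length(filter$min_counts) >= 2L && "k_ds2" %in% names(results))
    pc <- pc & results$k_ds2 >= filter$min_counts[[2L]]
  results$passes_counts <- pc
  results$enriched <- pc & !is.na(results$fold) &
    results$fold >= filter$fold_threshold
  results
}

#' Full enrichment table for a set of terms
#'
#' Combines \code{\link{foldAccumulation}}, \code{\link{chiSquare2x2}}
#' and \code{\link{selectEnriched}}. Optionally a Bonferroni/BH adjusted
#' p-value column is appended (off by default; the primary output is the
#' per-term chi-square p-value).
#'
#' @param annotation_ds,annotation_base \link{AnnotationSet}s.
#' @param dag the \link{GODag}.
#' @param terms term ids to evaluate; default: all terms with at least
#'   one dataset protein in the requested namespace.
#' @param filter an \code{\link{enrichFilter}}.
#' @param namespace root namespace for denominators.
#' @param p_adjust \code{"none"} (default), \code{"bonferroni"} or
#'   \code{"BH"}.
#' @return \code{data.frame}: term, name, counts, fold, chi2, p_value,
#'   passes_counts, enriched (plus \code{p_adjusted} when requested).
#' @export
goEnrichment <- function(annotation_ds, annotation_base, dag,
                         terms = NULL, filter = enrichFilter(),
                         namespace = "biological_process",
                         p_adjust = c("none", "bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  t <- goTerms(dag)
  if (is.null(terms)) {
    in_ns <- t$id[t$namespace == namespace]
    terms <- in_ns[vapply(in_ns, function(x)
      length(propagatedProteins(annotation_ds, x)) > 0L, logical(1))]
  }
  fa <- foldAccumulation(annotation_ds, annotation_base, terms, namespace)
  cs <- chiSquare2x2(fa$k_ds, fa$N_ds, fa$k_base, fa$N_base)
  out <- cbind(fa, cs)
  out$name <- t$name[match(out$term, t$id)]
  out <- selectEnriched(out, filter)
  if (p_adjust != "none")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out[order(-out$fold, out$term), ]
}
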