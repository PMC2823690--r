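## RT-PCR densitometry analysis: control-gene normalization, fold change
## versus the undamaged (day 0) baseline, paired t-tests across
## biological pools, and symmetric two-fold flagging.

#' Control-normalized fold-change profiles
#'
#' Each intensity is divided by the control-gene intensity of the same
#' timepoint and pool; the fold at timepoint t is the mean normalized
#' value at t over the mean normalized value at day 0. Rows whose control
#' intensity is zero are excluded with a warning.
#'
#' @param table densitometry \code{data.frame}: \code{gene},
#'   \code{timepoint}, \code{pool}, \code{intensity}.
#' @param control_gene name of the non-modulated control gene; must be
#'   present at every (timepoint, pool).
#' @param baseline_timepoint the reference day (default 0).
#' @return \code{data.frame} per gene and timepoint: \code{fold} (1 at
#'   the baseline by construction), \code{sd} of the per-pool fold, and
#'   \code{n_pools}.
#' @export
foldChangeProfile <- function(table, control_gene,
                              baseline_timepoint = 0) {
  norm <- normalizeToControl(table, control_gene)
  genes <- setdiff(unique(norm$gene), control_gene)
  out <- list()
  for (g in genes) {
    sub <- norm[norm$gene == g, , drop = FALSE]
    base <- sub$value[sub$timepoint == baseline_timepoint]
    if (!length(base))
      stop("gene ", g, " has no baseline (day ", baseline_timepoint,
           ") measurements", call. = FALSE)
    mb <- mean(base)
    for (tp in sort(unique(sub$timepoint))) {
      v <- sub$value[sub$timepoint == tp]
      out[[length(out) + 1L]] <- data.frame(
        gene = g, timepoint = tp, fold = mean(v) / mb,
        sd = stats::sd(v / mb), n_pools = length(v),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

normalizeToControl <- function(table, control_gene) {
  ctrl <- table[table$gene == control_gene, , drop = FALSE]
  if (!nrow(ctrl))
    stop("control gene ", control_gene, " not found", call. = FALSE)
  key <- function(df) paste(df$timepoint, df$pool)
  cmap <- stats::setNames(ctrl$intensity, key(ctrl))
  cv <- cmap[key(table)]
  if (any(is.na(cv)))
    stop("control gene missing at some (timepoint, pool)", call. = FALSE)
  zero <- !is.na(cv) & cv == 0
  if (any(zero)) {
    warning(sum(zero), " row(s) excluded: zero control intensity")
    table <- table[!zero, , drop = FALSE]
    cv <- cv[!zero]
  }
  data.frame(gene = table$gene, timepoint = table$timepoint,
             pool = table$pool, value = table$intensity / cv,
             stringsAsFactors = FALSE)
}

#' Paired t-tests and two-fold flags per gene and timepoint
#'
#' For each gene and non-baseline timepoint, a two-sided paired t-test of
#' the control-normalized values against day 0, paired by pool index.
#' \code{flagged_2fold} marks symmetric fold changes (fold >=
#' \code{fold_cut} or <= 1/\code{fold_cut}); significance is reported
#' separately. Fewer than two complete pairs give \code{p_value = NA}.
#'
#' @param table densitometry \code{data.frame} (see
#'   \code{\link{foldChangeProfile}}).
#' @param control_gene the non-modulated control gene.
#' @param alpha significance level (default 0.05).
#' @param fold_cut symmetric fold threshold (default 2).
#' @param baseline_timepoint reference day (default 0).
#' @return \code{data.frame}: gene, timepoint, fold, sd, p_value,
#'   flagged_2fold, significant.
#' @export
pairedTTestFlag <- function(table, control_gene, alpha = 0.05,
                            fold_cut = 2.0, baseline_timepoint = 0) {
  prof <- foldChangeProfile(table, control_gene, baseline_timepoint)
  norm <- normalizeToControl(table, control_gene)
  prof$p_value <- NA_real_
  for (i in seq_len(nrow(prof))) {
    g <- prof$gene[[i]]; tp <- prof$timepoint[[i]]
    if (tp == baseline_timepoint) { prof$p_value[[i]] <- NA_real_; next }
    sub <- norm[norm$gene == g, , drop = FALSE]
    b <- sub[sub$timepoint == baseline_timepoint, ]
    v <- sub[sub$timepoint == tp, ]
    pools <- intersect(b$pool, v$pool)
    if (length(pools) < 2L) next
    x <- v$value[match(pools, v$pool)]
    y <- b$value[match(pools, b$pool)]
    d <- x - y
    if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, mean(abs(y)))) {
      ## degenerate paired differences: no variance to test against
      prof$p_value[[i]] <- if (isTRUE(all.equal(mean(d), 0))) 1 else 0
      next
    }
    prof$p_value[[i]] <- stats::t.test(x, y, paired = TRUE)$p.value
  }
  prof$flagged_2fold <- prof$fold >= fold_cut | prof$fold <= 1 / fold_cut
  prof$significant <- !is.na(prof$p_value) & prof$p_value < alpha
  prof
}
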