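#' Cis-target genes of a lncRNA
#'
#' mRNAs whose genomic span overlaps the lncRNA span extended by `window`
#' bp on each side (half-open arithmetic: a gap of exactly `window` bp is
#' excluded, `window - 1` bp is included). Strand-agnostic.
#'
#' @param lncrna_id A lncRNA transcript id in `catalog`.
#' @param catalog A `TranscriptCatalog`.
#' @param window Window size in bp (default 10000).
#' @return Character vector of mRNA transcript ids, sorted.
#' @export
find_cis_targets <- function(lncrna_id, catalog, window = 10000) {
  stopifnot(inherits(catalog, "TranscriptCatalog"))
  if (window < 0) stop("negative window")
  tx <- catalog$transcripts
  i <- match(lncrna_id, tx$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", lncrna_id)
  lo <- tx$start[i] - window
  hi <- tx$end[i] + window
  hit <- tx$biotype == "mRNA" & tx$chrom == tx$chrom[i] &
    tx$start < hi & tx$end > lo
  sort(tx$transcript_id[hit])
}

#' Trans-target genes of a lncRNA by expression correlation
#'
#' mRNAs whose expression profile correlates with the lncRNA's at
#' `|Pearson r| >= threshold` across shared samples (sign retained;
#' `positive_only = TRUE` restricts to positive correlations). Samples with
#' non-finite values in either profile are dropped pairwise.
#'
#' @param lncrna_expr Named numeric vector: FPKM per sample for the lncRNA.
#' @param mrna_expr Numeric matrix: mRNA rows x sample columns (column
#'   names matching `names(lncrna_expr)`).
#' @param threshold Correlation threshold (default 0.9).
#' @param positive_only Keep only positive correlations (default FALSE).
#' @return data.frame `mrna_id`, `r` sorted by mrna_id.
#' @export
find_trans_targets <- function(lncrna_expr, mrna_expr, threshold = 0.9,
                               positive_only = FALSE) {
  if (is.null(rownames(mrna_expr))) stop("mrna_expr must have mRNA ids as rownames")
  common <- intersect(names(lncrna_expr), colnames(mrna_expr))
  if (length(common) < 3) stop("fewer than 3 shared samples")
  x <- lncrna_expr[common]
  m <- mrna_expr[, common, drop = FALSE]
  r <- apply(m, 1, function(y) {
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 3) return(NA_real_)
    suppressWarnings(stats::cor(x[keep], y[keep], method = "pearson"))
  })
  keep <- !is.na(r) & (if (positive_only) r >= threshold else abs(r) >= threshold)
  out <- data.frame(mrna_id = rownames(m)[keep], r = unname(r[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mrna_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen ceRNA candidate lncRNAs
#'
#' Union of (a) disease-flagged lncRNAs with methylation fold change
#' > `meth_fc_threshold` and (b) disease-flagged lncRNAs with expression
#' fold change > `expr_fc_threshold`. Infinite fold changes pass any
#' threshold. With `require_disease_flag = FALSE` the flag is ignored.
#'
#' @param diff_meth data.frame `lncrna_id`, `fold_change` (differentially
#'   methylated lncRNAs).
#' @param diff_expr data.frame `transcript_id`, `fold_change`
#'   (differentially expressed lncRNAs).
#' @param disease_flags Character vector of disease-associated lncRNA ids.
#' @param meth_fc_threshold,expr_fc_threshold Screen thresholds (defaults 7
#'   and 2.5).
#' @param require_disease_flag Require membership of `disease_flags`
#'   (default TRUE).
#' @return data.frame `lncrna_id`, `criterion` (`"methylation"`,
#'   `"expression"` or `"both"`), deduplicated and sorted by id.
#' @export
screen_cerna_candidates <- function(diff_meth, diff_expr, disease_flags,
                                    meth_fc_threshold = 7,
                                    expr_fc_threshold = 2.5,
                                    require_disease_flag = TRUE) {
  stopifnot(meth_fc_threshold > 0, expr_fc_threshold > 0)
  flagged <- function(ids) if (require_disease_flag) ids %in% disease_flags else
    rep(TRUE, length(ids))
  passes <- function(fc, thr) is.infinite(fc) | fc > thr  # Inf beats any threshold
  meth_ids <- diff_meth$lncrna_id[passes(diff_meth$fold_change, meth_fc_threshold) &
                                    flagged(diff_meth$lncrna_id)]
  expr_ids <- diff_expr$transcript_id[passes(diff_expr$fold_change, expr_fc_threshold) &
                                        flagged(diff_expr$transcript_id)]
  ids <- sort(unique(c(meth_ids, expr_ids)))
  crit <- ifelse(ids %in% meth_ids & ids %in% expr_ids, "both",
                 ifelse(ids %in% meth_ids, "methylation", "expression"))
  data.frame(lncrna_id = ids, criterion = crit, stringsAsFactors = FALSE)
}

# top-k partners of one source: score descending, partner id ascending
top_k_partners <- function(bindings, source, k) {
  b <- bindings[bindings$source_id == source, , drop = FALSE]
  b <- b[order(-b$score, b$target_id, method = "radix"), , drop = FALSE]
  utils::head(b, k)
}

#' Build the tripartite ceRNA (lncRNA-miRNA-mRNA) network
#'
#' For each screened lncRNA, its `k` highest-scoring predicted miRNAs; for
#' each selected miRNA, its `k` highest-scoring predicted mRNAs. Ties break
#' by partner id (lexicographic ascending); nodes are deduplicated across
#' lncRNAs. A lncRNA with fewer than `k` predictions contributes all it has
#' (the shortfall is reported with [message()]).
#'
#' @param screened_lncrnas Character vector of screened lncRNA ids.
#' @param lnc_mi_bindings data.frame `source_id` (lncRNA), `target_id`
#'   (miRNA), `score`.
#' @param mi_mrna_bindings data.frame `source_id` (miRNA), `target_id`
#'   (mRNA), `score`.
#' @param k Partners per node (default 5).
#' @return A `cerna_network` list with `nodes` (data.frame `id`, `type`) and
#'   `edges` (data.frame `source`, `target`, `edge_type`, `score`).
#' @export
build_cerna_network <- function(screened_lncrnas, lnc_mi_bindings,
                                mi_mrna_bindings, k = 5) {
  stopifnot(k >= 1)
  screened_lncrnas <- sort(unique(screened_lncrnas))
  e1 <- list()
  for (lnc in screened_lncrnas) {
    sel <- top_k_partners(lnc_mi_bindings, lnc, k)
    if (nrow(sel) < k) {
      message("build_cerna_network: lncRNA ", lnc, " has only ", nrow(sel),
              " predicted miRNA(s) (k = ", k, ")")
    }
    if (nrow(sel)) {
      e1[[lnc]] <- data.frame(source = lnc, target = sel$target_id,
                              edge_type = "lncRNA-miRNA", score = sel$score,
                              stringsAsFactors = FALSE)
    }
  }
  e1 <- if (length(e1)) do.call(rbind, e1) else
    data.frame(source = character(0), target = character(0),
               edge_type = character(0), score = numeric(0))
  mirnas <- sort(unique(e1$target))
  e2 <- list()
  for (mi in mirnas) {
    sel <- top_k_partners(mi_mrna_bindings, mi, k)
    if (nrow(sel)) {
      e2[[mi]] <- data.frame(source = mi, target = sel$target_id,
                             edge_type = "miRNA-mRNA", score = sel$score,
                             stringsAsFactors = FALSE)
    }
  }
  e2 <- if (length(e2)) do.call(rbind, e2) else
    data.frame(source = character(0), target = character(0),
               edge_type = character(0), score = numeric(0))
  edges <- rbind(e1, e2)
  rownames(edges) <- NULL
  nodes <- rbind(
    data.frame(id = screened_lncrnas, type = "lncRNA", stringsAsFactors = FALSE),
    data.frame(id = mirnas, type = "miRNA", stringsAsFactors = FALSE),
    data.frame(id = sort(unique(e2$target)), type = "mRNA", stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  out <- list(nodes = nodes, edges = edges)
  class(out) <- "cerna_network"
  out
}

#' @export
print.cerna_network <- function(x, ...) {
  n <- table(factor(x$nodes$type, levels = c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf("ceRNA network: %d lncRNAs, %d miRNAs, %d mRNAs; %d edges\n",
              n[["lncRNA"]], n[["miRNA"]], n[["mRNA"]], nrow(x$edges)))
  invisible(x)
}

#' Build the coding-non-coding (CNC) co-expression network
#'
#' One edge per (lncRNA, mRNA) pair with `|Pearson r| >= threshold` across
#' shared samples; the edge sign is the sign of r (`+` = positive
#' regulation, `-` = negative).
#'
#' @param lncrna_expr Numeric matrix: lncRNA rows x sample columns.
#' @param mrna_expr Numeric matrix: mRNA rows x sample columns.
#' @param threshold Correlation threshold (default 0.95).
#' @return A `cnc_network` list with `edges` (data.frame `lncrna_id`,
#'   `mrna_id`, `r`, `sign`) and `threshold`.
#' @export
build_cnc_network <- function(lncrna_expr, mrna_expr, threshold = 0.95) {
  common <- intersect(colnames(lncrna_expr), colnames(mrna_expr))
  if (length(common) < 3) stop("fewer than 3 shared samples")
  lx <- lncrna_expr[, common, drop = FALSE]
  mx <- mrna_expr[, common, drop = FALSE]
  r <- suppressWarnings(stats::cor(t(lx), t(mx), method = "pearson"))
  hit <- which(!is.na(r) & abs(r) >= threshold, arr.ind = TRUE)
  edges <- data.frame(
    lncrna_id = rownames(lx)[hit[, 1]],
    mrna_id = rownames(mx)[hit[, 2]],
    r = r[hit],
    sign = ifelse(r[hit] >= 0, "+", "-"),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$lncrna_id, edges$mrna_id, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  out <- list(edges = edges, threshold = threshold)
  class(out) <- "cnc_network"
  out
}

#' @export
print.cnc_network <- function(x, ...) {
  cat(sprintf("CNC network: %d lncRNAs, %d mRNAs, %d edges (|r| >= %g)\n",
              length(unique(x$edges$lncrna_id)), length(unique(x$edges$mrna_id)),
              nrow(x$edges), x$threshold))
  invisible(x)
}

#' Degree of each lncRNA in a CNC network
#' @param network A `cnc_network`.
#' @return Named integer vector: lncRNA id -> number of mRNA edges.
#' @export
cnc_degrees <- function(network) {
  stopifnot(inherits(network, "cnc_network"))
  tab <- table(network$edges$lncrna_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Edge table of a network in the unified 5-column layout
#' @param network A `cerna_network` or `cnc_network`.
#' @return data.frame `source`, `target`, `edge_type`, `sign`, `score`.
#' @export
network_edges <- function(network) {
  if (inherits(network, "cerna_network")) {
    n <- nrow(network$edges)
    data.frame(source = network$edges$source, target = network$edges$target,
               edge_type = network$edges$edge_type,
               sign = rep(NA_character_, n),
               score = network$edges$score, stringsAsFactors = FALSE)
  } else if (inherits(network, "cnc_network")) {
    n <- nrow(network$edges)
    data.frame(source = network$edges$lncrna_id, target = network$edges$mrna_id,
               edge_type = rep("lncRNA-mRNA", n), sign = network$edges$sign,
               score = network$edges$r, stringsAsFactors = FALSE)
  } else {
    stop("not a network object")
  }
}
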