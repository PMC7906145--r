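#' Round half away from zero
#'
#' Percentage rounding rule used throughout the summaries (1 decimal by
#' default): halves round away from zero, so 261/396 -> 65.9 and
#' 135/396 -> 34.1.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Minimal ratio-based differential peak caller
#'
#' Internal substitute for a dedicated differential-methylation caller, used
#' for synthetic end-to-end runs. Peaks are matched 1-1 across conditions by
#' greedy overlap matching; a matched pair gets `fold_change` =
#' larger/smaller enrichment and direction `hypermethylated` when the
#' condition-A enrichment is greater (ties count as hypermethylated with
#' fold change 1, so any threshold > 1 excludes them). Unmatched peaks get
#' the direction of their host condition (A -> hypermethylated) with
#' `fold_change = Inf` unless `fc_floor` caps it.
#'
#' @param peaks_a,peaks_b Peak data.frames (condition A = case).
#' @param fc_floor Optional finite fold change assigned to unmatched peaks
#'   instead of `Inf`.
#' @param min_overlap_bp Matching overlap threshold in bp.
#' @return Differential peak data.frame with columns `peak_id`, `chrom`,
#'   `start`, `end`, `strand`, `lncrna_id` (`NA`), `fold_change`,
#'   `direction`.
#' @export
call_differential_peaks <- function(peaks_a, peaks_b, fc_floor = Inf,
                                    min_overlap_bp = 1) {
  pairs <- match_peak_pairs(peaks_a, peaks_b, min_overlap_bp)
  rows <- list()
  if (nrow(pairs)) {
    ea <- peaks_a$fold_enrichment[pairs$a_row]
    eb <- peaks_b$fold_enrichment[pairs$b_row]
    rows$matched <- data.frame(
      peak_id = peaks_a$peak_id[pairs$a_row],
      chrom = peaks_a$chrom[pairs$a_row],
      start = peaks_a$start[pairs$a_row],
      end = peaks_a$end[pairs$a_row],
      strand = peaks_a$strand[pairs$a_row],
      lncrna_id = NA_character_,
      fold_change = pmax(ea, eb) / pmin(ea, eb),
      direction = ifelse(ea >= eb, "hypermethylated", "hypomethylated"),
      stringsAsFactors = FALSE)
  }
  un_a <- setdiff(seq_len(nrow(peaks_a)), pairs$a_row)
  un_b <- setdiff(seq_len(nrow(peaks_b)), pairs$b_row)
  if (length(un_a)) {
    rows$a_only <- data.frame(
      peak_id = peaks_a$peak_id[un_a], chrom = peaks_a$chrom[un_a],
      start = peaks_a$start[un_a], end = peaks_a$end[un_a],
      strand = peaks_a$strand[un_a], lncrna_id = NA_character_,
      fold_change = fc_floor, direction = "hypermethylated",
      stringsAsFactors = FALSE)
  }
  if (length(un_b)) {
    rows$b_only <- data.frame(
      peak_id = peaks_b$peak_id[un_b], chrom = peaks_b$chrom[un_b],
      start = peaks_b$start[un_b], end = peaks_b$end[un_b],
      strand = peaks_b$strand[un_b], lncrna_id = NA_character_,
      fold_change = fc_floor, direction = "hypomethylated",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    peak_id = character(0), chrom = character(0), start = numeric(0),
    end = numeric(0), strand = character(0), lncrna_id = character(0),
    fold_change = numeric(0), direction = character(0))
  rownames(out) <- NULL
  out
}

#' Summarize a regulation (direction) labeling
#'
#' Counts and percentages of the two direction labels of a differential
#' table: `hypermethylated`/`hypomethylated` for methylation or `up`/`down`
#' for expression. Percentages are rounded half away from zero to 1 decimal.
#'
#' @param direction Character vector of direction labels.
#' @return list with `n_total`, `n_hyper`, `n_hypo`, `pct_hyper`, `pct_hypo`
#'   (the "hyper" slot holds the up/hypermethylated label, "hypo" the
#'   down/hypomethylated one). Percentages are `NA` when `n_total` is 0.
#' @export
summarize_regulation <- function(direction) {
  up_labels <- c("hypermethylated", "up", "Up-expression", "up-expression")
  down_labels <- c("hypomethylated", "down", "Down-expression", "down-expression")
  known <- direction %in% c(up_labels, down_labels)
  if (!all(known)) stop("unknown direction label(s): ",
                        paste(unique(direction[!known]), collapse = ", "))
  n_total <- length(direction)
  n_hyper <- sum(direction %in% up_labels)
  n_hypo <- n_total - n_hyper
  list(n_total = n_total, n_hyper = n_hyper, n_hypo = n_hypo,
       pct_hyper = if (n_total) round_half_away(100 * n_hyper / n_total) else NA_real_,
       pct_hypo = if (n_total) round_half_away(100 * n_hypo / n_total) else NA_real_)
}

#' Length binning of differentially methylated lncRNAs
#'
#' Length is the summed exonic (mature transcript) length by default;
#' `use = "span"` switches to the genomic span. Coarse bins are 1,000 bp
#' wide from 1 bp up; fine bins are 200 bp wide inside 1-1,000 bp.
#'
#' @param ids lncRNA transcript ids.
#' @param catalog A `TranscriptCatalog`.
#' @param direction Optional direction label per id (recycled/na allowed);
#'   fractions are computed within each direction.
#' @param use `"exonic"` (default) or `"span"`.
#' @return list with `coarse` and `fine` data.frames (`bin`, `direction`,
#'   `n`, `fraction`) and `unresolved` (ids absent from the catalog).
#' @export
bin_lengths <- function(ids, catalog, direction = NULL, use = c("exonic", "span")) {
  use <- match.arg(use)
  if (is.null(direction)) direction <- rep("all", length(ids))
  stopifnot(length(direction) == length(ids))
  known <- ids %in% catalog$transcripts$transcript_id
  unresolved <- ids[!known]
  ids <- ids[known]; direction <- direction[known]
  len <- if (use == "exonic") {
    as.numeric(exonic_lengths(catalog, ids)[ids])
  } else {
    tx <- catalog$transcripts
    m <- match(ids, tx$transcript_id)
    tx$end[m] - tx$start[m]
  }
  bin_table <- function(lens, dirs, width, cap = Inf) {
    keep <- lens <= cap
    lens <- lens[keep]; dirs <- dirs[keep]
    res <- list()
    for (d in unique(dirs)) {
      v <- lens[dirs == d]
      idx <- floor((v - 1) / width)
      lab <- sprintf("%d-%d", idx * width + 1, (idx + 1) * width)
      counts <- table(lab)
      res[[d]] <- data.frame(bin = names(counts), direction = d,
                             n = as.integer(counts),
                             fraction = as.numeric(counts) / length(v),
                             stringsAsFactors = FALSE)
    }
    out <- if (length(res)) do.call(rbind, res) else
      data.frame(bin = character(0), direction = character(0),
                 n = integer(0), fraction = numeric(0))
    rownames(out) <- NULL
    # deterministic order: direction then lower bin edge
    lo <- as.numeric(sub("-.*$", "", out$bin))
    out[order(out$direction, lo), , drop = FALSE]
  }
  list(coarse = bin_table(len, direction, 1000),
       fine = bin_table(len, direction, 200, cap = 1000),
       unresolved = unresolved)
}

#' Chromosome distribution of differential lncRNAs
#'
#' @param chrom Chromosome label per record (normalized to a `chr` prefix).
#' @param direction Direction label per record.
#' @return data.frame `chrom`, `direction`, `n`, `fraction`; fractions sum
#'   to 1 within each direction.
#' @export
chromosome_distribution <- function(chrom, direction) {
  stopifnot(length(chrom) == length(direction))
  chrom <- ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  res <- list()
  for (d in unique(direction)) {
    counts <- table(chrom[direction == d])
    res[[d]] <- data.frame(chrom = names(counts), direction = d,
                           n = as.integer(counts),
                           fraction = as.numeric(counts) / sum(counts),
                           stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), direction = character(0),
               n = integer(0), fraction = numeric(0))
  rownames(out) <- NULL
  out[order(out$direction, out$chrom, method = "radix"), , drop = FALSE]
}

#' Mean differential fold change per positional class and direction
#'
#' Infinite fold changes are excluded (their count is returned); classes
#' with no finite record report `NA` with n = 0.
#'
#' @param diff_records Differential peak data.frame with `lncrna_id`,
#'   `fold_change`, `direction`.
#' @param class_mapping Named character vector lncRNA id -> class.
#' @return list with `summary` (data.frame class, direction, n, mean, sem)
#'   and `n_infinite_excluded`.
#' @export
mean_fold_change_by_class <- function(diff_records, class_mapping) {
  classes <- positional_classes()
  dirs <- c("hypermethylated", "hypomethylated")
  n_inf <- sum(is.infinite(diff_records$fold_change))
  rec <- diff_records[is.finite(diff_records$fold_change), , drop = FALSE]
  cl <- class_mapping[rec$lncrna_id]
  grid <- expand.grid(class = classes, direction = dirs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- rec$fold_change[!is.na(cl) & cl == grid$class[i] &
                           rec$direction == grid$direction[i]]
    n <- length(v)
    data.frame(class = grid$class[i], direction = grid$direction[i], n = n,
               mean = if (n) mean(v) else NA_real_,
               sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_)
  })
  out <- do.call(rbind, stats_rows)
  rownames(out) <- NULL
  list(summary = out, n_infinite_excluded = n_inf)
}

#' Cross-tabulate differential methylation against differential expression
#'
#' Every lncRNA seen in either table lands in exactly one cell of the
#' (hyper/hypo/not-differential) x (up/down/not-differential) table.
#'
#' @param diff_meth data.frame with `lncrna_id` and `direction`
#'   (`hypermethylated`/`hypomethylated`); at most one row per id.
#' @param diff_expr data.frame with `transcript_id` and `regulation`
#'   (`up`/`down`); at most one row per id.
#' @return list with `table` (3x3 integer matrix, rows hyper/hypo/none,
#'   columns up/down/none) and the four intersection counts `hyper_up`,
#'   `hyper_down`, `hypo_up`, `hypo_down`.
#' @export
join_methylation_expression <- function(diff_meth, diff_expr) {
  if (anyDuplicated(diff_meth$lncrna_id)) stop("duplicate ids in diff_meth")
  if (anyDuplicated(diff_expr$transcript_id)) stop("duplicate ids in diff_expr")
  all_ids <- union(diff_meth$lncrna_id, diff_expr$transcript_id)
  meth <- diff_meth$direction[match(all_ids, diff_meth$lncrna_id)]
  meth[is.na(meth)] <- "none"
  expr <- diff_expr$regulation[match(all_ids, diff_expr$transcript_id)]
  expr[is.na(expr)] <- "none"
  tab <- table(factor(meth, levels = c("hypermethylated", "hypomethylated", "none")),
               factor(expr, levels = c("up", "down", "none")))
  m <- matrix(as.integer(tab), nrow = 3, dimnames = dimnames(tab))
  list(table = m,
       hyper_up = m["hypermethylated", "up"],
       hyper_down = m["hypermethylated", "down"],
       hypo_up = m["hypomethylated", "up"],
       hypo_down = m["hypomethylated", "down"])
}

#' Correlate two paired per-lncRNA value vectors
#'
#' Pairs with any non-finite value are dropped (the retained n is reported);
#' the p-value uses the standard large-sample approximation.
#'
#' @param x,y Numeric vectors paired by lncRNA (same names or same order).
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `estimate`, `p_value`, `n`.
#' @export
correlate_levels <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("correlation undefined: fewer than 3 finite pairs")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Cumulative |log2FC| curves for m6A vs non-m6A lncRNAs
#'
#' Splits the expressed lncRNAs into those hosting at least one m6A peak in
#' either condition and the rest, and compares the empirical cumulative
#' distributions of |log2 fold change|. Infinite log2FC values are clamped
#' to the maximum finite value + 1 (the clamp count is reported) so every
#' lncRNA stays represented.
#'
#' @param expression Expression data.frame (see [read_expression_table()]);
#'   `fold_change` is the up/down-ratio (>= 0, possibly `Inf`) with the sign
#'   carried by `regulation`.
#' @param annotated_peaks Output of [filter_peaks_to_lncrna_exons()] pooled
#'   over both conditions (defines m6A membership).
#' @return list with `m6a` and `non_m6a` (each: sorted `values` and
#'   cumulative `fractions`), `ks_D`, `n_m6a`, `n_non_m6a`, `n_clamped`.
#' @export
cumulative_log2fc <- function(expression, annotated_peaks) {
  m6a_ids <- unique(annotated_peaks$lncrna_id)
  fc <- expression$fold_change
  # |log2FC|: fold_change is a >=1-style ratio with direction separate, but
  # tolerate ratios < 1 by folding them (|log2| is symmetric)
  v <- abs(log2(fc))
  v[fc == 0] <- Inf
  n_clamped <- sum(is.infinite(v))
  if (n_clamped && any(is.finite(v))) v[is.infinite(v)] <- max(v[is.finite(v)]) + 1
  in_m6a <- expression$transcript_id %in% m6a_ids
  if (!any(in_m6a)) stop("group 'm6a' is empty")
  if (!any(!in_m6a)) stop("group 'non_m6a' is empty")
  curve <- function(vals) {
    s <- sort(vals)
    list(values = s, fractions = seq_along(s) / length(s))
  }
  a <- v[in_m6a]; b <- v[!in_m6a]
  D <- unname(suppressWarnings(stats::ks.test(a, b))$statistic)
  list(m6a = curve(a), non_m6a = curve(b), ks_D = D,
       n_m6a = length(a), n_non_m6a = length(b), n_clamped = n_clamped)
}

#' Relative qPCR fold change by the 2^-ddCt method
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference gene in the
#'   case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference gene in the
#'   control sample.
#' @return Fold change `2^-((dCt_case) - (dCt_ctrl))`.
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Hypergeometric gene-set enrichment over a GMT collection
#'
#' Upper-tail hypergeometric test P(X >= k) per gene set, with
#' Benjamini-Hochberg adjustment across all tested sets. Sets are
#' intersected with the universe before testing.
#'
#' @param query_genes Character vector of query gene ids (must be a subset
#'   of `universe`).
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Character vector of background gene ids.
#' @return data.frame sorted by p then set name: `set`, `k` (overlap),
#'   `K` (set size in universe), `n` (query size), `N` (universe size),
#'   `p_value`, `p_adjust`.
#' @export
enrichment_test <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query_genes, universe), 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, query_genes))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      p_adjust = numeric(0)))
  }
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
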