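#' Filter m6A peaks to lncRNA exons
#'
#' A peak is retained iff it overlaps at least `min_overlap_bp` of at least
#' one exon of at least one lncRNA with a compatible strand (unstranded peaks
#' match both strands). A peak overlapping exons of several lncRNAs is
#' annotated to all of them, with the per-lncRNA exonic overlap in bp.
#'
#' @param peaks Peak data.frame (see [read_peak_table()]).
#' @param catalog A `TranscriptCatalog`.
#' @param min_overlap_bp Minimum exonic overlap in bp (default 1).
#' @return data.frame in long format: one row per (peak, host lncRNA) with
#'   the peak columns plus `lncrna_id` and `overlap_bp`.
#' @export
filter_peaks_to_lncrna_exons <- function(peaks, catalog, min_overlap_bp = 1) {
  stopifnot(inherits(catalog, "TranscriptCatalog"), min_overlap_bp >= 1)
  empty <- peaks[0, , drop = FALSE]
  empty$lncrna_id <- character(0)
  empty$overlap_bp <- numeric(0)
  if (!nrow(peaks)) return(empty)
  lnc_ids <- catalog$transcripts$transcript_id[catalog$transcripts$biotype == "lncRNA"]
  ex <- catalog$exons[catalog$exons$transcript_id %in% lnc_ids, , drop = FALSE]
  if (!nrow(ex)) return(empty)
  pk_gr <- as_granges0(peaks[, c("chrom", "start", "end", "strand")])
  ex_gr <- as_granges0(ex[, c("chrom", "start", "end", "strand", "transcript_id")])
  # unstranded ("*") peaks match both strands automatically in findOverlaps
  hits <- GenomicRanges::findOverlaps(pk_gr, ex_gr, ignore.strand = FALSE)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(GenomicRanges::ranges(pk_gr)[qi],
                                           GenomicRanges::ranges(ex_gr)[si]))
  df <- data.frame(peak_row = qi,
                   lncrna_id = ex$transcript_id[si],
                   overlap_bp = ov,
                   stringsAsFactors = FALSE)
  # sum exonic overlap per (peak, lncrna); a peak may hit several exons
  agg <- stats::aggregate(overlap_bp ~ peak_row + lncrna_id, data = df, FUN = sum)
  agg <- agg[agg$overlap_bp >= min_overlap_bp, , drop = FALSE]
  if (!nrow(agg)) return(empty)
  out <- cbind(peaks[agg$peak_row, , drop = FALSE],
               agg[, c("lncrna_id", "overlap_bp"), drop = FALSE])
  out <- out[order(agg$peak_row, agg$lncrna_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distribution of m6A peak counts per methylated lncRNA
#'
#' Fractions (over methylated lncRNAs only) of lncRNAs harboring 1, 2, 3 or
#' >= 4 m6A peaks in one condition.
#'
#' @param annotated_peaks Output of [filter_peaks_to_lncrna_exons()] for one
#'   condition.
#' @return data.frame with columns `bin` (`"1"`, `"2"`, `"3"`, `">=4"`),
#'   `n_lncrna` and `fraction`; fractions sum to 1. Zero rows on empty input.
#' @export
peaks_per_lncrna_distribution <- function(annotated_peaks) {
  if (!nrow(annotated_peaks)) {
    return(data.frame(bin = character(0), n_lncrna = integer(0), fraction = numeric(0)))
  }
  per_lnc <- tapply(annotated_peaks$peak_id, annotated_peaks$lncrna_id,
                    function(p) length(unique(p)))
  bins <- cut(as.numeric(per_lnc), breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
              labels = c("1", "2", "3", ">=4"))
  counts <- table(bins)
  data.frame(bin = names(counts),
             n_lncrna = as.integer(counts),
             fraction = as.numeric(counts) / length(per_lnc),
             stringsAsFactors = FALSE)
}

# greedy 1-1 matching of two peak sets by descending overlap; returns a
# data.frame(a_row, b_row, overlap_bp) of matched pairs
match_peak_pairs <- function(peaks_a, peaks_b, min_overlap_bp = 1) {
  if (!nrow(peaks_a) || !nrow(peaks_b)) {
    return(data.frame(a_row = integer(0), b_row = integer(0), overlap_bp = numeric(0)))
  }
  gr_a <- as_granges0(peaks_a[, c("chrom", "start", "end", "strand")])
  gr_b <- as_granges0(peaks_b[, c("chrom", "start", "end", "strand")])
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b, ignore.strand = FALSE)
  if (!length(hits)) {
    return(data.frame(a_row = integer(0), b_row = integer(0), overlap_bp = numeric(0)))
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(GenomicRanges::ranges(gr_a)[qi],
                                           GenomicRanges::ranges(gr_b)[si]))
  keep <- ov >= min_overlap_bp
  qi <- qi[keep]; si <- si[keep]; ov <- ov[keep]
  # deterministic greedy matching: overlap desc, then row indices
  ord <- order(-ov, qi, si)
  used_a <- logical(nrow(peaks_a))
  used_b <- logical(nrow(peaks_b))
  a_row <- integer(0); b_row <- integer(0); obp <- numeric(0)
  for (k in ord) {
    if (!used_a[qi[k]] && !used_b[si[k]]) {
      used_a[qi[k]] <- TRUE
      used_b[si[k]] <- TRUE
      a_row <- c(a_row, qi[k]); b_row <- c(b_row, si[k]); obp <- c(obp, ov[k])
    }
  }
  data.frame(a_row = a_row, b_row = b_row, overlap_bp = obp)
}

#' Compare two peak sets (Venn of shared and condition-unique peaks)
#'
#' Two peaks are "shared" iff they overlap by at least `min_overlap_bp` with
#' compatible strands; each peak is counted once (a peak overlapping several
#' opposite-set peaks is matched to one of them by greedy 1-1 matching on
#' descending overlap).
#'
#' @param peaks_a,peaks_b Peak data.frames for the two conditions.
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return A `peak_venn` list with `unique_a`, `unique_b`, `shared` and
#'   `shared_fraction` = shared / (unique_a + unique_b + shared).
#' @export
compare_peak_sets <- function(peaks_a, peaks_b, min_overlap_bp = 1) {
  pairs <- match_peak_pairs(peaks_a, peaks_b, min_overlap_bp)
  peak_venn(unique_a = nrow(peaks_a) - nrow(pairs),
            unique_b = nrow(peaks_b) - nrow(pairs),
            shared = nrow(pairs))
}

#' Build a peak Venn summary from counts
#'
#' @param unique_a,unique_b,shared Non-negative counts. Alternatively pass
#'   `n_a`, `n_b` (total peaks per side) with `shared`, and the unique counts
#'   are derived.
#' @param n_a,n_b Optional per-side totals.
#' @return A `peak_venn` list.
#' @export
peak_venn <- function(unique_a = NULL, unique_b = NULL, shared, n_a = NULL, n_b = NULL) {
  if (is.null(unique_a)) unique_a <- n_a - shared
  if (is.null(unique_b)) unique_b <- n_b - shared
  stopifnot(unique_a >= 0, unique_b >= 0, shared >= 0)
  denom <- unique_a + unique_b + shared
  out <- list(unique_a = unique_a, unique_b = unique_b, shared = shared,
              shared_fraction = if (denom > 0) shared / denom else NA_real_)
  class(out) <- "peak_venn"
  out
}

#' @export
print.peak_venn <- function(x, ...) {
  cat(sprintf("peak Venn: %d unique A | %d shared | %d unique B (shared fraction %.3f)\n",
              x$unique_a, x$shared, x$unique_b, x$shared_fraction))
  invisible(x)
}

#' Fold-enrichment distribution of m6A peaks per positional class
#'
#' Peaks hosted by lncRNAs of several classes are counted once per class.
#'
#' @param annotated_peaks Output of [filter_peaks_to_lncrna_exons()].
#' @param class_assignment Named character vector: lncRNA id -> positional
#'   class (see [classify_catalog()]).
#' @return data.frame with one row per class: `class`, `n`, `median`, `q1`,
#'   `q3` of peak fold enrichment.
#' @export
fold_enrichment_by_class <- function(annotated_peaks, class_assignment) {
  classes <- positional_classes()
  if (nrow(annotated_peaks)) {
    cl <- class_assignment[annotated_peaks$lncrna_id]
    if (anyNA(cl)) {
      stop("no positional class for lncRNA(s): ",
           paste(unique(annotated_peaks$lncrna_id[is.na(cl)]), collapse = ", "))
    }
    if (!all(cl %in% classes)) {
      stop("unknown class label(s): ", paste(setdiff(unique(cl), classes), collapse = ", "))
    }
    df <- data.frame(peak_id = annotated_peaks$peak_id,
                     fold_enrichment = annotated_peaks$fold_enrichment,
                     class = cl, stringsAsFactors = FALSE)
    df <- df[!duplicated(df[, c("peak_id", "class")]), , drop = FALSE]
  } else {
    df <- data.frame(peak_id = character(0), fold_enrichment = numeric(0),
                     class = character(0))
  }
  res <- lapply(classes, function(k) {
    v <- df$fold_enrichment[df$class == k]
    if (length(v)) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      data.frame(class = k, n = length(v), median = q[2], q1 = q[1], q3 = q[3])
    } else {
      data.frame(class = k, n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
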