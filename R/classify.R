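#' The six lncRNA positional classes
#'
#' Positional relationship of a lncRNA to the mRNA annotation, in the
#' priority order the classifier applies: overlap evidence outranks
#' proximity evidence.
#'
#' @return Character vector of the six class labels.
#' @export
positional_classes <- function() {
  c("exon_sense_overlapping", "intron_sense_overlapping", "natural_antisense",
    "intronic_antisense", "bidirectional", "intergenic")
}

# exon-exon overlap bp between a lncRNA and one mRNA (same chrom assumed)
exon_exon_overlap_bp <- function(lnc_ex, m_ex) {
  if (!nrow(lnc_ex) || !nrow(m_ex)) return(0)
  a <- IRanges::IRanges(lnc_ex$start + 1L, lnc_ex$end)
  b <- IRanges::IRanges(m_ex$start + 1L, m_ex$end)
  hits <- IRanges::findOverlaps(a, b)
  if (!length(hits)) return(0)
  sum(IRanges::width(IRanges::pintersect(a[S4Vectors::queryHits(hits)],
                                         b[S4Vectors::subjectHits(hits)])))
}

# TSS of a transcript row (0-based): start for '+', end for '-'
tss_position <- function(start, end, strand) ifelse(strand == "+", start, end)

#' Classify one lncRNA against the mRNA annotation
#'
#' Deterministic first-match classification, in priority order:
#' \enumerate{
#'   \item `exon_sense_overlapping`: >= 1 bp exon-exon overlap with an mRNA
#'     on the same strand;
#'   \item `intron_sense_overlapping`: the transcript span overlaps an mRNA
#'     on the same strand but with zero exon-exon bp;
#'   \item `natural_antisense`: >= 1 bp exon-exon overlap on the opposite
#'     strand;
#'   \item `intronic_antisense`: the transcript lies wholly within one mRNA
#'     intron on the opposite strand;
#'   \item `bidirectional`: no span overlap with the mRNA, opposite strand,
#'     divergently oriented (the two TSSs point away from each other), and
#'     TSS-to-TSS distance <= `bidirectional_window`;
#'   \item `intergenic`: no rule fired.
#' }
#'
#' @param lncrna_id Transcript id of a lncRNA in `catalog`.
#' @param catalog A `TranscriptCatalog` containing the mRNA annotation.
#' @param bidirectional_window Maximum TSS-to-TSS distance in bp for the
#'   bidirectional class (default 1000).
#' @param candidate_mrnas Optional character vector restricting the mRNAs
#'   examined (used internally by [classify_catalog()]).
#' @return A single class label (see [positional_classes()]).
#' @export
classify_lncrna <- function(lncrna_id, catalog, bidirectional_window = 1000,
                            candidate_mrnas = NULL) {
  stopifnot(inherits(catalog, "TranscriptCatalog"))
  tx <- catalog$transcripts
  i <- match(lncrna_id, tx$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", lncrna_id)
  if (tx$biotype[i] != "lncRNA") stop("transcript ", lncrna_id, " is not a lncRNA")
  lnc <- tx[i, ]
  mr <- tx[tx$biotype == "mRNA" & tx$chrom == lnc$chrom, , drop = FALSE]
  if (!is.null(candidate_mrnas)) mr <- mr[mr$transcript_id %in% candidate_mrnas, , drop = FALSE]
  if (!nrow(mr)) return("intergenic")
  lnc_ex <- transcript_exons(catalog, lncrna_id)

  span_overlap <- mr$start < lnc$end & mr$end > lnc$start
  same <- mr$strand == lnc$strand
  ee_bp <- vapply(seq_len(nrow(mr)), function(j) {
    if (!span_overlap[j]) return(0)
    exon_exon_overlap_bp(lnc_ex, transcript_exons(catalog, mr$transcript_id[j]))
  }, numeric(1))

  if (any(span_overlap & same & ee_bp > 0)) return("exon_sense_overlapping")
  if (any(span_overlap & same)) return("intron_sense_overlapping")
  if (any(span_overlap & !same & ee_bp > 0)) return("natural_antisense")
  # wholly inside one intron, opposite strand
  for (j in which(span_overlap & !same)) {
    introns <- transcript_introns(catalog, mr$transcript_id[j])
    if (nrow(introns) &&
        any(introns$start <= lnc$start & lnc$end <= introns$end)) {
      return("intronic_antisense")
    }
  }
  # bidirectional: divergent promoters on opposite strands, no span overlap
  lnc_tss <- tss_position(lnc$start, lnc$end, lnc$strand)
  for (j in which(!span_overlap & !same)) {
    m_tss <- tss_position(mr$start[j], mr$end[j], mr$strand[j])
    divergent <- if (mr$strand[j] == "+") lnc_tss <= m_tss else lnc_tss >= m_tss
    if (divergent && abs(m_tss - lnc_tss) <= bidirectional_window) {
      return("bidirectional")
    }
  }
  "intergenic"
}

#' Classify every lncRNA of a catalog
#'
#' Applies [classify_lncrna()] to each lncRNA (optionally a subset, e.g.
#' the differentially methylated ones) and tabulates class proportions.
#' Candidate mRNAs for each lncRNA are pre-restricted by an interval-index
#' query on the lncRNA span extended by `bidirectional_window`, which cannot
#' change the result (every rule requires overlap or TSS proximity within
#' that window).
#'
#' @param catalog A `TranscriptCatalog`.
#' @param ids Optional character vector of lncRNA ids to classify (default:
#'   all lncRNAs in the catalog).
#' @param bidirectional_window See [classify_lncrna()].
#' @return list with `classes` (named character vector lncRNA id -> class)
#'   and `proportions` (data.frame class, n, proportion over all six
#'   classes; proportions sum to 1 when any lncRNA was classified).
#' @export
classify_catalog <- function(catalog, ids = NULL, bidirectional_window = 1000) {
  stopifnot(inherits(catalog, "TranscriptCatalog"))
  tx <- catalog$transcripts
  lnc_ids <- tx$transcript_id[tx$biotype == "lncRNA"]
  if (!is.null(ids)) {
    missing <- setdiff(ids, lnc_ids)
    if (length(missing)) stop("not lncRNAs in the catalog: ", paste(missing, collapse = ", "))
    lnc_ids <- intersect(lnc_ids, ids)
  }
  classes <- positional_classes()
  if (!length(lnc_ids)) {
    return(list(
      classes = stats::setNames(character(0), character(0)),
      proportions = data.frame(class = classes, n = 0L, proportion = NA_real_)))
  }
  # candidate mRNAs per lncRNA via one batched overlap query
  li <- match(lnc_ids, tx$transcript_id)
  ext <- GenomicRanges::GRanges(
    tx$chrom[li],
    IRanges::IRanges(pmax(tx$start[li] - bidirectional_window, 0) + 1L,
                     tx$end[li] + bidirectional_window))
  mi <- which(tx$biotype == "mRNA")
  m_gr <- GenomicRanges::GRanges(tx$chrom[mi],
                                 IRanges::IRanges(tx$start[mi] + 1L, tx$end[mi]))
  hits <- GenomicRanges::findOverlaps(ext, m_gr, ignore.strand = TRUE)
  cand <- split(tx$transcript_id[mi][S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_along(lnc_ids)))
  assigned <- vapply(seq_along(lnc_ids), function(k) {
    classify_lncrna(lnc_ids[k], catalog, bidirectional_window,
                    candidate_mrnas = cand[[k]])
  }, character(1))
  names(assigned) <- lnc_ids
  counts <- table(factor(assigned, levels = classes))
  list(classes = assigned,
       proportions = data.frame(class = classes,
                                n = as.integer(counts),
                                proportion = as.numeric(counts) / length(assigned),
                                stringsAsFactors = FALSE))
}
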