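#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end strand
#' @importFrom IRanges IRanges overlapsAny pintersect width
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# GRanges/IRanges are 1-based closed, so conversion happens exactly here.

#' Convert internal 0-based half-open intervals to a GRanges
#'
#' @param df data.frame with columns chrom, start, end and optionally strand.
#' @return A [GenomicRanges::GRanges] (1-based closed) carrying any extra
#'   columns of `df` as metadata columns.
#' @keywords internal
as_granges0 <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    s <- as.character(df$strand)
    s[is.na(s) | s == "." | s == ""] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

# strand compatibility: "*" matches everything
strand_compatible <- function(a, b) a == "*" | b == "*" | a == b

#' Construct a transcript catalog
#'
#' A `TranscriptCatalog` holds exon-resolved transcript models (mRNA and
#' lncRNA) with an interval index for overlap queries. All coordinates are
#' 0-based half-open.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand` (one of `+`, `-`), `biotype`
#'   (`"mRNA"` or `"lncRNA"`).
#' @param exons data.frame with columns `transcript_id`, `start`, `end`.
#'   Exons must lie within their transcript, be sorted by start, and be
#'   separated by at least 1 bp.
#' @return An object of class `TranscriptCatalog`.
#' @export
transcript_catalog <- function(transcripts, exons) {
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(req %in% names(transcripts))) {
    stop("transcripts must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(transcripts)) {
    if (anyDuplicated(transcripts$transcript_id)) {
      stop("duplicate transcript_id: ",
           paste(unique(transcripts$transcript_id[duplicated(transcripts$transcript_id)]),
                 collapse = ", "))
    }
    if (any(transcripts$start < 0) || any(transcripts$start >= transcripts$end)) {
      stop("invalid transcript interval: need 0 <= start < end")
    }
    if (!all(transcripts$biotype %in% c("mRNA", "lncRNA"))) {
      stop("biotype must be 'mRNA' or 'lncRNA'")
    }
    if (!all(transcripts$strand %in% c("+", "-"))) {
      stop("transcript strand must be '+' or '-'")
    }
  }
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id), exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  # per-transcript validation
  split_idx <- split(seq_len(nrow(exons)), exons$transcript_id)
  missing_ex <- setdiff(transcripts$transcript_id, names(split_idx))
  if (length(missing_ex)) {
    stop("transcript(s) without exons: ", paste(missing_ex, collapse = ", "))
  }
  tx_lookup <- transcripts
  rownames(tx_lookup) <- tx_lookup$transcript_id
  for (tid in names(split_idx)) {
    if (!tid %in% transcripts$transcript_id) {
      stop("exon refers to unknown transcript: ", tid)
    }
    ex <- exons[split_idx[[tid]], , drop = FALSE]
    tx <- tx_lookup[tid, ]
    if (any(ex$start < tx$start) || any(ex$end > tx$end)) {
      stop("exon outside declared transcript bounds for transcript ", tid)
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)] + 1L)) {
      stop("exons of transcript ", tid, " overlap or touch (introns must be >= 1 bp)")
    }
  }
  # keep exon chrom/strand in sync with the transcript
  exons$chrom <- tx_lookup[exons$transcript_id, "chrom"]
  exons$strand <- tx_lookup[exons$transcript_id, "strand"]
  exons <- exons[, c("transcript_id", "chrom", "start", "end", "strand")]

  obj <- list(transcripts = transcripts, exons = exons)
  obj$tx_gr <- as_granges0(transcripts[, c("chrom", "start", "end", "strand")])
  obj$exon_gr <- as_granges0(exons[, c("chrom", "start", "end", "strand", "transcript_id")])
  class(obj) <- "TranscriptCatalog"
  obj
}

#' @export
print.TranscriptCatalog <- function(x, ...) {
  n <- table(factor(x$transcripts$biotype, levels = c("mRNA", "lncRNA")))
  cat(sprintf("TranscriptCatalog: %d transcripts (%d mRNA, %d lncRNA), %d exons\n",
              nrow(x$transcripts), n[["mRNA"]], n[["lncRNA"]], nrow(x$exons)))
  invisible(x)
}

#' @export
length.TranscriptCatalog <- function(x) nrow(x$transcripts)

#' Subset a catalog by biotype
#' @param catalog A `TranscriptCatalog`.
#' @param biotype `"mRNA"` or `"lncRNA"`.
#' @return data.frame of matching transcript records.
#' @export
catalog_transcripts <- function(catalog, biotype = NULL) {
  stopifnot(inherits(catalog, "TranscriptCatalog"))
  tx <- catalog$transcripts
  if (!is.null(biotype)) tx <- tx[tx$biotype %in% biotype, , drop = FALSE]
  rownames(tx) <- NULL
  tx
}

#' Query transcripts overlapping an interval
#'
#' Interval-index lookup: returns the transcript records whose genomic span
#' overlaps the query interval (0-based half-open) by at least 1 bp. Strand
#' `"*"` matches both strands.
#'
#' @param catalog A `TranscriptCatalog`.
#' @param chrom Chromosome label.
#' @param start,end 0-based half-open query coordinates.
#' @param strand Query strand; `"*"` (default) matches both.
#' @return data.frame of overlapping transcript records.
#' @export
catalog_query <- function(catalog, chrom, start, end, strand = "*") {
  stopifnot(inherits(catalog, "TranscriptCatalog"), start < end)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), strand = strand)
  hits <- GenomicRanges::findOverlaps(q, catalog$tx_gr, ignore.strand = FALSE)
  res <- catalog$transcripts[S4Vectors::subjectHits(hits), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Exonic (mature transcript) lengths
#'
#' @param catalog A `TranscriptCatalog`.
#' @param ids Optional transcript ids to restrict to.
#' @return Named numeric vector of summed exon lengths in bp.
#' @export
exonic_lengths <- function(catalog, ids = NULL) {
  stopifnot(inherits(catalog, "TranscriptCatalog"))
  ex <- catalog$exons
  if (!is.null(ids)) ex <- ex[ex$transcript_id %in% ids, , drop = FALSE]
  if (!nrow(ex)) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(ex$end - ex$start, ex$transcript_id, sum)
  stats::setNames(as.numeric(out), names(out))
}

# exons of one transcript as a data.frame (sorted by start)
transcript_exons <- function(catalog, id) {
  ex <- catalog$exons[catalog$exons$transcript_id == id, , drop = FALSE]
  ex[order(ex$start), , drop = FALSE]
}

# introns of one transcript (0-based half-open), possibly zero rows
transcript_introns <- function(catalog, id) {
  ex <- transcript_exons(catalog, id)
  if (nrow(ex) < 2) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  data.frame(chrom = ex$chrom[-1],
             start = ex$end[-nrow(ex)],
             end = ex$start[-1])
}
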