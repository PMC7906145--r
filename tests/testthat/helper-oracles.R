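# Independent brute-force oracles: plain loops and closed forms, no shared
# code with the implementation paths they check.

.ov <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))

.strand_ok <- function(a, b) a == "*" || b == "*" || a == b

# all-pairs exon-overlap scan: peak x lncRNA retained pairs with overlap bp
oracle_filter_peaks <- function(peaks, catalog, min_overlap_bp = 1) {
  tx <- catalog$transcripts
  lnc <- tx[tx$biotype == "lncRNA", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(lnc))) {
      if (peaks$chrom[i] != lnc$chrom[j]) next
      if (!.strand_ok(peaks$strand[i], lnc$strand[j])) next
      ex <- catalog$exons[catalog$exons$transcript_id == lnc$transcript_id[j], ]
      bp <- 0
      for (k in seq_len(nrow(ex))) {
        bp <- bp + .ov(peaks$start[i], peaks$end[i], ex$start[k], ex$end[k])
      }
      if (bp >= min_overlap_bp) {
        out[[length(out) + 1]] <- data.frame(
          peak_id = peaks$peak_id[i], lncrna_id = lnc$transcript_id[j],
          overlap_bp = bp, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(peak_id = character(0), lncrna_id = character(0),
               overlap_bp = numeric(0))
}

# literal six-rule classifier over all mRNAs
oracle_classify <- function(catalog, lncrna_id, window = 1000) {
  tx <- catalog$transcripts
  lnc <- tx[tx$transcript_id == lncrna_id, ]
  lex <- catalog$exons[catalog$exons$transcript_id == lncrna_id, ]
  mr <- tx[tx$biotype == "mRNA" & tx$chrom == lnc$chrom, , drop = FALSE]
  ee <- function(mid) {
    mex <- catalog$exons[catalog$exons$transcript_id == mid, ]
    bp <- 0
    for (a in seq_len(nrow(lex))) for (b in seq_len(nrow(mex))) {
      bp <- bp + .ov(lex$start[a], lex$end[a], mex$start[b], mex$end[b])
    }
    bp
  }
  span_ov <- function(j) .ov(lnc$start, lnc$end, mr$start[j], mr$end[j]) > 0
  for (j in seq_len(nrow(mr))) {
    if (span_ov(j) && mr$strand[j] == lnc$strand && ee(mr$transcript_id[j]) > 0)
      return("exon_sense_overlapping")
  }
  for (j in seq_len(nrow(mr))) {
    if (span_ov(j) && mr$strand[j] == lnc$strand)
      return("intron_sense_overlapping")
  }
  for (j in seq_len(nrow(mr))) {
    if (span_ov(j) && mr$strand[j] != lnc$strand && ee(mr$transcript_id[j]) > 0)
      return("natural_antisense")
  }
  for (j in seq_len(nrow(mr))) {
    if (!span_ov(j) || mr$strand[j] == lnc$strand) next
    mex <- catalog$exons[catalog$exons$transcript_id == mr$transcript_id[j], ]
    mex <- mex[order(mex$start), ]
    if (nrow(mex) < 2) next
    for (k in seq_len(nrow(mex) - 1)) {
      if (mex$end[k] <= lnc$start && lnc$end <= mex$start[k + 1])
        return("intronic_antisense")
    }
  }
  lnc_tss <- if (lnc$strand == "+") lnc$start else lnc$end
  for (j in seq_len(nrow(mr))) {
    if (span_ov(j) || mr$strand[j] == lnc$strand) next
    m_tss <- if (mr$strand[j] == "+") mr$start[j] else mr$end[j]
    divergent <- if (mr$strand[j] == "+") lnc_tss <= m_tss else lnc_tss >= m_tss
    if (divergent && abs(m_tss - lnc_tss) <= window) return("bidirectional")
  }
  "intergenic"
}

# greedy 1-1 overlap matching, written independently with plain loops
oracle_venn <- function(peaks_a, peaks_b, min_overlap_bp = 1) {
  pairs <- list()
  for (i in seq_len(nrow(peaks_a))) for (j in seq_len(nrow(peaks_b))) {
    if (peaks_a$chrom[i] != peaks_b$chrom[j]) next
    if (!.strand_ok(peaks_a$strand[i], peaks_b$strand[j])) next
    bp <- .ov(peaks_a$start[i], peaks_a$end[i], peaks_b$start[j], peaks_b$end[j])
    if (bp >= min_overlap_bp) pairs[[length(pairs) + 1]] <- c(i, j, bp)
  }
  shared <- 0
  if (length(pairs)) {
    m <- do.call(rbind, pairs)
    m <- m[order(-m[, 3], m[, 1], m[, 2]), , drop = FALSE]
    ua <- rep(FALSE, nrow(peaks_a)); ub <- rep(FALSE, nrow(peaks_b))
    for (r in seq_len(nrow(m))) {
      if (!ua[m[r, 1]] && !ub[m[r, 2]]) {
        ua[m[r, 1]] <- TRUE; ub[m[r, 2]] <- TRUE; shared <- shared + 1
      }
    }
  }
  list(unique_a = nrow(peaks_a) - shared, unique_b = nrow(peaks_b) - shared,
       shared = shared)
}

# cis window by explicit gap arithmetic
oracle_cis <- function(catalog, lncrna_id, window = 10000) {
  tx <- catalog$transcripts
  lnc <- tx[tx$transcript_id == lncrna_id, ]
  mr <- tx[tx$biotype == "mRNA" & tx$chrom == lnc$chrom, , drop = FALSE]
  hits <- character(0)
  for (j in seq_len(nrow(mr))) {
    gap <- max(mr$start[j] - lnc$end, lnc$start - mr$end[j], 0)
    overlap <- .ov(lnc$start, lnc$end, mr$start[j], mr$end[j]) > 0
    if (overlap || gap < window) hits <- c(hits, mr$transcript_id[j])
  }
  sort(hits)
}

# top-k selection by explicit sort
oracle_top_k <- function(bindings, source, k) {
  b <- bindings[bindings$source_id == source, , drop = FALSE]
  b <- b[order(-b$score, b$target_id), , drop = FALSE]
  head(b$target_id, k)
}

# exact hypergeometric upper tail by summation of the pmf
oracle_hyper_p <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Spearman rho by explicit rank formula (handles ties via average ranks)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# ECDF by counting
oracle_ecdf <- function(values, at) {
  vapply(at, function(t) mean(values <= t), numeric(1))
}
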