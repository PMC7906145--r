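#' Read a GTF annotation into a transcript catalog
#'
#' Parses an Ensembl-dialect GTF (1-based closed coordinates) with
#' [rtracklayer::import()] and converts to the internal 0-based half-open
#' convention. Exons are grouped per transcript; the transcript interval is
#' taken from the `transcript` feature when present, otherwise from the exon
#' hull. Biotype assignment is injectable via `biotype_rule`.
#'
#' @param path Path to a GTF file.
#' @param biotype_rule list with elements `attribute` (GTF attribute key,
#'   default `"gene_biotype"`), `lncrna` (attribute values mapped to lncRNA)
#'   and `mrna` (values mapped to mRNA). Transcripts with any other biotype
#'   are dropped; the dropped count is reported with [message()].
#' @return A [transcript_catalog()].
#' @export
read_gtf <- function(path,
                     biotype_rule = list(
                       attribute = "gene_biotype",
                       lncrna = c("lncRNA", "antisense", "lincRNA", "processed_transcript"),
                       mrna = "protein_coding")) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  raw <- readLines(path)
  body <- which(!grepl("^#", raw) & nzchar(trimws(raw)))
  if (!length(body)) {
    return(transcript_catalog(
      data.frame(transcript_id = character(0), gene_id = character(0),
                 chrom = character(0), start = numeric(0), end = numeric(0),
                 strand = character(0), biotype = character(0)),
      data.frame(transcript_id = character(0), start = numeric(0), end = numeric(0))))
  }
  nfield <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- body[nfield < 9]
    stop("malformed GTF line(s) (fewer than 9 tab-separated fields): line ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  feat <- sub("^([^\t]*\t){2}([^\t]*)\t.*$", "\\2", raw[body])
  need_tid <- body[feat %in% c("transcript", "exon")]
  no_tid <- need_tid[!grepl("transcript_id", raw[need_tid], fixed = TRUE)]
  if (length(no_tid)) {
    stop("GTF parse error: missing transcript_id attribute at line ",
         paste(utils::head(no_tid, 10), collapse = ", "))
  }

  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(S4Vectors::mcols(gr))
  attr_col <- biotype_rule$attribute
  biotype_raw <- if (attr_col %in% names(md)) as.character(md[[attr_col]]) else
    rep(NA_character_, length(gr))
  biotype <- rep(NA_character_, length(gr))
  biotype[biotype_raw %in% biotype_rule$lncrna] <- "lncRNA"
  biotype[biotype_raw %in% biotype_rule$mrna] <- "mRNA"

  is_exon <- md$type == "exon"
  is_tx <- md$type == "transcript"
  # GRanges is 1-based closed; internal is 0-based half-open: start-1, end as-is
  df <- data.frame(
    type = as.character(md$type),
    transcript_id = as.character(md$transcript_id),
    gene_id = if ("gene_id" %in% names(md)) as.character(md$gene_id) else
      as.character(md$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  exdf <- df[is_exon & !is.na(df$transcript_id), , drop = FALSE]
  if (!nrow(exdf)) {
    return(transcript_catalog(
      data.frame(transcript_id = character(0), gene_id = character(0),
                 chrom = character(0), start = numeric(0), end = numeric(0),
                 strand = character(0), biotype = character(0)),
      data.frame(transcript_id = character(0), start = numeric(0), end = numeric(0))))
  }
  # transcript table: declared transcript features, else exon hull
  txdf <- df[is_tx & !is.na(df$transcript_id), , drop = FALSE]
  hull_start <- tapply(exdf$start, exdf$transcript_id, min)
  hull_end <- tapply(exdf$end, exdf$transcript_id, max)
  first <- exdf[!duplicated(exdf$transcript_id), , drop = FALSE]
  tx <- data.frame(
    transcript_id = first$transcript_id,
    gene_id = first$gene_id,
    chrom = first$chrom,
    start = as.numeric(hull_start[first$transcript_id]),
    end = as.numeric(hull_end[first$transcript_id]),
    strand = first$strand,
    biotype = first$biotype,
    stringsAsFactors = FALSE
  )
  if (nrow(txdf)) {
    m <- match(tx$transcript_id, txdf$transcript_id)
    has_tx <- !is.na(m)
    declared_start <- txdf$start[m[has_tx]]
    declared_end <- txdf$end[m[has_tx]]
    out_of_bounds <- tx$start[has_tx] < declared_start | tx$end[has_tx] > declared_end
    if (any(out_of_bounds)) {
      stop("exon outside declared transcript bounds for transcript ",
           paste(tx$transcript_id[has_tx][out_of_bounds], collapse = ", "))
    }
    tx$start[has_tx] <- declared_start
    tx$end[has_tx] <- declared_end
    if (any(!is.na(txdf$biotype))) {
      tb <- txdf$biotype[m]
      tx$biotype <- ifelse(!is.na(tb), tb, tx$biotype)
    }
  }
  dropped <- sum(is.na(tx$biotype))
  if (dropped > 0) {
    message("read_gtf: dropped ", dropped, " transcript(s) with unmapped biotype")
    keep <- !is.na(tx$biotype)
    tx <- tx[keep, , drop = FALSE]
    exdf <- exdf[exdf$transcript_id %in% tx$transcript_id, , drop = FALSE]
  }
  transcript_catalog(tx, exdf[, c("transcript_id", "start", "end")])
}

#' Write a transcript catalog as GTF
#'
#' Emits `transcript` and `exon` features with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes, converting back to GTF's 1-based closed
#' coordinates. Reading the file with [read_gtf()] reproduces the catalog.
#'
#' @param catalog A `TranscriptCatalog`.
#' @param path Output path.
#' @export
write_gtf <- function(catalog, path) {
  stopifnot(inherits(catalog, "TranscriptCatalog"))
  tx <- catalog$transcripts
  ex <- catalog$exons
  bt <- function(b) ifelse(b == "mRNA", "protein_coding", "lncRNA")
  fmt <- function(chrom, start, end, strand, type, gid, tid, biotype) {
    sprintf("%s\tlncm6a\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_biotype \"%s\";",
            chrom, type, as.integer(start) + 1L, as.integer(end), strand, gid, tid, biotype)
  }
  lines <- character(0)
  if (nrow(tx)) {
    ex_gid <- tx$gene_id[match(ex$transcript_id, tx$transcript_id)]
    ex_bt <- bt(tx$biotype[match(ex$transcript_id, tx$transcript_id)])
    tx_lines <- fmt(tx$chrom, tx$start, tx$end, tx$strand, "transcript",
                    tx$gene_id, tx$transcript_id, bt(tx$biotype))
    ex_lines <- fmt(ex$chrom, ex$start, ex$end, ex$strand, "exon",
                    ex_gid, ex$transcript_id, ex_bt)
    # transcript line followed by its exons, in catalog order
    ord <- order(match(ex$transcript_id, tx$transcript_id), ex$start)
    ex_lines <- ex_lines[ord]
    grp <- match(ex$transcript_id[ord], tx$transcript_id)
    lines <- unlist(lapply(seq_len(nrow(tx)), function(i) {
      c(tx_lines[i], ex_lines[grp == i])
    }))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a peak table
#'
#' Supported dialects:
#' \describe{
#'   \item{`bed6+`}{0-based half-open BED with columns chrom, start, end,
#'     name, score, strand, fold_enrichment and optional p_value; no header.}
#'   \item{`macs-xls`}{MACS peak .xls: `#` comment lines, a header line, then
#'     1-based closed rows; needs columns chr, start, end and fold_enrichment.}
#'   \item{`diffreps`}{differential-methylation table with columns chrom,
#'     txStart, txEnd, name, Foldchange, regulation (1-based closed); yields
#'     differential peak records with direction parsed from the regulation
#'     label or, when numeric, from the sign of a log2 fold change.}
#' }
#' All records are returned in 0-based half-open coordinates.
#'
#' @param path Input file.
#' @param condition Condition label attached to each peak (e.g. `"CRC"`).
#' @param dialect One of `"bed6+"`, `"macs-xls"`, `"diffreps"`.
#' @return For `bed6+`/`macs-xls`: data.frame of peak records with columns
#'   `peak_id`, `chrom`, `start`, `end`, `strand`, `fold_enrichment`,
#'   `p_value`, `condition`. For `diffreps`: data.frame of differential peak
#'   records with columns `peak_id`, `chrom`, `start`, `end`, `strand`,
#'   `lncrna_id`, `fold_change`, `direction`.
#' @export
read_peak_table <- function(path, condition = NA_character_,
                            dialect = c("bed6+", "macs-xls", "diffreps")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak table not found: ", path)
  if (dialect == "bed6+") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 7) stop("bed6+ dialect requires >= 7 columns (fold enrichment in column 7)")
    out <- data.frame(
      peak_id = as.character(tab[[4]]),
      chrom = as.character(tab[[1]]),
      start = as.numeric(tab[[2]]),
      end = as.numeric(tab[[3]]),
      strand = as.character(tab[[6]]),
      fold_enrichment = as.numeric(tab[[7]]),
      p_value = if (ncol(tab) >= 8) as.numeric(tab[[8]]) else NA_real_,
      condition = condition,
      stringsAsFactors = FALSE
    )
  } else if (dialect == "macs-xls") {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(trimws(lines))
    tab <- utils::read.table(text = lines[keep], sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
    cn <- tolower(names(tab))
    need <- c("chr", "start", "end", "fold_enrichment")
    if (!all(need %in% cn)) stop("macs-xls dialect needs columns: ", paste(need, collapse = ", "))
    pcol <- grep("pvalue", cn)
    out <- data.frame(
      peak_id = if ("name" %in% cn) as.character(tab[[which(cn == "name")]]) else
        paste0("macs_peak_", seq_len(nrow(tab))),
      chrom = as.character(tab[[which(cn == "chr")]]),
      start = as.numeric(tab[[which(cn == "start")]]) - 1,  # 1-based -> 0-based
      end = as.numeric(tab[[which(cn == "end")]]),
      strand = "*",
      fold_enrichment = as.numeric(tab[[which(cn == "fold_enrichment")]]),
      p_value = if (length(pcol)) 10^(-as.numeric(tab[[pcol[1]]]) / 10) else NA_real_,
      condition = condition,
      stringsAsFactors = FALSE
    )
  } else {
    first <- readLines(path, n = 1)
    has_header <- grepl("chrom", first, ignore.case = TRUE)
    tab <- utils::read.table(path, sep = "\t", header = has_header,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 6) stop("diffreps dialect requires 6 columns: chrom, start, end, name, foldchange, regulation")
    fc_raw <- tab[[5]]
    reg <- as.character(tab[[6]])
    direction <- rep(NA_character_, nrow(tab))
    direction[grepl("^hyper", reg, ignore.case = TRUE)] <- "hypermethylated"
    direction[grepl("^hypo", reg, ignore.case = TRUE)] <- "hypomethylated"
    if (anyNA(direction)) {
      # numeric regulation column: sign of log2 fold change
      lg <- suppressWarnings(as.numeric(reg))
      direction[is.na(direction) & !is.na(lg)] <-
        ifelse(lg[is.na(direction) & !is.na(lg)] >= 0, "hypermethylated", "hypomethylated")
    }
    if (anyNA(direction)) stop("diffreps dialect: unrecognized regulation label(s): ",
                               paste(unique(reg[is.na(direction)]), collapse = ", "))
    fc <- suppressWarnings(as.numeric(fc_raw))
    fc[fc_raw %in% c("inf", "Inf", "+Inf", "-Inf", "-inf")] <- Inf
    out <- data.frame(
      peak_id = paste0("diff_peak_", seq_len(nrow(tab))),
      chrom = as.character(tab[[1]]),
      start = as.numeric(tab[[2]]) - 1,  # 1-based -> 0-based
      end = as.numeric(tab[[3]]),
      strand = "*",
      lncrna_id = as.character(tab[[4]]),
      fold_change = fc,
      direction = direction,
      stringsAsFactors = FALSE
    )
    if (any(!is.na(out$fold_change) & out$fold_change <= 0)) {
      stop("diffreps dialect: fold change must be > 0")
    }
  }
  if (nrow(out)) {
    if (any(out$start < 0)) stop("negative coordinates in peak table ", path)
    if (any(out$start >= out$end)) stop("empty/inverted interval in peak table ", path)
    if ("fold_enrichment" %in% names(out) && any(out$fold_enrichment <= 0)) {
      stop("fold enrichment must be > 0 in ", path)
    }
    out$strand[out$strand %in% c(".", "")] <- "*"
  }
  rownames(out) <- NULL
  out
}

#' Write peaks as BED6+ (0-based half-open)
#'
#' @param peaks Peak data.frame as returned by [read_peak_table()].
#' @param path Output path.
#' @export
write_peak_table <- function(peaks, path) {
  lines <- if (nrow(peaks)) {
    sprintf("%s\t%d\t%d\t%s\t.\t%s\t%s\t%s",
            peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
            peaks$peak_id,
            ifelse(peaks$strand == "*", ".", peaks$strand),
            format(peaks$fold_enrichment, trim = TRUE, scientific = FALSE),
            ifelse(is.na(peaks$p_value), "NA",
                   format(peaks$p_value, trim = TRUE, scientific = TRUE)))
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write a differential-peak table in the diffreps dialect
#' @param diff_peaks Differential peak data.frame (see [read_peak_table()]).
#' @param path Output path.
#' @export
write_diff_peak_table <- function(diff_peaks, path) {
  header <- "chrom\ttxStart\ttxEnd\tGeneName\tFoldchange\tregulation"
  lines <- if (nrow(diff_peaks)) {
    sprintf("%s\t%d\t%d\t%s\t%s\t%s",
            diff_peaks$chrom, as.integer(diff_peaks$start) + 1L,
            as.integer(diff_peaks$end), diff_peaks$lncrna_id,
            ifelse(is.infinite(diff_peaks$fold_change), "Inf",
                   format(diff_peaks$fold_change, trim = TRUE, scientific = FALSE)),
            diff_peaks$direction)
  } else character(0)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a transcript expression table
#'
#' Tab-separated with a header. First column `transcript_id`; the trailing
#' columns `fold_change`, `p_value`, `regulation`; every other column is a
#' per-sample FPKM column named `<condition>_<replicate>` (the condition
#' assignment is parsed from the name). `inf`/`Inf`/`-Inf` fold-change tokens
#' become `+Inf` with direction carried by the regulation label.
#'
#' @param path Input file.
#' @return data.frame with one row per transcript and an attribute `samples`
#'   (data.frame with columns `sample`, `condition`).
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"transcript_id" %in% names(tab)) stop("expression table needs a transcript_id column")
  meta_cols <- c("transcript_id", "fold_change", "p_value", "regulation")
  sample_cols <- setdiff(names(tab), meta_cols)
  for (sc in sample_cols) {
    v <- as.numeric(tab[[sc]])
    if (any(v < 0, na.rm = TRUE)) stop("negative FPKM in column ", sc)
    tab[[sc]] <- v
  }
  if ("fold_change" %in% names(tab)) {
    raw <- tab$fold_change
    fc <- suppressWarnings(as.numeric(raw))
    fc[as.character(raw) %in% c("inf", "Inf", "+Inf", "-Inf", "-inf")] <- Inf
    if (any(fc < 0, na.rm = TRUE)) stop("fold_change must be non-negative")
    tab$fold_change <- fc
  }
  if (!"regulation" %in% names(tab)) tab$regulation <- "unchanged"
  attr(tab, "samples") <- data.frame(
    sample = sample_cols,
    condition = sub("_[^_]*$", "", sample_cols),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  tab
}

#' Write a transcript expression table
#' @param expr Expression data.frame (see [read_expression_table()]).
#' @param path Output path.
#' @export
write_expression_table <- function(expr, path) {
  out <- expr
  if ("fold_change" %in% names(out)) {
    out$fold_change <- ifelse(is.infinite(out$fold_change), "inf",
                              format(out$fold_change, trim = TRUE, scientific = FALSE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated GMT: set name, description, then member genes. Duplicate
#' members within a set are deduplicated; a duplicate set name or a line with
#' fewer than 3 fields is an error (with the line number).
#'
#' @param path Input file.
#' @return Named list of character vectors (one per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) stop("GMT line ", i, ": fewer than 3 tab-separated fields")
    nm <- fields[1]
    if (nm %in% names(sets)) stop("GMT line ", i, ": duplicate set name '", nm, "'")
    sets[[nm]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Read a scored binding-prediction table
#'
#' Tab-separated with header columns `source_id`, `target_id`, `score`
#' (higher score = stronger predicted binding).
#'
#' @param path Input file.
#' @return data.frame with those three columns.
#' @export
read_binding_table <- function(path) {
  if (!file.exists(path)) stop("binding table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("source_id", "target_id", "score")
  if (!all(need %in% names(tab))) stop("binding table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab[, c("source_id", "target_id")])) {
    stop("duplicate (source_id, target_id) pair in binding table")
  }
  tab[, need]
}

#' Write a binding-prediction table
#' @param bindings data.frame with columns source_id, target_id, score.
#' @param path Output path.
#' @export
write_binding_table <- function(bindings, path) {
  utils::write.table(bindings[, c("source_id", "target_id", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as a Cytoscape-importable edge list
#'
#' Tab-separated columns: `source`, `target`, `edge_type`
#' (`lncRNA-miRNA`, `miRNA-mRNA` or `lncRNA-mRNA`), `sign` (`+`, `-` or `NA`)
#' and `score`. Rows are ordered by source then target (C-locale), so the
#' output is byte-deterministic.
#'
#' @param network A `cerna_network` or `cnc_network` object.
#' @param path Output path.
#' @export
write_network_edges <- function(network, path) {
  ed <- network_edges(network)
  ord <- order(ed$source, ed$target, method = "radix")
  ed <- ed[ord, , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("source\ttarget\tedge_type\tsign\tscore", con)
  if (nrow(ed)) {
    writeLines(sprintf("%s\t%s\t%s\t%s\t%s", ed$source, ed$target, ed$edge_type,
                       ifelse(is.na(ed$sign), "NA", ed$sign),
                       format(ed$score, trim = TRUE, scientific = FALSE, digits = 10)),
               con)
  }
  invisible(path)
}

#' Read an edge list written by [write_network_edges()]
#' @param path Input file.
#' @return data.frame with columns source, target, edge_type, sign, score.
#' @export
read_network_edges <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  tab
}
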