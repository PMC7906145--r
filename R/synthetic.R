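#' Configuration of a synthetic m6A lncRNA study
#'
#' Defaults emulate the study structure at desk scale: peak counts scaled
#' down ~100x from the reported landscape (83 and 71 peaks per condition
#' with a 0.375 shared fraction), ~91% single-peak lncRNAs, 34.1% of
#' differential peaks hypermethylated, 16 planted differentially expressed
#' lncRNAs with ~27% upregulated, five samples per condition, and a planted
#' methylation-expression Spearman correlation of 0.49.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_mrna,n_lncrna Transcript counts.
#' @param class_proportions Named probabilities over the six positional
#'   classes (must sum to 1); allocation is largest-remainder, so planted
#'   class counts are exact.
#' @param n_peaks_a,n_peaks_b m6A peak counts for conditions A (case) and B.
#' @param shared_peak_fraction Target shared fraction of the peak-set union
#'   in \[0,1\]; the shared count is `round(f*(nA+nB)/(1+f))`.
#' @param peaks_per_lncrna_probs Probabilities of a methylated lncRNA
#'   hosting 1, 2, 3 or 4 peaks.
#' @param peak_width Peak width in bp.
#' @param enrich_meanlog,enrich_sdlog Log-normal parameters of peak fold
#'   enrichment.
#' @param enrich_noise_sd sdlog of the cross-condition jitter on shared,
#'   non-differential peaks.
#' @param n_diff_peaks Planted differential peaks (a subset of the shared
#'   peaks).
#' @param frac_hyper Probability that a differential peak is
#'   hypermethylated.
#' @param diff_fc_meanlog,diff_fc_sdlog Log-normal parameters of the
#'   differential-methylation fold change.
#' @param n_de_lncrna Planted differentially expressed lncRNAs.
#' @param de_log2fc_mean,de_log2fc_sd Normal parameters of the planted
#'   |log2 fold change|.
#' @param frac_up_de Probability that a planted DE lncRNA is upregulated.
#' @param de_fc_threshold Fold-change threshold for the up/down/unchanged
#'   regulation label.
#' @param meth_expr_corr Target Spearman correlation between a methylated
#'   lncRNA's peak fold enrichment and its expression, in \[-1,1\]
#'   (internally converted to the Gaussian-copula Pearson parameter).
#' @param n_samples_per_condition Samples per condition.
#' @param conditions Two condition labels (case first).
#' @param fpkm_meanlog,fpkm_sdlog Log-normal parameters of baseline FPKM.
#' @param noise_sd Per-sample log-FPKM noise (natural-log sd); must be > 0
#'   for trans-target planting.
#' @param n_trans_pairs Planted trans-target lncRNA-mRNA pairs.
#' @param trans_corr Planted sample Pearson correlation of each pair
#'   (constructed exactly).
#' @param n_mirna miRNA pool size.
#' @param bindings_per_lncrna,bindings_per_mirna Predicted partners per
#'   source (>= 5).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_mrna = 80,
                       n_lncrna = 100,
                       class_proportions = c(exon_sense_overlapping = 0.57,
                                             intron_sense_overlapping = 0.06,
                                             natural_antisense = 0.07,
                                             intronic_antisense = 0.045,
                                             bidirectional = 0.035,
                                             intergenic = 0.22),
                       n_peaks_a = 83,
                       n_peaks_b = 71,
                       shared_peak_fraction = 0.375,
                       peaks_per_lncrna_probs = c(0.91, 0.07, 0.015, 0.005),
                       peak_width = 100,
                       enrich_meanlog = 1,
                       enrich_sdlog = 0.5,
                       enrich_noise_sd = 0.2,
                       n_diff_peaks = 40,
                       frac_hyper = 0.341,
                       diff_fc_meanlog = 2.5,
                       diff_fc_sdlog = 1,
                       n_de_lncrna = 16,
                       de_log2fc_mean = 3,
                       de_log2fc_sd = 0.5,
                       frac_up_de = 0.27,
                       de_fc_threshold = 2,
                       meth_expr_corr = 0.49,
                       n_samples_per_condition = 5,
                       conditions = c("CRC", "NC"),
                       fpkm_meanlog = 3,
                       fpkm_sdlog = 1,
                       noise_sd = 0.25,
                       n_trans_pairs = 3,
                       trans_corr = 0.99,
                       n_mirna = 120,
                       bindings_per_lncrna = 8,
                       bindings_per_mirna = 8) {
  cfg <- as.list(environment())
  cls <- positional_classes()
  if (!setequal(names(cfg$class_proportions), cls)) {
    stop("class_proportions must be named by the six positional classes")
  }
  cfg$class_proportions <- cfg$class_proportions[cls]
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9) stop("class_proportions must sum to 1")
  if (any(cfg$class_proportions < 0)) stop("class_proportions must be non-negative")
  if (cfg$shared_peak_fraction < 0 || cfg$shared_peak_fraction > 1) {
    stop("shared_peak_fraction must be in [0, 1]")
  }
  if (abs(cfg$meth_expr_corr) > 1) stop("meth_expr_corr must be in [-1, 1]")
  if (abs(cfg$trans_corr) > 1) stop("trans_corr must be in [-1, 1]")
  if (cfg$frac_hyper < 0 || cfg$frac_hyper > 1) stop("frac_hyper must be in [0, 1]")
  counts <- c(cfg$n_mrna, cfg$n_lncrna, cfg$n_peaks_a, cfg$n_peaks_b,
              cfg$n_diff_peaks, cfg$n_de_lncrna, cfg$n_mirna, cfg$n_trans_pairs)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (cfg$bindings_per_lncrna < 5 || cfg$bindings_per_mirna < 5) {
    stop("bindings_per_lncrna and bindings_per_mirna must be >= 5")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(cfg$conditions) != 2) stop("exactly two condition labels required")
  if (abs(sum(cfg$peaks_per_lncrna_probs) - 1) > 1e-9) {
    stop("peaks_per_lncrna_probs must sum to 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

# largest-remainder allocation of n among probabilities p (exact counts)
allocate_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic annotation with planted positional classes
#'
#' Each lncRNA is constructed geometrically to satisfy exactly its planted
#' class under the classifier's documented rules. Every lncRNA lives in its
#' own 50 kb block (with a dedicated partner mRNA for the five
#' mRNA-relative classes), so no lncRNA accidentally satisfies a
#' higher-priority class; remaining mRNAs get standalone blocks. Blocks are
#' laid out 100 per synthetic chromosome.
#'
#' @param config A [sim_config()].
#' @return list with `catalog` (a `TranscriptCatalog`) and `truth`
#'   (data.frame `lncrna_id`, `class`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_lnc <- config$n_lncrna
  counts <- allocate_counts(n_lnc, config$class_proportions)
  classes <- rep(positional_classes(), counts)
  if (n_lnc > 0) classes <- sample(classes)          # mix classes across blocks
  needed_mrna <- sum(classes != "intergenic")
  if (config$n_mrna < needed_mrna) {
    stop("sizing error: ", needed_mrna, " partner mRNAs needed but n_mrna = ",
         config$n_mrna)
  }
  n_standalone <- config$n_mrna - needed_mrna
  n_blocks <- n_lnc + n_standalone
  stride <- 50000
  blocks_per_chrom <- 100

  tx <- list(); ex <- list()
  add_tx <- function(tid, gid, chrom, strand, biotype, exons) {
    tx[[length(tx) + 1]] <<- data.frame(
      transcript_id = tid, gene_id = gid, chrom = chrom,
      start = min(exons$start), end = max(exons$end),
      strand = strand, biotype = biotype, stringsAsFactors = FALSE)
    ex[[length(ex) + 1]] <<- data.frame(
      transcript_id = tid, start = exons$start, end = exons$end,
      stringsAsFactors = FALSE)
  }
  rint <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1)
  flip <- function(s) if (s == "+") "-" else "+"

  make_mrna <- function(tid, chrom, base, strand) {
    l1 <- rint(800, 1200); i1 <- rint(1500, 2500)
    l2 <- rint(600, 1000); i2 <- rint(2000, 3000)
    l3 <- rint(800, 1200)
    s1 <- base
    e <- data.frame(start = c(s1, s1 + l1 + i1, s1 + l1 + i1 + l2 + i2),
                    end = c(s1 + l1, s1 + l1 + i1 + l2, s1 + l1 + i1 + l2 + i2 + l3))
    add_tx(tid, paste0("G_", tid), chrom, strand, "mRNA", e)
    list(exons = e, strand = strand,
         intron1 = c(e$end[1], e$start[2]))   # first intron [start, end)
  }

  truth_id <- character(0); truth_class <- character(0)
  mrna_i <- 0; lnc_i <- 0
  for (b in seq_len(n_blocks)) {
    chrom <- paste0("chr", (b - 1) %/% blocks_per_chrom + 1)
    base <- 20000 + ((b - 1) %% blocks_per_chrom) * stride
    if (b <= n_lnc) {
      lnc_i <- lnc_i + 1
      cl <- classes[lnc_i]
      lid <- sprintf("LNC%04d", lnc_i)
      if (cl == "intergenic") {
        len <- rint(500, 900)
        add_tx(lid, paste0("G_", lid), chrom, sample(c("+", "-"), 1), "lncRNA",
               data.frame(start = base, end = base + len))
      } else {
        mrna_i <- mrna_i + 1
        mid <- sprintf("MRNA%04d", mrna_i)
        mstrand <- sample(c("+", "-"), 1)
        m <- make_mrna(mid, chrom, base, mstrand)
        i1 <- m$intron1
        if (cl == "exon_sense_overlapping" || cl == "natural_antisense") {
          ov <- rint(200, 500); len <- rint(700, 900)
          s <- m$exons$end[1] - ov
          lstrand <- if (cl == "exon_sense_overlapping") mstrand else flip(mstrand)
          add_tx(lid, paste0("G_", lid), chrom, lstrand, "lncRNA",
                 data.frame(start = s, end = s + len))
        } else if (cl == "intron_sense_overlapping") {
          off <- rint(50, 200); l1 <- rint(250, 350)
          gap <- rint(100, 200); l2 <- rint(300, 400)
          s1 <- i1[1] + off
          add_tx(lid, paste0("G_", lid), chrom, mstrand, "lncRNA",
                 data.frame(start = c(s1, s1 + l1 + gap),
                            end = c(s1 + l1, s1 + l1 + gap + l2)))
        } else if (cl == "intronic_antisense") {
          off <- rint(150, 300)
          len <- rint(400, min(700, (i1[2] - i1[1]) - off - 150))
          s <- i1[1] + off
          add_tx(lid, paste0("G_", lid), chrom, flip(mstrand), "lncRNA",
                 data.frame(start = s, end = s + len))
        } else {  # bidirectional
          d <- rint(100, 900); len <- rint(500, 800)
          if (mstrand == "+") {
            e <- base - d          # lncRNA TSS (its end, '-' strand)
            add_tx(lid, paste0("G_", lid), chrom, "-", "lncRNA",
                   data.frame(start = e - len, end = e))
          } else {
            s <- m$exons$end[3] + d
            add_tx(lid, paste0("G_", lid), chrom, "+", "lncRNA",
                   data.frame(start = s, end = s + len))
          }
        }
      }
      truth_id <- c(truth_id, lid); truth_class <- c(truth_class, cl)
    } else {
      mrna_i <- mrna_i + 1
      make_mrna(sprintf("MRNA%04d", mrna_i), chrom, base, sample(c("+", "-"), 1))
    }
  }
  transcripts <- if (length(tx)) do.call(rbind, tx) else
    data.frame(transcript_id = character(0), gene_id = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), biotype = character(0))
  exons <- if (length(ex)) do.call(rbind, ex) else
    data.frame(transcript_id = character(0), start = numeric(0), end = numeric(0))
  list(catalog = transcript_catalog(transcripts, exons),
       truth = data.frame(lncrna_id = truth_id, class = truth_class,
                          stringsAsFactors = FALSE))
}

#' Generate two-condition m6A peak sets with planted differential peaks
#'
#' Peaks are placed on non-overlapping `peak_width` slots of lncRNA exons,
#' so every peak lies on a lncRNA exon by construction and peaks of
#' different slots never overlap. Shared peaks occupy identical exonic
#' intervals in both conditions; per-lncRNA peak multiplicities in
#' condition A follow `peaks_per_lncrna_probs`. A subset of the shared
#' peaks is planted differential: the condition enrichments are set to
#' `base*sqrt(fc)` and `base/sqrt(fc)` so the enrichment ratio equals the
#' planted fold change exactly, with direction hypermethylated for a
#' `frac_hyper` share.
#'
#' @param config A [sim_config()].
#' @param catalog Catalog from [generate_annotation()].
#' @return list with `peaks_a`, `peaks_b` (peak data.frames), `diff_peaks`
#'   (diffreps-style differential records) and `truth` (list: `peaks` with
#'   host/shared labels and cross-condition pair ids, `diff` with planted
#'   directions and fold changes).
#' @export
generate_peak_sets <- function(config, catalog) {
  stopifnot(inherits(config, "sim_config"), inherits(catalog, "TranscriptCatalog"))
  nA <- config$n_peaks_a; nB <- config$n_peaks_b
  f <- config$shared_peak_fraction
  n_shared <- round(f * (nA + nB) / (1 + f))
  if (n_shared > min(nA, nB)) {
    stop("shared_peak_fraction infeasible: shared count ", n_shared,
         " exceeds a condition's peak count")
  }
  if (config$n_diff_peaks > n_shared) {
    stop("n_diff_peaks (", config$n_diff_peaks, ") exceeds shared peak count (",
         n_shared, ")")
  }
  empty_peaks <- data.frame(peak_id = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            strand = character(0), fold_enrichment = numeric(0),
                            p_value = numeric(0), condition = character(0),
                            stringsAsFactors = FALSE)
  empty_diff <- data.frame(peak_id = character(0), chrom = character(0),
                           start = numeric(0), end = numeric(0),
                           strand = character(0), lncrna_id = character(0),
                           fold_change = numeric(0), direction = character(0),
                           stringsAsFactors = FALSE)
  lnc_ids <- catalog$transcripts$transcript_id[catalog$transcripts$biotype == "lncRNA"]
  if (!length(lnc_ids) || (nA + nB) == 0) {
    return(list(peaks_a = empty_peaks, peaks_b = empty_peaks,
                diff_peaks = empty_diff,
                truth = list(peaks = data.frame(), diff = data.frame())))
  }
  # slot pool: non-overlapping peak_width windows on lncRNA exons
  w <- config$peak_width
  exl <- catalog$exons[catalog$exons$transcript_id %in% lnc_ids, , drop = FALSE]
  slots <- do.call(rbind, lapply(seq_len(nrow(exl)), function(i) {
    k <- (exl$end[i] - exl$start[i]) %/% w
    if (k < 1) return(NULL)
    data.frame(lncrna_id = exl$transcript_id[i], chrom = exl$chrom[i],
               start = exl$start[i] + (seq_len(k) - 1) * w,
               stringsAsFactors = FALSE)
  }))
  slots$end <- slots$start + w
  slots$used <- FALSE

  probs <- config$peaks_per_lncrna_probs
  draw_hosts <- function(n_peaks, pool) {
    # per-host multiplicities until n_peaks covered; truncate the last host
    hosts <- character(0); mult <- integer(0); total <- 0
    pool <- sample(pool)
    for (h in pool) {
      if (total >= n_peaks) break
      avail <- sum(!slots$used[slots$lncrna_id == h])
      if (avail < 1) next
      m <- sample.int(length(probs), 1, prob = probs)
      m <- min(m, avail, n_peaks - total)
      hosts <- c(hosts, h); mult <- c(mult, m); total <- total + m
    }
    if (total < n_peaks) stop("not enough lncRNA exon slots for the requested peaks")
    list(hosts = hosts, mult = mult)
  }
  take_slots <- function(hosts, mult) {
    idx <- integer(0)
    for (i in seq_along(hosts)) {
      cand <- which(slots$lncrna_id == hosts[i] & !slots$used)
      pick <- if (length(cand) == 1) cand else sample(cand, mult[i])
      pick <- pick[seq_len(mult[i])]
      slots$used[pick] <<- TRUE
      idx <- c(idx, pick)
    }
    idx
  }

  ha <- draw_hosts(nA, lnc_ids)
  idx_a <- take_slots(ha$hosts, ha$mult)
  shared_pos <- if (n_shared > 0) sample(seq_len(nA), n_shared) else integer(0)
  n_b_unique <- nB - n_shared
  hb <- if (n_b_unique > 0) draw_hosts(n_b_unique, lnc_ids) else
    list(hosts = character(0), mult = integer(0))
  idx_b_unique <- if (n_b_unique > 0) take_slots(hb$hosts, hb$mult) else integer(0)

  condA <- config$conditions[1]; condB <- config$conditions[2]
  mk_peaks <- function(idx, ids, cond, enrich) {
    data.frame(peak_id = ids, chrom = slots$chrom[idx],
               start = slots$start[idx], end = slots$end[idx], strand = "*",
               fold_enrichment = enrich, p_value = NA_real_, condition = cond,
               stringsAsFactors = FALSE)
  }
  ids_a <- sprintf("%s_peak_%04d", condA, seq_len(nA))
  e_a <- stats::rlnorm(nA, config$enrich_meanlog, config$enrich_sdlog)
  # condition-B peaks: shared intervals first, then B-unique
  ids_b <- sprintf("%s_peak_%04d", condB, seq_len(nB))
  idx_b <- c(idx_a[shared_pos], idx_b_unique)
  e_b <- c(e_a[shared_pos] * exp(stats::rnorm(n_shared, 0, config$enrich_noise_sd)),
           stats::rlnorm(n_b_unique, config$enrich_meanlog, config$enrich_sdlog))

  # plant differential peaks among the shared ones
  n_diff <- config$n_diff_peaks
  diff_sel <- if (n_diff > 0) sample(seq_len(n_shared), n_diff) else integer(0)
  diff_dir <- character(0); diff_fc <- numeric(0)
  if (n_diff > 0) {
    diff_dir <- ifelse(stats::runif(n_diff) < config$frac_hyper,
                       "hypermethylated", "hypomethylated")
    diff_fc <- stats::rlnorm(n_diff, config$diff_fc_meanlog, config$diff_fc_sdlog)
    diff_fc <- pmax(diff_fc, 1.5)   # keep planted ratios clear of ties
    a_pos <- shared_pos[diff_sel]
    base <- e_a[a_pos]
    up <- diff_dir == "hypermethylated"
    e_a[a_pos] <- base * ifelse(up, sqrt(diff_fc), 1 / sqrt(diff_fc))
    e_b[diff_sel] <- base * ifelse(up, 1 / sqrt(diff_fc), sqrt(diff_fc))
  }
  peaks_a <- mk_peaks(idx_a, ids_a, condA, e_a)
  peaks_b <- mk_peaks(idx_b, ids_b, condB, e_b)

  host_a <- slots$lncrna_id[idx_a]
  host_b <- slots$lncrna_id[idx_b]
  truth_peaks <- rbind(
    data.frame(peak_id = ids_a, condition = condA, lncrna_id = host_a,
               shared = seq_len(nA) %in% shared_pos,
               pair_id = ifelse(seq_len(nA) %in% shared_pos,
                                ids_b[match(seq_len(nA), shared_pos)], NA_character_),
               stringsAsFactors = FALSE),
    data.frame(peak_id = ids_b, condition = condB, lncrna_id = host_b,
               shared = seq_len(nB) <= n_shared,
               pair_id = c(ids_a[shared_pos], rep(NA_character_, n_b_unique)),
               stringsAsFactors = FALSE))
  diff_truth <- if (n_diff > 0) {
    a_pos <- shared_pos[diff_sel]
    data.frame(peak_id = ids_a[a_pos], lncrna_id = host_a[a_pos],
               chrom = slots$chrom[idx_a[a_pos]],
               start = slots$start[idx_a[a_pos]],
               end = slots$end[idx_a[a_pos]],
               fold_change = diff_fc, direction = diff_dir,
               stringsAsFactors = FALSE)
  } else {
    data.frame(peak_id = character(0), lncrna_id = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               fold_change = numeric(0), direction = character(0))
  }
  diff_peaks <- data.frame(
    peak_id = diff_truth$peak_id, chrom = diff_truth$chrom,
    start = diff_truth$start, end = diff_truth$end, strand = "*",
    lncrna_id = diff_truth$lncrna_id, fold_change = diff_truth$fold_change,
    direction = diff_truth$direction, stringsAsFactors = FALSE)
  list(peaks_a = peaks_a, peaks_b = peaks_b, diff_peaks = diff_peaks,
       truth = list(peaks = truth_peaks, diff = diff_truth))
}

#' Generate a per-sample FPKM expression table with planted structure
#'
#' Baseline log-FPKM is log-normal. For methylated lncRNAs, the baseline is
#' coupled to the log fold enrichment of their strongest condition-A peak
#' through a Gaussian copula whose Pearson parameter is derived from the
#' target Spearman `meth_expr_corr` (`2*sin(pi*rho/6)`). `n_de_lncrna`
#' lncRNAs get a planted log2 fold change applied to the case samples.
#' Planted trans-target mRNA profiles are constructed to have exactly the
#' planted sample Pearson correlation with their lncRNA profile.
#'
#' @param config A [sim_config()].
#' @param catalog Catalog from [generate_annotation()].
#' @param peak_truth `truth$peaks` from [generate_peak_sets()] (or NULL for
#'   no methylation coupling); condition-A enrichments are looked up from
#'   `peaks_a`.
#' @param peaks_a Condition-A peak data.frame (for the enrichment values).
#' @param trans_pairs Optional data.frame `lncrna_id`, `mrna_id`, `r`
#'   overriding the default planting of `n_trans_pairs` pairs.
#' @return list with `expression` (data.frame as in
#'   [read_expression_table()], mRNAs included) and `truth` (list: `de`
#'   data.frame, `trans` data.frame, `meth_expr` data.frame of the coupled
#'   lncRNAs with their methylation level).
#' @export
generate_expression_matrix <- function(config, catalog, peak_truth = NULL,
                                       peaks_a = NULL, trans_pairs = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(catalog, "TranscriptCatalog"))
  tx <- catalog$transcripts
  n_tx <- nrow(tx)
  ns <- config$n_samples_per_condition
  condA <- config$conditions[1]; condB <- config$conditions[2]
  samples <- c(paste0(condA, "_", seq_len(ns)), paste0(condB, "_", seq_len(ns)))
  is_case <- rep(c(TRUE, FALSE), each = ns)
  empty <- data.frame(transcript_id = character(0))
  if (n_tx == 0 || ns == 0) {
    return(list(expression = empty,
                truth = list(de = data.frame(), trans = data.frame(),
                             meth_expr = data.frame())))
  }

  # baseline mean log-FPKM, with methylation coupling for methylated lncRNAs
  mu <- config$fpkm_meanlog + config$fpkm_sdlog * stats::rnorm(n_tx)
  names(mu) <- tx$transcript_id
  meth_expr_truth <- data.frame()
  if (!is.null(peak_truth) && nrow(peak_truth) && !is.null(peaks_a)) {
    pa <- peak_truth[peak_truth$condition == condA, , drop = FALSE]
    enr <- peaks_a$fold_enrichment[match(pa$peak_id, peaks_a$peak_id)]
    lev <- tapply(enr, pa$lncrna_id, max)           # methylation level = max enrichment
    meth_ids <- names(lev)
    m <- length(meth_ids)
    if (m >= 2) {
      rho_p <- 2 * sin(pi * config$meth_expr_corr / 6)
      z <- stats::qnorm((rank(as.numeric(lev), ties.method = "average") - 0.5) / m)
      eps <- stats::rnorm(m)
      mu[meth_ids] <- config$fpkm_meanlog +
        config$fpkm_sdlog * (rho_p * z + sqrt(max(0, 1 - rho_p^2)) * eps)
      meth_expr_truth <- data.frame(lncrna_id = meth_ids,
                                    meth_level = as.numeric(lev),
                                    stringsAsFactors = FALSE)
    }
  }

  # planted differential expression on lncRNAs
  lnc_ids <- tx$transcript_id[tx$biotype == "lncRNA"]
  n_de <- min(config$n_de_lncrna, length(lnc_ids))
  de_ids <- if (n_de > 0) sample(lnc_ids, n_de) else character(0)
  de_sign <- ifelse(stats::runif(n_de) < config$frac_up_de, 1, -1)
  de_l2fc <- abs(stats::rnorm(n_de, config$de_log2fc_mean, config$de_log2fc_sd))
  delta <- stats::setNames(rep(0, n_tx), tx$transcript_id)
  delta[de_ids] <- de_sign * de_l2fc * log(2)        # natural-log shift on case samples

  # per-sample log-FPKM
  logf <- matrix(rep(mu, 2 * ns), nrow = n_tx, ncol = 2 * ns,
                 dimnames = list(tx$transcript_id, samples))
  logf[, is_case] <- logf[, is_case] + delta
  logf <- logf + config$noise_sd * matrix(stats::rnorm(n_tx * 2 * ns), n_tx)

  # planted trans-target pairs: exact sample Pearson correlation
  if (is.null(trans_pairs)) {
    mrna_ids <- tx$transcript_id[tx$biotype == "mRNA"]
    k <- min(config$n_trans_pairs, length(mrna_ids),
             length(setdiff(lnc_ids, de_ids)))
    trans_pairs <- if (k > 0 && config$noise_sd > 0) {
      data.frame(lncrna_id = sample(setdiff(lnc_ids, de_ids), k),
                 mrna_id = sample(mrna_ids, k),
                 r = config$trans_corr, stringsAsFactors = FALSE)
    } else data.frame(lncrna_id = character(0), mrna_id = character(0),
                      r = numeric(0))
  }
  if (nrow(trans_pairs) && config$noise_sd <= 0) {
    stop("trans-target planting needs noise_sd > 0 (sample profiles are constant otherwise)")
  }
  for (i in seq_len(nrow(trans_pairs))) {
    x <- logf[trans_pairs$lncrna_id[i], ]
    xc <- x - mean(x)
    if (sum(xc^2) == 0) stop("trans-target planting infeasible: constant lncRNA profile")
    wraw <- stats::rnorm(length(x))
    wc <- wraw - mean(wraw)
    wc <- wc - sum(wc * xc) / sum(xc^2) * xc          # orthogonal to x
    if (sum(wc^2) == 0) stop("trans-target planting degenerate noise draw")
    r <- trans_pairs$r[i]
    y <- r * xc / sqrt(sum(xc^2)) + sqrt(1 - r^2) * wc / sqrt(sum(wc^2))
    logf[trans_pairs$mrna_id[i], ] <- mu[trans_pairs$mrna_id[i]] +
      y * config$noise_sd * sqrt(length(x))           # rescale to sample-noise magnitude
  }

  fpkm <- exp(logf)
  mean_a <- rowMeans(fpkm[, is_case, drop = FALSE])
  mean_b <- rowMeans(fpkm[, !is_case, drop = FALSE])
  ratio <- ifelse(mean_b == 0, ifelse(mean_a == 0, NA_real_, Inf), mean_a / mean_b)
  fold_change <- ifelse(is.na(ratio), 0, pmax(ratio, 1 / ratio))
  regulation <- ifelse(is.na(ratio), "unchanged",
                       ifelse(ratio >= config$de_fc_threshold, "up",
                              ifelse(ratio <= 1 / config$de_fc_threshold, "down",
                                     "unchanged")))
  p_value <- vapply(seq_len(n_tx), function(i) {
    a <- logf[i, is_case]; b <- logf[i, !is_case]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (abs(mean(a) - mean(b)) > 0) 0 else 1)
    }
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
  }, numeric(1))

  expression <- data.frame(transcript_id = tx$transcript_id,
                           stringsAsFactors = FALSE)
  for (s in samples) expression[[s]] <- unname(fpkm[, s])
  expression$fold_change <- unname(fold_change)
  expression$p_value <- unname(p_value)
  expression$regulation <- unname(regulation)
  attr(expression, "samples") <- data.frame(
    sample = samples, condition = rep(config$conditions, each = ns),
    stringsAsFactors = FALSE)

  de_truth <- data.frame(transcript_id = de_ids,
                         log2fc = de_sign * de_l2fc,
                         regulation = ifelse(de_sign > 0, "up", "down"),
                         stringsAsFactors = FALSE)
  list(expression = expression,
       truth = list(de = de_truth, trans = trans_pairs,
                    meth_expr = meth_expr_truth))
}

#' Generate scored binding-prediction tables
#'
#' Scores within each source are strictly distinct, so the top-5 selection
#' is unique. In `disjoint` mode every lncRNA's partner miRNAs and every
#' miRNA's partner mRNAs are globally unique, so downstream ceRNA node
#' counts obey the k / k^2 law exactly.
#'
#' @param config A [sim_config()].
#' @param screened_ids lncRNA ids to predict partners for.
#' @param disjoint Make partner sets globally disjoint (default FALSE).
#' @return list with `lnc_mi` and `mi_mrna` binding data.frames
#'   (`source_id`, `target_id`, `score`).
#' @export
generate_binding_predictions <- function(config, screened_ids, disjoint = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  screened_ids <- sort(unique(screened_ids))
  n_lnc <- length(screened_ids)
  kl <- config$bindings_per_lncrna
  km <- config$bindings_per_mirna
  if (n_lnc == 0) {
    empty <- data.frame(source_id = character(0), target_id = character(0),
                        score = numeric(0))
    return(list(lnc_mi = empty, mi_mrna = empty))
  }
  if (disjoint) {
    if (config$n_mirna < n_lnc * kl) {
      stop("disjoint mode infeasible: need ", n_lnc * kl, " miRNAs, have ",
           config$n_mirna)
    }
    mi_pool <- matrix(sprintf("hsa-mir-sim-%04d", seq_len(n_lnc * kl)),
                      nrow = n_lnc, byrow = TRUE)
  } else {
    mirnas <- sprintf("hsa-mir-sim-%04d", seq_len(config$n_mirna))
    if (config$n_mirna < kl) stop("n_mirna smaller than bindings_per_lncrna")
    mi_pool <- t(vapply(seq_len(n_lnc), function(i) sample(mirnas, kl),
                        character(kl)))
  }
  lnc_mi <- data.frame(source_id = rep(screened_ids, each = kl),
                       target_id = as.vector(t(mi_pool)),
                       score = stats::runif(n_lnc * kl, 50, 200),
                       stringsAsFactors = FALSE)
  used_mirnas <- sort(unique(lnc_mi$target_id))
  n_mi <- length(used_mirnas)
  if (disjoint) {
    mrna_pool <- matrix(sprintf("TGT%05d", seq_len(n_mi * km)),
                        nrow = n_mi, byrow = TRUE)
  } else {
    mrnas <- sprintf("TGT%05d", seq_len(max(4 * km, n_mi)))
    mrna_pool <- t(vapply(seq_len(n_mi), function(i) sample(mrnas, km),
                          character(km)))
  }
  mi_mrna <- data.frame(source_id = rep(used_mirnas, each = km),
                        target_id = as.vector(t(mrna_pool)),
                        score = stats::runif(n_mi * km, 50, 200),
                        stringsAsFactors = FALSE)
  # enforce strictly distinct scores within each source (resample ties)
  dedup_scores <- function(b) {
    for (s in unique(b$source_id)) {
      i <- which(b$source_id == s)
      while (anyDuplicated(b$score[i])) b$score[i] <- stats::runif(length(i), 50, 200)
    }
    b
  }
  list(lnc_mi = dedup_scores(lnc_mi), mi_mrna = dedup_scores(mi_mrna))
}

#' Generate a complete synthetic study on disk
#'
#' Runs every generator component under sub-seeds derived from
#' `config$seed` by fixed offsets and writes the study bundle: GTF
#' annotation, two BED6+ peak tables, a diffreps-dialect differential
#' table, the expression TSV, two binding TSVs, a disease-flag list and the
#' ground truth as JSON. Byte-deterministic under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory objects (`catalog`,
#'   `peaks_a`, `peaks_b`, `diff_peaks`, `expression`, `bindings`,
#'   `truth`) and `files` (named paths).
#' @export
generate_full_study <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  set.seed(seed)
  ann <- generate_annotation(config)
  set.seed(seed + 1000L)
  pk <- generate_peak_sets(config, ann$catalog)
  set.seed(seed + 2000L)
  ex <- generate_expression_matrix(config, ann$catalog,
                                   peak_truth = pk$truth$peaks,
                                   peaks_a = pk$peaks_a)

  # screened candidates: differentially methylated above the default
  # methylation screen plus DE lncRNAs above the expression screen; all are
  # flagged disease-associated so the flag does not alter the FC screen
  expr <- ex$expression
  lnc_ids <- ann$catalog$transcripts$transcript_id[
    ann$catalog$transcripts$biotype == "lncRNA"]
  de_expr <- expr[expr$transcript_id %in% lnc_ids &
                    expr$regulation %in% c("up", "down"), , drop = FALSE]
  screened <- sort(unique(c(
    pk$diff_peaks$lncrna_id[pk$diff_peaks$fold_change > 7],
    de_expr$transcript_id[de_expr$fold_change > 2.5])))
  disease_flags <- sort(unique(c(pk$diff_peaks$lncrna_id, de_expr$transcript_id)))
  set.seed(seed + 3000L)
  bind <- generate_binding_predictions(config, screened)

  files <- c(gtf = "annotation.gtf",
             peaks_a = paste0("peaks_", config$conditions[1], ".bed"),
             peaks_b = paste0("peaks_", config$conditions[2], ".bed"),
             diff_peaks = "diff_peaks.tsv",
             expression = "expression.tsv",
             lnc_mi = "bindings_lnc_mirna.tsv",
             mi_mrna = "bindings_mirna_mrna.tsv",
             disease_flags = "disease_flags.tsv",
             ground_truth = "ground_truth.json")
  files <- stats::setNames(file.path(outdir, files), names(files))
  write_gtf(ann$catalog, files[["gtf"]])
  write_peak_table(pk$peaks_a, files[["peaks_a"]])
  write_peak_table(pk$peaks_b, files[["peaks_b"]])
  write_diff_peak_table(pk$diff_peaks, files[["diff_peaks"]])
  write_expression_table(ex$expression, files[["expression"]])
  write_binding_table(bind$lnc_mi, files[["lnc_mi"]])
  write_binding_table(bind$mi_mrna, files[["mi_mrna"]])
  writeLines(disease_flags, files[["disease_flags"]])

  truth <- list(classes = as.list(stats::setNames(ann$truth$class, ann$truth$lncrna_id)),
                peaks = pk$truth$peaks,
                diff = pk$truth$diff,
                de = ex$truth$de,
                trans = ex$truth$trans,
                meth_expr = ex$truth$meth_expr,
                screened = screened,
                disease_flags = disease_flags,
                seed = seed)
  jsonlite::write_json(truth, files[["ground_truth"]], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(catalog = ann$catalog, peaks_a = pk$peaks_a,
                 peaks_b = pk$peaks_b, diff_peaks = pk$diff_peaks,
                 expression = ex$expression, bindings = bind,
                 truth = truth, files = files))
}
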