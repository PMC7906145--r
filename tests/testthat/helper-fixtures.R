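# Fixtures built in code; no binary files.

# hand-built toy catalog: one 3-exon mRNA per archetype situation plus
# lncRNAs realizing each positional relationship
toy_catalog <- function() {
  tx <- data.frame(
    transcript_id = c("M1", "M2", "L_es", "L_is", "L_na", "L_ia", "L_bi", "L_ig"),
    gene_id = paste0("G", 1:8),
    chrom = "chr1",
    start = c(10000, 200000, 10800, 11200, 10800, 11300, 8800, 150000),
    end = c(20000, 210000, 11600, 12100, 11600, 11900, 9700, 150800),
    strand = c("+", "+", "+", "+", "-", "-", "-", "+"),
    biotype = c("mRNA", "mRNA", rep("lncRNA", 6)),
    stringsAsFactors = FALSE)
  ex <- rbind(
    data.frame(transcript_id = "M1", start = c(10000, 13000, 19000),
               end = c(11000, 14000, 20000)),
    data.frame(transcript_id = "M2", start = c(200000, 205000),
               end = c(201000, 210000)),
    data.frame(transcript_id = "L_es", start = 10800, end = 11600),
    data.frame(transcript_id = "L_is", start = c(11200, 11700),
               end = c(11500, 12100)),
    data.frame(transcript_id = "L_na", start = 10800, end = 11600),
    data.frame(transcript_id = "L_ia", start = 11300, end = 11900),
    data.frame(transcript_id = "L_bi", start = 8800, end = 9700),
    data.frame(transcript_id = "L_ig", start = 150000, end = 150800))
  transcript_catalog(tx, ex)
}

# random unconstrained catalog (valid invariants, arbitrary geometry) for
# index/filter equivalence checks
make_random_catalog <- function(n, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    chrom <- paste0("chr", sample(1:3, 1))
    start <- sample(1:500000, 1)
    n_ex <- sample(1:3, 1)
    widths <- sample(100:800, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1) sample(50:2000, n_ex - 1, replace = TRUE) else integer(0)
    s <- start + c(0, cumsum(widths[-n_ex] + gaps))
    e <- s + widths
    tid <- sprintf("T%04d", i)
    list(tx = data.frame(transcript_id = tid, gene_id = paste0("G", tid),
                         chrom = chrom, start = min(s), end = max(e),
                         strand = sample(c("+", "-"), 1),
                         biotype = sample(c("mRNA", "lncRNA"), 1),
                         stringsAsFactors = FALSE),
         ex = data.frame(transcript_id = tid, start = s, end = e))
  })
  transcript_catalog(do.call(rbind, lapply(rows, `[[`, "tx")),
                     do.call(rbind, lapply(rows, `[[`, "ex")))
}

random_peaks <- function(n, seed, chroms = paste0("chr", 1:3),
                         max_pos = 500000, condition = "A") {
  set.seed(seed)
  start <- sample(seq_len(max_pos), n)
  width <- sample(50:300, n, replace = TRUE)
  data.frame(peak_id = sprintf("%s_pk%04d", condition, seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             strand = sample(c("+", "-", "*"), n, replace = TRUE),
             fold_enrichment = stats::rlnorm(n, 1, 0.5),
             p_value = NA_real_, condition = condition,
             stringsAsFactors = FALSE)
}

# small sim config for fast end-to-end tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_lncrna = 40, n_mrna = 35, n_peaks_a = 25,
             n_peaks_b = 20, n_diff_peaks = 10, n_de_lncrna = 6,
             n_trans_pairs = 2, ...)
}
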