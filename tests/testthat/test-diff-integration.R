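test_that("ratio caller computes fold changes, directions and infinities", {
  a <- data.frame(peak_id = c("a1", "a2", "a3"), chrom = "chr1",
                  start = c(100, 500, 900), end = c(200, 600, 1000),
                  strand = "*", fold_enrichment = c(10, 3, 2),
                  p_value = NA_real_, condition = "A")
  b <- data.frame(peak_id = c("b1", "b2"), chrom = "chr1",
                  start = c(100, 500), end = c(200, 600), strand = "*",
                  fold_enrichment = c(2, 3), p_value = NA_real_,
                  condition = "B")
  d <- call_differential_peaks(a, b)
  expect_equal(d$fold_change[d$peak_id == "a1"], 5)
  expect_equal(d$direction[d$peak_id == "a1"], "hypermethylated")
  # equal enrichments: fold change 1, excluded at any threshold > 1
  expect_equal(d$fold_change[d$peak_id == "a2"], 1)
  # unmatched A peak: infinite fold change, host-condition direction
  expect_equal(d$fold_change[d$peak_id == "a3"], Inf)
  expect_equal(d$direction[d$peak_id == "a3"], "hypermethylated")
  d_floor <- call_differential_peaks(a, b, fc_floor = 100)
  expect_equal(d_floor$fold_change[d_floor$peak_id == "a3"], 100)
})

test_that("regulation summaries reproduce the printed-percentage arithmetic", {
  peaks <- summarize_regulation(rep(c("hypomethylated", "hypermethylated"),
                                    c(261, 135)))
  expect_equal(peaks$n_total, 396)
  expect_equal(peaks$pct_hypo, 65.9)
  expect_equal(peaks$pct_hyper, 34.1)
  lncs <- summarize_regulation(rep(c("hypomethylated", "hypermethylated"),
                                   c(251, 132)))
  expect_equal(lncs$pct_hypo, 65.5)
  expect_equal(lncs$pct_hyper, 34.5)
  expr <- summarize_regulation(rep(c("up", "down"), c(44, 119)))
  expect_equal(expr$n_total, 163)
  expect_equal(expr$n_hyper + expr$n_hypo, 163)
  empty <- summarize_regulation(character(0))
  expect_true(is.na(empty$pct_hyper))
  expect_error(summarize_regulation("sideways"), "unknown direction")
})

test_that("length binning uses exonic length with 1000/200 bp bins", {
  tx <- data.frame(transcript_id = c("L1", "L2", "L3"),
                   gene_id = paste0("g", 1:3), chrom = "chr1",
                   start = c(0, 5000, 20000), end = c(2000, 6500, 20100),
                   strand = "+", biotype = "lncRNA")
  ex <- rbind(data.frame(transcript_id = "L1", start = c(0, 1000),
                         end = c(300, 1200)),      # exonic length 500
              data.frame(transcript_id = "L2", start = 5000, end = 6500),
              data.frame(transcript_id = "L3", start = 20000, end = 20100))
  cat <- transcript_catalog(tx, ex)
  lb <- bin_lengths(c("L1", "L2"), cat)
  expect_equal(lb$fine$bin[lb$fine$n == 1], "401-600")   # L1 = 500 bp
  expect_equal(lb$coarse$fraction[lb$coarse$bin == "1-1000"], 0.5)
  expect_equal(lb$coarse$fraction[lb$coarse$bin == "1001-2000"], 0.5)
  # genomic span variant
  lb_span <- bin_lengths("L1", cat, use = "span")
  expect_equal(lb_span$coarse$bin, "1001-2000")          # span = 2000 bp
  # unresolved ids reported, not dropped silently
  lb_un <- bin_lengths(c("L1", "ghost"), cat)
  expect_equal(lb_un$unresolved, "ghost")
  # random catalog: totals equal a brute-force histogram
  rcat <- make_random_catalog(60, seed = 31)
  ids <- rcat$transcripts$transcript_id[rcat$transcripts$biotype == "lncRNA"]
  lens <- exonic_lengths(rcat, ids)[ids]
  lb_r <- bin_lengths(ids, rcat)
  for (i in seq_len(nrow(lb_r$coarse))) {
    lo <- as.numeric(sub("-.*", "", lb_r$coarse$bin[i]))
    expect_equal(lb_r$coarse$n[i], sum(lens >= lo & lens <= lo + 999))
  }
})

test_that("chromosome fractions per direction sum to 1 and match group-by", {
  cd <- chromosome_distribution(rep("chr1", 4), rep("hypomethylated", 4))
  expect_equal(cd$fraction, 1)
  set.seed(5)
  chrom <- sample(paste0("chr", 1:5), 40, TRUE)
  dir <- sample(c("hypermethylated", "hypomethylated"), 40, TRUE)
  cd2 <- chromosome_distribution(chrom, dir)
  for (d in unique(dir)) {
    expect_equal(sum(cd2$fraction[cd2$direction == d]), 1)
    for (ch in unique(chrom)) {
      row <- cd2[cd2$direction == d & cd2$chrom == ch, ]
      want <- sum(chrom == ch & dir == d)
      expect_equal(if (nrow(row)) row$n else 0L, want)
    }
  }
  # 3/20 on one chromosome -> 0.15
  cd3 <- chromosome_distribution(rep(c("chr19", "chr2"), c(3, 17)),
                                 rep("hypomethylated", 20))
  expect_equal(cd3$fraction[cd3$chrom == "chr19"], 0.15)
  # labels normalized to chr prefix
  cd4 <- chromosome_distribution(c("1", "chr1"), rep("up", 2))
  expect_equal(nrow(cd4), 1)
})

test_that("mean fold change per class excludes infinities and computes SEM", {
  recs <- data.frame(lncrna_id = c("L1", "L1", "L2"),
                     fold_change = c(2, 4, Inf),
                     direction = c("hypermethylated", "hypermethylated",
                                   "hypermethylated"))
  cls <- c(L1 = "intergenic", L2 = "bidirectional")
  out <- mean_fold_change_by_class(recs, cls)
  row <- out$summary[out$summary$class == "intergenic" &
                       out$summary$direction == "hypermethylated", ]
  expect_equal(row$mean, 3)
  expect_equal(row$sem, 1)
  bid <- out$summary[out$summary$class == "bidirectional" &
                       out$summary$direction == "hypermethylated", ]
  expect_true(is.na(bid$mean))   # all-infinite class -> NA with n = 0
  expect_equal(bid$n, 0)
  expect_equal(out$n_infinite_excluded, 1)
})

test_that("methylation-expression cross-tabulation is exhaustive and exclusive", {
  meth <- data.frame(lncrna_id = sprintf("L%03d", 1:383),
                     direction = rep(c("hypomethylated", "hypermethylated"),
                                     c(251, 132)))
  # 5 of the hypomethylated also down-expressed; plus 10 DE-only lncRNAs
  expr <- data.frame(transcript_id = c(sprintf("L%03d", 1:5),
                                       sprintf("X%02d", 1:10)),
                     regulation = rep(c("down", "up"), c(5, 10)))
  j <- join_methylation_expression(meth, expr)
  expect_equal(j$hypo_down, 5)
  expect_equal(j$hyper_up + j$hyper_down, 0)
  expect_equal(sum(j$table), length(union(meth$lncrna_id, expr$transcript_id)))
  expect_error(join_methylation_expression(rbind(meth, meth[1, ]), expr),
               "duplicate")
  disjoint <- join_methylation_expression(
    data.frame(lncrna_id = "A", direction = "hypomethylated"),
    data.frame(transcript_id = "B", regulation = "up"))
  expect_equal(disjoint$hypo_up + disjoint$hypo_down, 0)
})

test_that("correlation wrapper matches the rank oracle and handles bad pairs", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  expect_equal(correlate_levels(x, x, "spearman")$estimate, 1)
  expect_equal(correlate_levels(x, -x, "spearman")$estimate, -1)
  set.seed(6)
  a <- rnorm(20); b <- 0.5 * a + rnorm(20)
  got <- correlate_levels(a, b, "spearman")
  expect_equal(got$estimate, oracle_spearman(a, b), tolerance = 1e-12)
  expect_equal(got$n, 20)
  # infinite values dropped pairwise, n reported
  a2 <- c(a, Inf); b2 <- c(b, 1)
  expect_equal(correlate_levels(a2, b2, "spearman")$n, 20)
  expect_error(correlate_levels(c(1, 2), c(3, 4)), "fewer than 3")
})

test_that("cumulative |log2FC| curves match a counting ECDF and KS separations", {
  ann <- data.frame(peak_id = "p1", lncrna_id = "L1")
  same <- data.frame(transcript_id = c("L1", "L2"), fold_change = c(4, 4),
                     regulation = c("up", "down"))
  cc <- cumulative_log2fc(same, ann)
  expect_equal(cc$ks_D, 0)
  apart <- data.frame(transcript_id = c("L1", "L2"), fold_change = c(1, 4),
                      regulation = c("unchanged", "up"))
  expect_equal(cumulative_log2fc(apart, ann)$ks_D, 1)
  # ECDF values equal the counting oracle; infinities clamped, all retained
  set.seed(7)
  expr <- data.frame(transcript_id = sprintf("L%03d", 1:50),
                     fold_change = c(rlnorm(48, 1, 1), Inf, Inf),
                     regulation = "up")
  ann2 <- data.frame(peak_id = sprintf("p%d", 1:20),
                     lncrna_id = sprintf("L%03d", 1:20))
  cc2 <- cumulative_log2fc(expr, ann2)
  expect_equal(cc2$n_clamped, 2)
  expect_equal(cc2$n_m6a + cc2$n_non_m6a, 50)
  expect_equal(cc2$m6a$fractions,
               oracle_ecdf(cc2$m6a$values, cc2$m6a$values))
  expect_true(all(diff(cc2$non_m6a$fractions) >= 0))
  expect_error(cumulative_log2fc(same[0, ], ann), "empty")
})

test_that("KS D between identically distributed groups shrinks at n = 2000", {
  set.seed(8)
  expr <- data.frame(transcript_id = sprintf("L%04d", 1:4000),
                     fold_change = rlnorm(4000, 1, 1),
                     regulation = "up")
  ann <- data.frame(peak_id = sprintf("p%d", 1:2000),
                    lncrna_id = sprintf("L%04d", 1:2000))
  expect_lt(cumulative_log2fc(expr, ann)$ks_D, 0.06)
})

test_that("2^-ddCt fold change follows the closed form", {
  expect_equal(ddct_fold_change(20, 18, 22, 20), 1)
  expect_equal(ddct_fold_change(20, 18, 24, 18), 16)
  set.seed(9)
  for (i in 1:25) {
    ct <- runif(4, 15, 30)
    expect_equal(ddct_fold_change(ct[1], ct[2], ct[3], ct[4]),
                 2^(-((ct[1] - ct[2]) - (ct[3] - ct[4]))))
  }
})

test_that("hypergeometric enrichment equals closed forms and enumeration", {
  # query identical to the only set over a universe equal to the set
  out <- enrichment_test(sprintf("g%d", 1:5),
                         list(S = sprintf("g%d", 1:5)),
                         sprintf("g%d", 1:5))
  expect_equal(out$p_value, 1)
  # N=10, K=5, n=5, k=5 -> 1/C(10,5)
  uni <- sprintf("g%d", 1:10)
  out2 <- enrichment_test(sprintf("g%d", 1:5),
                          list(S = sprintf("g%d", 1:5)), uni)
  expect_equal(out2$p_value, 1 / choose(10, 5))
  # 50 random sets vs enumeration oracle at N = 20
  set.seed(10)
  uni20 <- sprintf("g%02d", 1:20)
  sets <- lapply(1:50, function(i) sample(uni20, sample(3:12, 1)))
  names(sets) <- sprintf("S%02d", 1:50)
  query <- sample(uni20, 7)
  out3 <- enrichment_test(query, sets, uni20)
  for (i in seq_len(nrow(out3))) {
    expect_equal(out3$p_value[i],
                 oracle_hyper_p(out3$k[i], out3$K[i], out3$n[i], out3$N[i]),
                 tolerance = 1e-12)
  }
  expect_error(enrichment_test("g1", sets, character(0)), "empty universe")
  expect_error(enrichment_test("zz", sets, uni20), "outside the universe")
})

test_that("BH adjustment is monotone over random p-vectors", {
  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(3:30, 1))
    adj <- p.adjust(p, "BH")
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))
  }
})
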