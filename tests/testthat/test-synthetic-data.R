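test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(shared_peak_fraction = 1.2), "shared_peak_fraction")
  expect_error(sim_config(meth_expr_corr = 2), "meth_expr_corr")
  expect_error(sim_config(bindings_per_lncrna = 3), ">= 5")
  bad_props <- c(exon_sense_overlapping = 0.5, intron_sense_overlapping = 0.1,
                 natural_antisense = 0.1, intronic_antisense = 0.1,
                 bidirectional = 0.1, intergenic = 0.2)
  expect_error(sim_config(class_proportions = bad_props), "sum to 1")
})

test_that("planted positional classes are recovered exactly", {
  props <- stats::setNames(rep(1 / 6, 6), positional_classes())
  cfg <- sim_config(seed = 7, n_lncrna = 60, n_mrna = 55,
                    class_proportions = props,
                    n_peaks_a = 30, n_peaks_b = 25, n_diff_peaks = 10)
  set.seed(7)
  ann <- generate_annotation(cfg)
  cls <- classify_catalog(ann$catalog)
  expect_equal(unname(cls$classes[ann$truth$lncrna_id]), ann$truth$class)
  # exact 10-per-class allocation
  expect_equal(unname(table(ann$truth$class)[positional_classes()]),
               rep(10L, 6), ignore_attr = TRUE)
  expect_equal(cls$proportions$proportion, rep(1 / 6, 6))
})

test_that("single-class limit puts every lncRNA far from mRNAs", {
  props <- stats::setNames(c(0, 0, 0, 0, 0, 1), positional_classes())
  cfg <- sim_config(seed = 2, n_lncrna = 12, n_mrna = 5,
                    class_proportions = props, n_peaks_a = 6, n_peaks_b = 6,
                    n_diff_peaks = 2)
  set.seed(2)
  ann <- generate_annotation(cfg)
  tx <- ann$catalog$transcripts
  lnc <- tx[tx$biotype == "lncRNA", ]
  mr <- tx[tx$biotype == "mRNA", ]
  for (i in seq_len(nrow(lnc))) {
    same <- mr[mr$chrom == lnc$chrom[i], ]
    if (nrow(same)) {
      gaps <- pmax(same$start - lnc$end[i], lnc$start[i] - same$end, 0)
      expect_true(all(gaps >= 10000))
    }
  }
})

test_that("annotation generation is deterministic and sizing-checked", {
  cfg <- small_sim_config(seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  set.seed(5); a1 <- generate_annotation(cfg)
  write_gtf(a1$catalog, f1 <- tempfile(fileext = ".gtf"))
  set.seed(5); a2 <- generate_annotation(cfg)
  write_gtf(a2$catalog, f2 <- tempfile(fileext = ".gtf"))
  expect_identical(readLines(f1), readLines(f2))
  expect_error({set.seed(1); generate_annotation(sim_config(n_lncrna = 50, n_mrna = 2))},
               "sizing error")
})

test_that("peak sets realize the planted Venn structure and lie on lncRNA exons", {
  cfg <- sim_config(seed = 3, n_lncrna = 100, n_mrna = 80, n_peaks_a = 83,
                    n_peaks_b = 71, shared_peak_fraction = 0.375,
                    n_diff_peaks = 40)
  set.seed(3)
  ann <- generate_annotation(cfg)
  set.seed(4)
  pk <- generate_peak_sets(cfg, ann$catalog)
  v <- compare_peak_sets(pk$peaks_a, pk$peaks_b)
  expect_equal(v$shared, 42)                       # round(.375*154/1.375)
  expect_equal(v$shared_fraction, 42 / (83 + 71 - 42))
  # every peak on a lncRNA exon: the filter retains all of them
  annp <- filter_peaks_to_lncrna_exons(pk$peaks_a, ann$catalog)
  expect_setequal(unique(annp$peak_id), pk$peaks_a$peak_id)
  annp_b <- filter_peaks_to_lncrna_exons(pk$peaks_b, ann$catalog)
  expect_setequal(unique(annp_b$peak_id), pk$peaks_b$peak_id)

  # shared_peak_fraction = 1 with equal counts leaves no unique peaks
  cfg1 <- sim_config(seed = 3, n_lncrna = 60, n_mrna = 50, n_peaks_a = 20,
                     n_peaks_b = 20, shared_peak_fraction = 1, n_diff_peaks = 5)
  set.seed(3); ann1 <- generate_annotation(cfg1)
  set.seed(4); pk1 <- generate_peak_sets(cfg1, ann1$catalog)
  v1 <- compare_peak_sets(pk1$peaks_a, pk1$peaks_b)
  expect_equal(v1$unique_a, 0)
  expect_equal(v1$unique_b, 0)
})

test_that("hypermethylated share of planted differential peaks is binomially consistent", {
  hyper <- numeric(10)
  for (s in 1:10) {
    cfg <- sim_config(seed = s, n_lncrna = 150, n_mrna = 120, n_peaks_a = 130,
                      n_peaks_b = 120, n_diff_peaks = 60, frac_hyper = 0.341)
    set.seed(s); ann <- generate_annotation(cfg)
    set.seed(s + 100); pk <- generate_peak_sets(cfg, ann$catalog)
    hyper[s] <- sum(pk$truth$diff$direction == "hypermethylated")
  }
  n <- 60 * 10
  expect_lt(abs(sum(hyper) - n * 0.341), 3 * sqrt(n * 0.341 * 0.659))
})

test_that("planted differential labels survive the ratio caller", {
  cfg <- small_sim_config(seed = 9)
  set.seed(9); ann <- generate_annotation(cfg)
  set.seed(10); pk <- generate_peak_sets(cfg, ann$catalog)
  called <- call_differential_peaks(pk$peaks_a, pk$peaks_b)
  m <- match(pk$truth$diff$peak_id, called$peak_id)
  expect_false(anyNA(m))
  expect_equal(called$direction[m], pk$truth$diff$direction)
  expect_equal(called$fold_change[m], pk$truth$diff$fold_change,
               tolerance = 1e-10)
})

test_that("methylation-expression copula hits its Spearman limits", {
  # rho = 1, noise-free copula: Spearman exactly 1
  cfg <- sim_config(seed = 21, n_lncrna = 80, n_mrna = 70, n_peaks_a = 60,
                    n_peaks_b = 50, n_diff_peaks = 20, meth_expr_corr = 1)
  set.seed(21); ann <- generate_annotation(cfg)
  set.seed(22); pk <- generate_peak_sets(cfg, ann$catalog)
  set.seed(23)
  ex <- generate_expression_matrix(cfg, ann$catalog, pk$truth$peaks, pk$peaks_a)
  mt <- ex$truth$meth_expr
  smp <- attr(ex$expression, "samples")
  ca <- smp$sample[smp$condition == "CRC"]
  fpkm <- rowMeans(ex$expression[, ca])
  names(fpkm) <- ex$expression$transcript_id
  de <- ex$truth$de$transcript_id
  keep <- !mt$lncrna_id %in% de      # DE shifts move case-mean FPKM off the copula
  rho <- oracle_spearman(mt$meth_level[keep], as.numeric(fpkm[mt$lncrna_id[keep]]))
  expect_gt(rho, 0.9)

  # rho = 0: near-zero correlation at moderate n
  cfg0 <- sim_config(seed = 31, n_lncrna = 500, n_mrna = 400, n_peaks_a = 450,
                     n_peaks_b = 420, shared_peak_fraction = 0.375,
                     n_diff_peaks = 100, meth_expr_corr = 0, n_de_lncrna = 0)
  set.seed(31); ann0 <- generate_annotation(cfg0)
  set.seed(32); pk0 <- generate_peak_sets(cfg0, ann0$catalog)
  set.seed(33)
  ex0 <- generate_expression_matrix(cfg0, ann0$catalog, pk0$truth$peaks,
                                    pk0$peaks_a)
  mt0 <- ex0$truth$meth_expr
  fpkm0 <- rowMeans(ex0$expression[, ca])
  names(fpkm0) <- ex0$expression$transcript_id
  rho0 <- oracle_spearman(mt0$meth_level, as.numeric(fpkm0[mt0$lncrna_id]))
  expect_lt(abs(rho0), 0.2)
})

test_that("planted trans-target pairs carry exactly the planted sample correlation", {
  cfg <- small_sim_config(seed = 13, trans_corr = 0.99)
  set.seed(13); ann <- generate_annotation(cfg)
  set.seed(14); pk <- generate_peak_sets(cfg, ann$catalog)
  set.seed(15)
  ex <- generate_expression_matrix(cfg, ann$catalog, pk$truth$peaks, pk$peaks_a)
  smp <- attr(ex$expression, "samples")$sample
  tp <- ex$truth$trans
  expect_gt(nrow(tp), 0)
  for (i in seq_len(nrow(tp))) {
    x <- log(unlist(ex$expression[ex$expression$transcript_id == tp$lncrna_id[i],
                                  smp]))
    y <- log(unlist(ex$expression[ex$expression$transcript_id == tp$mrna_id[i],
                                  smp]))
    expect_equal(stats::cor(x, y), 0.99, tolerance = 1e-8)
  }
})

test_that("binding scores are strictly distinct per source; disjoint mode gives the node-count law", {
  cfg <- sim_config(seed = 2, n_mirna = 200)
  ids <- sprintf("L%02d", 1:16)
  set.seed(2)
  b <- generate_binding_predictions(cfg, ids, disjoint = TRUE)
  net <- build_cerna_network(ids, b$lnc_mi, b$mi_mrna, k = 5)
  expect_equal(sum(net$nodes$type == "lncRNA"), 16)
  expect_equal(sum(net$nodes$type == "miRNA"), 80)
  expect_equal(sum(net$nodes$type == "mRNA"), 400)

  set.seed(3)
  for (rep in 1:20) {
    b <- generate_binding_predictions(cfg, sprintf("L%02d", 1:5))
    for (tab in b) {
      per_source <- split(tab$score, tab$source_id)
      expect_true(all(vapply(per_source,
                             function(s) !anyDuplicated(s), logical(1))))
    }
  }
  expect_error(generate_binding_predictions(sim_config(n_mirna = 10),
                                            ids, disjoint = TRUE),
               "disjoint mode infeasible")
})

test_that("the full study bundle is byte-deterministic and reader-clean", {
  cfg <- small_sim_config(seed = 1)
  d1 <- file.path(tempdir(), "study_det_1")
  d2 <- file.path(tempdir(), "study_det_2")
  s1 <- generate_full_study(cfg, d1)
  s2 <- generate_full_study(cfg, d2)
  for (nm in names(s1$files)) {
    expect_identical(unname(tools::md5sum(s1$files[[nm]])),
                     unname(tools::md5sum(s2$files[[nm]])), label = nm)
  }
  # every emitted file loads through its reader without error
  expect_silent(pa <- read_peak_table(s1$files[["peaks_a"]], "CRC", "bed6+"))
  expect_silent(pb <- read_peak_table(s1$files[["peaks_b"]], "NC", "bed6+"))
  expect_silent(dp <- read_peak_table(s1$files[["diff_peaks"]],
                                      dialect = "diffreps"))
  expect_silent(ex <- read_expression_table(s1$files[["expression"]]))
  expect_silent(read_binding_table(s1$files[["lnc_mi"]]))
  expect_silent(read_binding_table(s1$files[["mi_mrna"]]))
  cat2 <- read_gtf(s1$files[["gtf"]])
  expect_equal(length(cat2), cfg$n_lncrna + cfg$n_mrna)
  expect_equal(nrow(pa), cfg$n_peaks_a)
  expect_equal(nrow(dp), cfg$n_diff_peaks)
})

test_that("an empty study degrades cleanly end to end", {
  cfg <- sim_config(seed = 1, n_lncrna = 0, n_mrna = 5, n_peaks_a = 0,
                    n_peaks_b = 0, n_diff_peaks = 0, n_de_lncrna = 0,
                    n_trans_pairs = 0)
  d <- file.path(tempdir(), "study_empty")
  s <- generate_full_study(cfg, d)
  cat0 <- read_gtf(s$files[["gtf"]])
  expect_equal(sum(cat0$transcripts$biotype == "lncRNA"), 0)
  annp <- filter_peaks_to_lncrna_exons(s$peaks_a, cat0)
  expect_equal(nrow(annp), 0)
  expect_equal(nrow(peaks_per_lncrna_distribution(annp)), 0)
  cls <- classify_catalog(cat0)
  expect_length(cls$classes, 0)
})
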