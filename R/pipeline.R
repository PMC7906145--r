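#' Assemble and validate a pipeline configuration
#'
#' Bundles the input paths and every analysis threshold used by
#' [run_pipeline()]. All referenced files must exist at validation time.
#'
#' @param gtf GTF annotation path.
#' @param peaks_a,peaks_b BED6+ peak tables for case and control.
#' @param diff_peaks diffreps-dialect differential-methylation table.
#' @param expression Expression TSV (see [read_expression_table()]).
#' @param lnc_mi,mi_mrna Binding-prediction TSVs (optional: networks are
#'   skipped without them).
#' @param disease_flags Text file with one disease-associated lncRNA id per
#'   line (optional).
#' @param gmt GMT gene-set collection for enrichment (optional).
#' @param outdir Output directory.
#' @param conditions Two condition labels (case first).
#' @param min_overlap_bp Exon-overlap threshold for peak filtering.
#' @param bidirectional_window TSS window for the bidirectional class (bp).
#' @param cis_window Cis-target window (bp).
#' @param trans_threshold Trans-target |Pearson r| threshold.
#' @param cnc_threshold CNC-network |Pearson r| threshold.
#' @param meth_fc_threshold,expr_fc_threshold ceRNA screen thresholds.
#' @param top_k Partners per node in the ceRNA network.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(gtf, peaks_a, peaks_b, diff_peaks, expression,
                            lnc_mi = NULL, mi_mrna = NULL,
                            disease_flags = NULL, gmt = NULL,
                            outdir = "lncm6a_out",
                            conditions = c("CRC", "NC"),
                            min_overlap_bp = 1,
                            bidirectional_window = 1000,
                            cis_window = 10000,
                            trans_threshold = 0.9,
                            cnc_threshold = 0.95,
                            meth_fc_threshold = 7,
                            expr_fc_threshold = 2.5,
                            top_k = 5) {
  cfg <- as.list(environment())
  required <- c("gtf", "peaks_a", "peaks_b", "diff_peaks", "expression")
  for (nm in required) {
    if (!file.exists(cfg[[nm]])) stop("config error: missing input file '", nm,
                                      "': ", cfg[[nm]])
  }
  for (nm in c("lnc_mi", "mi_mrna", "disease_flags", "gmt")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]])) {
      stop("config error: missing input file '", nm, "': ", cfg[[nm]])
    }
  }
  stopifnot(min_overlap_bp >= 1, bidirectional_window >= 0, cis_window >= 0,
            trans_threshold > 0, cnc_threshold > 0,
            meth_fc_threshold > 0, expr_fc_threshold > 0, top_k >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — peak annotation, positional
#' classification, differential summaries, methylation-expression
#' integration, target inference and network construction — writing every
#' stage's TSV under `config$outdir` plus `summary.json` (the headline
#' counts, percentages, correlations and network sizes) and `manifest.json`
#' (config hash and package version). A rerun on identical inputs is
#' byte-identical. Any stage failure halts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list()

  inputs <- stage("read-inputs", {
    list(catalog = read_gtf(config$gtf),
         peaks_a = read_peak_table(config$peaks_a, config$conditions[1], "bed6+"),
         peaks_b = read_peak_table(config$peaks_b, config$conditions[2], "bed6+"),
         diff_peaks = read_peak_table(config$diff_peaks, dialect = "diffreps"),
         expression = read_expression_table(config$expression),
         lnc_mi = if (!is.null(config$lnc_mi)) read_binding_table(config$lnc_mi),
         mi_mrna = if (!is.null(config$mi_mrna)) read_binding_table(config$mi_mrna),
         disease_flags = if (!is.null(config$disease_flags))
           readLines(config$disease_flags),
         gmt = if (!is.null(config$gmt)) read_gmt(config$gmt))
  })
  catalog <- inputs$catalog
  lnc_ids <- catalog$transcripts$transcript_id[catalog$transcripts$biotype == "lncRNA"]

  ann <- stage("annotate-peaks", {
    ann_a <- filter_peaks_to_lncrna_exons(inputs$peaks_a, catalog,
                                          config$min_overlap_bp)
    ann_b <- filter_peaks_to_lncrna_exons(inputs$peaks_b, catalog,
                                          config$min_overlap_bp)
    write_tsv(ann_a, file.path(config$outdir, "annotated_peaks_a.tsv"))
    write_tsv(ann_b, file.path(config$outdir, "annotated_peaks_b.tsv"))
    venn <- compare_peak_sets(ann_a[!duplicated(ann_a$peak_id), , drop = FALSE],
                              ann_b[!duplicated(ann_b$peak_id), , drop = FALSE],
                              config$min_overlap_bp)
    dist_a <- peaks_per_lncrna_distribution(ann_a)
    write_tsv(dist_a, file.path(config$outdir, "peaks_per_lncrna_a.tsv"))
    report$peaks <- list(
      n_peaks_a = length(unique(ann_a$peak_id)),
      n_peaks_b = length(unique(ann_b$peak_id)),
      n_lncrna_a = length(unique(ann_a$lncrna_id)),
      n_lncrna_b = length(unique(ann_b$lncrna_id)),
      venn = unclass(venn),
      single_peak_fraction_a = if (nrow(dist_a)) dist_a$fraction[dist_a$bin == "1"]
      else NA_real_)
    list(a = ann_a, b = ann_b)
  })

  cls <- stage("classify", {
    res <- classify_catalog(catalog,
                            bidirectional_window = config$bidirectional_window)
    if (length(res$classes)) {
      write_tsv(data.frame(lncrna_id = names(res$classes),
                           class = unname(res$classes)),
                file.path(config$outdir, "positional_classes.tsv"))
    }
    write_tsv(res$proportions, file.path(config$outdir, "class_proportions.tsv"))
    report$classes <- stats::setNames(as.list(res$proportions$proportion),
                                        res$proportions$class)
    res
  })

  diff <- stage("differential-summaries", {
    dp <- inputs$diff_peaks
    peak_reg <- summarize_regulation(dp$direction)
    # lncRNA-level direction: a lncRNA takes the direction of its largest-
    # fold-change differential peak
    ord <- order(-ifelse(is.infinite(dp$fold_change), .Machine$double.xmax,
                         dp$fold_change), dp$lncrna_id)
    lnc_level <- dp[ord, , drop = FALSE]
    lnc_level <- lnc_level[!duplicated(lnc_level$lncrna_id), , drop = FALSE]
    lnc_reg <- summarize_regulation(lnc_level$direction)
    in_catalog <- lnc_level$lncrna_id %in% lnc_ids
    lb <- bin_lengths(lnc_level$lncrna_id[in_catalog], catalog,
                      lnc_level$direction[in_catalog])
    write_tsv(lb$coarse, file.path(config$outdir, "length_bins_coarse.tsv"))
    write_tsv(lb$fine, file.path(config$outdir, "length_bins_fine.tsv"))
    cd <- chromosome_distribution(lnc_level$chrom, lnc_level$direction)
    write_tsv(cd, file.path(config$outdir, "chromosome_distribution.tsv"))
    mfc <- mean_fold_change_by_class(dp[dp$lncrna_id %in% names(cls$classes), ,
                                        drop = FALSE], cls$classes)
    write_tsv(mfc$summary, file.path(config$outdir, "fold_change_by_class.tsv"))
    expr <- inputs$expression
    de <- expr[expr$transcript_id %in% lnc_ids &
                 expr$regulation %in% c("up", "down"), , drop = FALSE]
    de_reg <- summarize_regulation(de$regulation)
    report$differential <- list(
      peaks = peak_reg, lncrnas = lnc_reg,
      expression = list(n_total = de_reg$n_total, n_up = de_reg$n_hyper,
                        n_down = de_reg$n_hypo, pct_up = de_reg$pct_hyper,
                        pct_down = de_reg$pct_hypo))
    list(lnc_level = lnc_level, de = de)
  })

  integ <- stage("integration", {
    joined <- join_methylation_expression(
      diff$lnc_level[, c("lncrna_id", "direction")],
      diff$de[, c("transcript_id", "regulation")])
    expr <- inputs$expression
    samples <- attr(expr, "samples")
    cond_a_samples <- samples$sample[samples$condition == config$conditions[1]]
    meth_level <- tapply(ann$a$fold_enrichment, ann$a$lncrna_id, max)
    corr <- NULL
    if (length(meth_level) >= 3 && length(cond_a_samples)) {
      fpkm_a <- rowMeans(expr[, cond_a_samples, drop = FALSE])
      names(fpkm_a) <- expr$transcript_id
      common <- intersect(names(meth_level), names(fpkm_a))
      if (length(common) >= 3) {
        corr <- correlate_levels(as.numeric(meth_level[common]),
                                 as.numeric(fpkm_a[common]), "spearman")
      }
    }
    curves <- NULL
    pooled <- rbind(ann$a, ann$b)
    lnc_expr <- expr[expr$transcript_id %in% lnc_ids, , drop = FALSE]
    if (length(unique(pooled$lncrna_id)) &&
        any(!lnc_expr$transcript_id %in% pooled$lncrna_id)) {
      curves <- cumulative_log2fc(lnc_expr, pooled)
    }
    report$integration <- list(
      meth_expr_overlap = joined[c("hyper_up", "hyper_down",
                                   "hypo_up", "hypo_down")],
      meth_expr_spearman = if (!is.null(corr)) corr else NA,
      cumulative_ks_D = if (!is.null(curves)) curves$ks_D else NA_real_)
    list(joined = joined, corr = corr, curves = curves)
  })

  if (!is.null(inputs$gmt)) {
    stage("enrichment", {
      universe <- catalog$transcripts$gene_id[catalog$transcripts$biotype == "mRNA"]
      near <- unique(unlist(lapply(
        intersect(diff$lnc_level$lncrna_id, lnc_ids), function(id) {
          m <- find_cis_targets(id, catalog, config$cis_window)
          catalog$transcripts$gene_id[match(m, catalog$transcripts$transcript_id)]
        })))
      near <- intersect(near, universe)
      if (length(near) && length(universe)) {
        enr <- enrichment_test(near, inputs$gmt, universe)
        write_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
        report$enrichment <- list(n_query = length(near),
                                    n_sets = nrow(enr),
                                    top_set = if (nrow(enr)) enr$set[1] else NA)
      }
      NULL
    })
  }

  nets <- stage("networks", {
    out <- list()
    expr <- inputs$expression
    samples <- attr(expr, "samples")$sample
    if (!is.null(inputs$lnc_mi) && !is.null(inputs$mi_mrna)) {
      flags <- if (!is.null(inputs$disease_flags)) inputs$disease_flags else
        character(0)
      screened <- screen_cerna_candidates(
        diff$lnc_level[, c("lncrna_id", "fold_change")],
        diff$de[, c("transcript_id", "fold_change")],
        flags,
        meth_fc_threshold = config$meth_fc_threshold,
        expr_fc_threshold = config$expr_fc_threshold,
        require_disease_flag = !is.null(inputs$disease_flags))
      write_tsv(screened, file.path(config$outdir, "screened_candidates.tsv"))
      cerna <- build_cerna_network(screened$lncrna_id, inputs$lnc_mi,
                                   inputs$mi_mrna, config$top_k)
      write_network_edges(cerna, file.path(config$outdir, "cerna_edges.tsv"))
      nt <- table(factor(cerna$nodes$type, levels = c("lncRNA", "miRNA", "mRNA")))
      report$cerna <- list(n_screened = nrow(screened),
                             n_lncrna = nt[["lncRNA"]], n_mirna = nt[["miRNA"]],
                             n_mrna = nt[["mRNA"]], n_edges = nrow(cerna$edges))
      out$cerna <- cerna
      out$screened <- screened
    }
    mrna_ids <- catalog$transcripts$transcript_id[catalog$transcripts$biotype == "mRNA"]
    lnc_rows <- expr$transcript_id %in% intersect(diff$de$transcript_id, lnc_ids)
    mrna_rows <- expr$transcript_id %in% mrna_ids
    if (sum(lnc_rows) && sum(mrna_rows) && length(samples) >= 3) {
      lx <- as.matrix(expr[lnc_rows, samples, drop = FALSE])
      rownames(lx) <- expr$transcript_id[lnc_rows]
      mx <- as.matrix(expr[mrna_rows, samples, drop = FALSE])
      rownames(mx) <- expr$transcript_id[mrna_rows]
      cnc <- build_cnc_network(lx, mx, config$cnc_threshold)
      write_network_edges(cnc, file.path(config$outdir, "cnc_edges.tsv"))
      report$cnc <- list(n_lncrna = length(unique(cnc$edges$lncrna_id)),
                           n_mrna = length(unique(cnc$edges$mrna_id)),
                           n_edges = nrow(cnc$edges))
      out$cnc <- cnc
    }
    out
  })

  stage("report", {
    cfg_for_hash <- config[!names(config) %in% "outdir"]
    cfg_json <- file.path(config$outdir, "config.json")
    jsonlite::write_json(cfg_for_hash, cfg_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest <- list(config_hash = unname(tools::md5sum(cfg_json)),
                     package = "lncm6a",
                     version = as.character(utils::packageVersion("lncm6a")))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(report, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    NULL
  })
  invisible(report)
}

#' Generate a synthetic study bundle (pipeline-ready)
#'
#' Thin wrapper over [generate_full_study()] that also returns a
#' [pipeline_config()] pointing at the emitted files, so
#' `run_pipeline(simulate_study(sim_config(seed = 1), dir)$config)` runs the
#' full pipeline end to end on synthetic data.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory for the bundle.
#' @return list with `study` (see [generate_full_study()]) and `config`
#'   (a `pipeline_config`).
#' @export
simulate_study <- function(config, outdir) {
  study <- generate_full_study(config, outdir)
  f <- study$files
  pcfg <- pipeline_config(
    gtf = f[["gtf"]], peaks_a = f[["peaks_a"]], peaks_b = f[["peaks_b"]],
    diff_peaks = f[["diff_peaks"]], expression = f[["expression"]],
    lnc_mi = f[["lnc_mi"]], mi_mrna = f[["mi_mrna"]],
    disease_flags = f[["disease_flags"]],
    outdir = file.path(outdir, "pipeline_out"),
    conditions = config$conditions)
  list(study = study, config = pcfg)
}
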