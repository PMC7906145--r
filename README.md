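# lncm6a

Downstream analysis of **N6-methyladenosine (m6A) modification of long
non-coding RNAs** from MeRIP-seq peak calls and RNA-seq expression tables,
for a two-condition design (e.g. tumor vs tumor-adjacent tissue).

m6A is the most abundant internal RNA modification; on lncRNAs it is a
candidate regulatory layer in cancer. Given peak calls (MACS-style BED
tables with IP/input fold enrichment), a differential-methylation table, a
transcript annotation (GTF) and per-sample FPKM expression, `lncm6a`
computes the standard landscape and integration statistics of such a study:

* **Peak annotation** — filter m6A peaks to lncRNA exons (strand-aware,
  unstranded peaks match both strands), count peaks per lncRNA, and build
  the cross-condition Venn: two peaks are shared iff they overlap ≥ 1 bp,
  matched 1-1 greedily by overlap, with shared fraction
  `shared / (unique_A + unique_B + shared)`.
* **Positional classification** — each lncRNA receives one of six classes
  against the mRNA annotation, by first-match priority: exon
  sense-overlapping ≻ intron sense-overlapping ≻ natural antisense ≻
  intronic antisense ≻ bidirectional (divergent promoters, TSS distance
  ≤ 1 kb) ≻ intergenic.
* **Differential integration** — hyper/hypomethylation summaries (counts
  and percentages, rounded half away from zero), exonic-length and
  chromosome distributions, mean fold change per class, cross-tabulation of
  differential methylation × differential expression, Spearman correlation
  of methylation level (max peak fold enrichment) vs FPKM, cumulative
  |log2FC| curves of m6A vs non-m6A lncRNAs with a Kolmogorov–Smirnov D,
  the 2^−ΔΔCt qPCR fold change, and hypergeometric gene-set enrichment
  (upper tail P(X ≥ k), Benjamini–Hochberg adjusted) over any GMT
  collection.
* **Targets and networks** — cis targets (mRNAs within a 10 kb window,
  strict half-open gaps), trans targets (|Pearson r| ≥ 0.9 across
  samples), a ceRNA (lncRNA–miRNA–mRNA) network from top-5 binding
  partners of screened candidates (methylation FC > 7 or expression
  FC > 2.5, disease-flagged), and a signed coding–non-coding (CNC)
  co-expression network at |Pearson r| ≥ 0.95. Networks export as
  Cytoscape-importable edge lists.

Because raw data for this analysis type is typically not deposited, the
package ships a **deterministic synthetic-study generator**
(`sim_config()`, `generate_full_study()`) that emits a complete study —
GTF, peak BEDs, differential table, expression TSV, binding tables — with
known ground truth (planted positional classes, shared/unique peaks,
hyper/hypo labels, DE lncRNAs, methylation–expression correlation,
trans-target pairs), so every stage is testable end to end.

## Worked example

```r
library(lncm6a)

# a complete synthetic study (seed-deterministic), then the full pipeline
sim <- simulate_study(sim_config(seed = 1), "demo_study")
rep <- run_pipeline(sim$config)

rep$peaks$venn
#> $unique_a: 41   $unique_b: 29   $shared: 42   $shared_fraction: 0.375

rep$differential$peaks[c("n_total", "pct_hyper", "pct_hypo")]
#> $n_total: 40   $pct_hyper: 30   $pct_hypo: 70

rep$integration$meth_expr_spearman[c("estimate", "n")]
#> $estimate: 0.433   $n: 74

rep$cerna[c("n_lncrna", "n_mirna", "n_mrna")]
#> $n_lncrna: 38   $n_mirna: 98   $n_mrna: 114
```

Reading: of the 83 + 71 peaks called on lncRNA exons in the two conditions,
42 are shared (shared fraction 0.375 — the generator's planted value); 40
differential peaks split 30% hyper / 70% hypomethylated; the methylation
level of the 74 methylated lncRNAs correlates with their expression at
Spearman ρ = 0.43 (the planted copula value is 0.49; a single study of this
size estimates it with sd ≈ 0.1); and the ceRNA network over the 38
screened lncRNAs has 98 miRNA and 114 mRNA partner nodes. Every stage also
writes a TSV under `sim$config$outdir` (annotated peaks, classes, length
bins, screened candidates, edge lists, `summary.json`, `manifest.json`).

The same pipeline runs on real data by pointing `pipeline_config()` at
your GTF / BED / TSV files, or from the shell via
`Rscript inst/scripts/lncm6a.R run-all --gtf ... --outdir out`.

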