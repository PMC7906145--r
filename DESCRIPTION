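Package: lncm6a
Title: Analysis of lncRNA m6A Methylation Landscapes from MeRIP-Seq Peak Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of N6-methyladenosine (m6A) modification of long
    non-coding RNAs from MeRIP-seq peak calls and RNA-seq expression tables:
    filtering of m6A peaks to lncRNA exons, six-way positional classification of
    lncRNAs against the mRNA annotation, differential-methylation and
    differential-expression summaries and their integration (correlation,
    cross-tabulation, cumulative fold-change curves, hypergeometric gene-set
    enrichment), cis/trans target inference, and construction of competing
    endogenous RNA (ceRNA) and coding-non-coding (CNC) co-expression networks.
    Includes a deterministic synthetic-study generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
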