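Package: demi
Title: Probe-Level Differential Expression by Hypergeometric Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates differential expression of targets (genes,
    transcripts, exons, gene sets and genomic regions) directly from
    probe-level microarray intensities. Arrays are normalized to relative
    ranks, individual probes are classified as up-, down- or unchanged
    with a design-appropriate rank statistic (exact Wilcoxon-Mann-Whitney
    for two-group comparisons, Kendall's tau for monotonic time courses),
    and each target is scored by hypergeometric enrichment of its
    differentially expressed probes against the array-wide background,
    with optional censoring of large targets, a probe-multiplicity
    filter and Benjamini-Hochberg or Benjamini-Yekutieli FDR control.
    Includes a sliding-genomic-window mode for regional expression
    changes and a simulation benchmark generator and evaluator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
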