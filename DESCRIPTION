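Package: ampliMeth
Title: Methylation Haplotype Analysis for Targeted Bisulfite Amplicon
    Sequencing of Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies tissue-specific cell-free DNA from targeted
    bisulfite amplicon sequencing using per-read CpG methylation
    haplotypes. Provides an assay definition layer (amplicon reference,
    CpG offsets, primers, in-silico converted reference), a cfDNA read
    simulator (tissue methylation haplotype mixtures, fragmentation,
    bisulfite chemistry, sequencing error, spike-in dilutions and
    longitudinal cohorts), an amplicon-scale bisulfite-aware aligner with
    pair merging and quality filters, a per-molecule haplotype caller
    with non-CpG conversion-rate estimation, and exact-binomial sample
    statistics: fully-unmethylated fraction with Clopper-Pearson
    intervals, genome equivalents, negative-control limit of detection,
    spike-in calibration curves and cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
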