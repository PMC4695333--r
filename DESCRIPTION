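Package: methdeduce
Title: Reference-Free Differential DNA Methylation Analysis from RRBS Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses reduced representation bisulfite sequencing (RRBS) data
    without a reference genome. Deduces an ad hoc genome directly from the
    bisulfite reads by consensus clustering, aligns reads back to it with
    bisulfite-aware matching, calls per-CpG methylation with coverage
    filtering, detects and ranks differentially methylated CpGs and fragments
    between sample groups (moderated t-statistics, FDR control, weighted
    p-value combination, worst-of-three ranking), and interprets the results
    by reference-free motif enrichment with Markov-shuffled background
    control. Ships an RRBS simulator (in-silico MspI digestion, size
    selection, bisulfite conversion, spike-in controls) providing ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
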