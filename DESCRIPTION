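Package: garmotif
Title: Detection and Characterization of Glycine- and Arginine-Rich (GAR)
    Motifs in Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates glycine- and arginine-rich (GAR) motifs in protein
    sequences as maximal chains of RG/RGG anchor units under a bounded-wildcard
    gap grammar, computes per-motif composition statistics (RG/RGG unit counts,
    non-GR residue spectrum, G/R ratio, coverage and residue percentages),
    produces batch summaries, CSV/text reports and chart data, and supports
    proteome-scale censuses of long GAR motifs with RG-richness and
    tri/di-RGG-class labels. Ships a curated set of published motif strings as
    golden fixtures together with a seeded synthetic-motif generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
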