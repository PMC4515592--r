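Package: rhophylo
Title: Rho-Statistic Dating and Phylogeography of Mitochondrial Haplogroups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lineage-based phylogeographic analysis of human
    mitochondrial DNA. Converts rCRS-aligned sequences into haplotypes,
    builds reduced-median haplotype networks and extracts frequency-guided
    mutation-labelled trees, dates clades with the rho statistic and
    genealogy-aware (Saillard) standard errors under configurable molecular
    clocks, performs founder analysis of migrations into a sink region, and
    compares populations on the HVS-I hypervariable fragment (AMOVA-based
    FST with permutation tests, Bonferroni correction, Slatkin
    linearization, S-stress multidimensional scaling, and haplogroup
    composition tables). Includes a matrilineal coalescent simulator with
    infinite-sites mutations so every stage can be validated against known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
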