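Package: svkit
Title: Allele Typing and Amylopectin Chain-Length Dispersity Analysis for
    Maize Starch Genes
Version: 0.1.0
Authors@R: person("svkit", "maintainers", email = "svkit@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational side of a maize kernel-vitreousness
    study: global alignment and variant calling between near-identical
    starch-gene allele cDNAs (pullulanase Zpu1, starch synthase III) with
    synonymous/missense classification and protein-domain assignment;
    in-silico restriction digestion with IUPAC-degenerate recognition sites
    for CAPS genotyping (BslI); number-average and mass-average degree of
    polymerization and the dispersity index of amylopectin glucan
    chain-length distributions; and the statistical battery linking
    pullulanase activity and chain dispersity to kernel vitreousness
    (slope ANOVA, pairwise-t and Tukey HSD compact letter displays,
    exponential growth-curve regression with a growth-rate confidence
    interval). A synthetic-data generator reproduces the statistical
    structure of the study's recombinant-inbred-line panels so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
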