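Package: ranabias
Title: Sex-Biased Expression, Tissue Specificity and Molecular Evolution Across Frog Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying the dynamics of sex-biased gene
    expression across developmental stages and adult tissues in amphibians with
    homomorphic sex chromosomes. Provides expression filtering, TMM
    normalization, a conditional negative-binomial exact test for per-tissue
    sex-bias calling, the Tau tissue-specificity index, direction-turnover
    accounting between tissues, reciprocal-best-hit ortholog assignment,
    permutation tests for sex-chromosome enrichment, sliding-window genome
    scans, pairwise dN/dS estimation by Nei-Gojobori (1986) counting with
    Jukes-Cantor correction, and square-root-transformed linear models of
    evolutionary rate on sex bias and specificity. A fully seeded synthetic
    data generator emulates the multi-stage, multi-tissue study design so the
    whole pipeline is testable end to end with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    zoo,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
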