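Package: varkit
Title: Population Variation Toolkit with Compressed Genotypes, On-the-Fly
    LD and Variant Consequence Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for population variation data:
    an assembly-independent variant model with flanking-sequence mapping
    and quality control, a windowed delta-encoded binary genotype codec,
    on-the-fly pairwise linkage disequilibrium via EM haplotype-frequency
    estimation, rule-based prediction of variant consequences on transcript
    models, and compact resequencing representations (read-coverage
    intervals plus individual-sequence reconstruction). Includes
    deterministic fixture generators for toy genomes, transcripts and
    simulated population genotypes, plain-text dataset persistence, and
    FASTA/GFF3/VCF interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
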