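Package: dbsconcord
Title: Genotype Concordance Evaluation for Dried Blood Spot Exome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-calling evaluation pipeline for whole-exome sequencing of
    whole-genome-amplified DNA from dried blood spots (DBS) against matched
    whole-blood (WB) references. Merges the PASS call sets of two variant
    callers by priority, classifies variants into SNPs, insertions, deletions
    and multiallelic calls, applies a variant-level average-depth filter and a
    sample-level reference genotype-quality filter, and quantifies pairwise
    sample similarity through a five-category genotype concordance scheme with
    per-variant-type rates, replicate averaging, and exome coverage-by-depth
    summaries. A synthetic-cohort generator emulates the pilot study designs
    (subjects by sample type, allele dropout, amplification error, depth
    attenuation) so the entire pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    vcfR,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
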