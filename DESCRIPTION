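Package: musapaint
Title: Subgenome Dosage Painting and Ploidy Inference for Musa Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control of genome composition in wild and cultivated
    banana (Musa) accessions. Implements diagnostic SNP discovery between
    the A (M. acuminata) and B (M. balbisiana) subgenomes from read
    pileups, per-site B-allele dosage profiling with LOESS chromosome
    painting and Circos track export, Gaussian-mixture delta-log-likelihood
    ploidy inference from heterozygous-site allele frequencies, and
    reconciliation of observed against expected ploidy and composition.
    Includes a synthetic allopolyploid data generator (divergent subgenome
    references, composed polyploid genotypes with optional homeologous
    exchange, Poisson-depth pileups with base-call error) so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    jsonlite
Config/testthat/edition: 3
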