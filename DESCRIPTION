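Package: sigcraft
Title: Mutational Signature Extraction, Refitting and Diagnostics for
    Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of single-base-substitution mutational
    signatures from somatic SNV calls: construction of SBS96
    trinucleotide catalogs from VCF and an indexed reference genome,
    de novo signature extraction by bootstrapped non-negative matrix
    factorization with stability-based rank selection, assignment of
    extracted signatures to a reference catalog (single signatures or
    non-negative pairs), constrained refitting by non-negative least
    squares with sparse forward selection and a relative-contribution
    pruning rule, diagnostics for spurious or missing signatures
    (reconstruction-error necessity tests, exposure clustering,
    inter-sample bleeding checks via split extraction), detection and
    signature analysis of localized hypermutation (kataegis and
    immunoglobulin-locus activity), and a fully seeded synthetic-cohort
    simulator so the whole workflow is testable without controlled-access
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    cluster,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
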