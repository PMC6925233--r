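Package: mhcpipe
Title: Replicated Amplicon Genotyping, Expression Classification and
    Divergence of MHC Class I Alleles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for verifying major histocompatibility complex class I
    (MHC-I) alleles from replicated amplicon-sequencing read counts,
    classifying each expressed allele as high or low expression against a
    per-individual equal-expression threshold, separating putatively
    classical from non-classical alleles by bootstrap-supported phylogenetic
    clustering combined with expression and divergence criteria, and
    summarising sequence divergence (haplotype degeneracy, amino-acid
    P-distance, Nei-Gojobori dN/dS) per allele class.  Includes a synthetic
    cohort generator with planted truth so the full pipeline can be
    exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
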