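Package: sigchip
Title: Sigma-Factor ChIP-Seq Regulon Analysis with Simulated Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing a bacterial sigma-factor regulon from
    ChIP-seq data: a Poisson window peak caller comparing an immunoprecipitated
    (IP) library against a sonicated Input library, strand cross-correlation
    and locus-enrichment quality controls, strand-aware attribution of peaks
    to downstream promoters and genes, minus-10 element alignment with IUPAC
    consensus derivation and scoring of sigma-S promoter determinants
    (-13C/-12C/-8C/-6T and the A/T-rich discriminator), and a synthetic
    ChIP-seq experiment generator that plants binding sites with known
    enrichment so every stage can be verified against ground truth. Ships the
    published E. coli sigma-S binding-site tables as machine-readable fixtures
    and reproduces their accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
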