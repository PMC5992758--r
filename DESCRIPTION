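Package: panelcall
Title: Somatic SNV/Indel, Gene-Fusion and Copy-Number Calling for Noisy
    Targeted Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls somatic single-nucleotide variants and short indels,
    DNA-level gene fusions, and copy-number alterations from targeted
    capture sequencing of degraded (FFPE) tumor samples against an
    unmatched pooled-normal control. Variant extraction uses Fisher's
    exact test on tumor-versus-control pileups followed by a cascade of
    non-parametric noise filters driven by internal controls estimated
    from the data, including a beta-mixture model of the variant allele
    frequency distribution with ICL-BIC model selection and a
    beta-binomial test against the low-frequency error component. Fusion
    detection combines split-read mapping across gene pairs with a
    virtual-junction rescue step and optional discordant-pair evidence.
    Copy-number calling applies LOWESS GC correction, windowed circular
    binary segmentation with a Mann-Whitney statistic, a segment abortion
    rule, and bootstrap classification of amplifications and deletions.
    Seeded simulators of FFPE-like reads, chimeric fusion reads, and
    binned depth profiles make every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
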