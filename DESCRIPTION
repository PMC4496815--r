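Package: apisweep
Title: Genome-Wide Selection Scans for Small Population Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selection-scan toolkit for whole-genome SNP data from small
    population samples. Implements per-gene protein-evolution tests
    (pN/pS with Nei-Gojobori effective site counts, fixed-difference
    ratios against a reference genome, and the McDonald-Kreitman
    fixation index), genome-wide allele-frequency tests (runs of
    homozygosity, the Reich-Patterson FST estimator per SNP and
    overall, windowed Tajima's D and the Zeng-normalized Fay-Wu H), a
    locally optimal maximal-scoring-segment scanner with
    permutation-based empirical p-values, and a neutral coalescent
    simulator used to calibrate significance cutoffs. Includes
    synthetic fixture generators (island-model genotypes, selective
    sweep tracts, toy coding genes) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
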