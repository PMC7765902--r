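Package: ImprintScan
Title: Detection of Genomic Imprinting from Reciprocal-Cross
    Allele-Specific Expression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies maternally and paternally expressed genes (MEGs and
    PEGs) from allele-specific read counts measured in reciprocal hybrid
    crosses. Implements the chi-square ratio test against the 2m:1p
    (triploid endosperm) and 1m:1p (diploid embryo) parental expectations
    with fold-change filters and the requirement of consistency across both
    reciprocal crosses; builds parental pseudo-genomes by SNP/InDel
    substitution with bidirectional coordinate liftover; classifies why
    genes escape detection (no parental SNP, no allele-specific read,
    non-significant); detects mini clusters of adjacent imprinted genes and
    tests their excess against a neighbor-permutation null; quantifies
    conservation of imprinted-gene sets by permutation of an annotated
    background; and matches orthologs across species by bidirectional hit
    rate (BHR). A synthetic-data generator produces genomes, parental
    variants, cross designs and allele-specific count tables with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Epigenetics, Genetics
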