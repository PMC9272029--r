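Package: pcampr
Title: Multi-Pool Bulked-Segregant Scans and Marker Diversity for Wild Rice Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping trait loci and describing genetic diversity in
    structured plant populations. Implements a pair-wise comparison analysis for
    multiple pool-seq (PCAMP): per-site Euclidean-distance (ED) statistics
    between phenotype bulks, power correction, distance-weighted smoothing,
    median + 3 SD thresholding, candidate-interval extraction and SNP/InDel
    intersection across all pool pairs. Also provides variant-quality filters
    for pooled VCF data, per-locus co-dominant marker diversity statistics
    (observed and expected heterozygosity, Nei's gene diversity, effective
    allele number, Shannon-Weaver index, nucleotide diversity), Nei's standard
    genetic distance with UPGMA dendrograms, minimum-spanning haplotype
    networks, ABBA-BABA D statistics with block-jackknife significance, and
    synthetic-data generators that emulate phenotype bulks, selfing marker
    populations, haplotype genealogies and four-taxon frequency panels so the
    whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
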