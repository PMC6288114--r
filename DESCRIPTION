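Package: mosaicmap
Title: Window-Based Local Ancestry and Introgression Analysis for Mosaic
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates per-window ancestry of admixed individuals against
    two diverged reference populations using an FST-like per-SNP
    differentiation statistic averaged in fixed-size windows, calls
    contiguous introgressed segments, and compares their length spectrum
    against a neutral breed-formation forward simulation.  Also detects
    sites fixed for the alternative allele in a cohort with
    annotation-class enrichment tests, builds permutation nulls for
    annotation-keyword enrichment, and scans windowed read depth for
    duplication and deletion signatures at candidate loci.  Includes
    seeded generators for synthetic cohorts, diverged reference panels,
    and depth profiles with planted structural variants, so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
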