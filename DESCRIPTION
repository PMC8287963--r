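Package: MethylSites
Title: Distribution Analysis of Bacterial DNA Methylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the genomic distribution of bacterial DNA
    methylation sites, in particular the bipartite recognition motifs of
    Type I restriction-modification systems and the short palindromic
    motifs of orphan methyltransferases (Dam, Dcm). Provides degenerate
    IUPAC motif scanning on linear and circular genomes, strand-aware
    promoter windows upstream of transcription start sites, genic and
    intergenic site classification, a circular-shift (rotation) permutation
    test for promoter enrichment or depletion with empirical P-values and
    Bonferroni correction, small assay statistics (competitive index,
    transformation efficiency, delta-delta-Ct fold change, exact Wilcoxon
    signed-rank test), and a synthetic-data generator with known ground
    truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MethylSites-package.R'
    'methods.R'
    'assay-stats.R'
    'motif-scan.R'
    'site-context.R'
    'enrichment.R'
    'genome-io.R'
    'synthetic.R'
    'pipeline.R'
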