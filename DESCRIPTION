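Package: radiadiv
Title: Genome and Methylome Divergence Analysis for Adaptive Radiations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative population-genomic and population-epigenomic toolkit
    for multi-clade resequencing plus whole-genome bisulfite panels, built
    around a ten-species columbine (Aquilegia) study design. Provides windowed
    nucleotide diversity and Weir-Cockerham FST selection scans, neighbor
    joining phylogenies and PCA, Nei-Gojobori (1986) dN/dS selection classes,
    conservative clade-specific high-impact variant (CCV) calling,
    Cochran-Mantel-Haenszel differential-methylation (DMR/DMG) calling,
    CpG-island detection with genic and island metaprofiles, chromosomal
    methylation discrepancy indices, CG-loss variant regression, and an
    Eigenstrat-corrected cis-driver scan linking DMRs to nearby genotypes.
    Ships a clade-structured synthetic data generator (FASTA, GFF3, VCF,
    cytosine reports, sample sheet, truth manifest) used for benchmarking and
    calibration of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    ape,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
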