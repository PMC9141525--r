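# Population-genomic scans: windowed nucleotide diversity (pi) per clade,
# windowed Weir-Cockerham FST for the focal sister-species pair, LDGR/HDGR
# 5% tails and their overlap, LD-pruned PCA, the neighbor-joining phylogeny
# and NG86 dN/dS selection classes.

source("analysis/00_common.R")

rc <- study_config()
st <- run_pipeline(rc, stages = c("io", "popgen"))
pg <- st$popgen

say("pi computed over %d windows of 100 kb for %d clades; FST for %s vs %s.",
    nrow(pg$windows), length(pg$pi), rc$sim$dmr_comparison[1],
    rc$sim$dmr_comparison[2])
reg <- pg$regions
say("Selection-signature tails: %d LDGR and %d HDGR windows, %d overlapping.",
    nrow(reg$ldgr), nrow(reg$hdgr), nrow(reg$overlap))
say("PCA on %d LD-pruned SNPs; PC1 explains %.1f%% of variance.",
    pg$n_pruned, 100 * pg$pca$explained[1])
say("NJ tree over %d accessions written as newick.",
    length(pg$tree$tip.label))
say("dN/dS classes: %d positive, %d purifying, %d undefined of %d genes.",
    sum(pg$selection$class == "positive"),
    sum(pg$selection$class == "purifying"),
    sum(pg$selection$class == "undefined"), nrow(pg$selection))
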