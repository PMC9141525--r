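# Generate the bundled synthetic ten-species dataset: reference genome with
# planted CpG islands and gene models, clade-structured variants (including
# planted high-impact clade-fixed variants, CG-loss SNPs and cis-driver
# alleles), and per-accession bisulfite cytosine reports with planted DMRs.

source("analysis/00_common.R")

rc <- study_config()
st <- run_pipeline(rc, stages = "simulate")
sim <- st$simulate

say("Dataset written under %s/data (seed %d).", study_dir, study_seed)
say("%d accessions over %d species in %d lineages.",
    nrow(sim$sheet), length(unique(sim$sheet$species[!sim$sheet$is_hybrid])),
    length(unique(sim$sheet$lineage)))
say("%d variant records (%d QC-pass), %d CpG sites on the methylation grid.",
    nrow(sim$vars$emit$info), nrow(sim$vars$variants$info),
    length(sim$meth$mm$pos))
say("Planted truth: %d CCVs, %d DMR windows (%d with a cis driver), %d CG-loss loci.",
    nrow(sim$manifest$ccvs), nrow(sim$manifest$dmrs),
    sum(sim$manifest$dmrs$driver), sum(sim$manifest$cg_loss$carrying))
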