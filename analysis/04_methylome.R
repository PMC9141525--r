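# Methylome profiling: per-accession global CG methylation, methylome PCA,
# chromosomal methylation discrepancy index (MDI) against a reference
# accession, CpG island detection, and genic / CpG-island metaprofiles per
# lineage.

source("analysis/00_common.R")

rc <- study_config()
st <- run_pipeline(rc, stages = c("io", "methylome"))
me <- st$methylome

say("Global CG methylation: mean %.1f%% (range %.1f-%.1f%%) over %d accessions.",
    mean(me$global$pct_methylated), min(me$global$pct_methylated),
    max(me$global$pct_methylated), nrow(me$global))
say("Methylome PCA: PC1+PC2 explain %.1f%% of variance over %d QC-pass loci.",
    100 * sum(me$pca$explained[1:2]), me$pca$n_features)
say("%d CpG islands detected (median length %d bp).",
    nrow(me$islands), as.integer(median(me$islands$length)))
say("MDI computed per chromosome against the first A. viridiflora accession.")
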