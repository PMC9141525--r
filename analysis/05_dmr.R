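# Differential methylation between the focal sister species: 100-bp
# windowed CMH scan (CG sites as strata, read counts pooled per group),
# BH correction over tested windows, 25% divergence gate, and DMG calling
# (genes with >20% of their body covered by DMR windows).

source("analysis/00_common.R")

rc <- study_config()
st <- run_pipeline(rc, stages = c("io", "dmr"))
d <- st$dmr$dmrs

say("%d of %d windows tested (>=%d informative CG sites).",
    sum(d$tested), nrow(d), rc$dmr_min_sites)
say("%d DMRs pass adjusted p < %.2f and divergence > %.0f%%.",
    sum(d$is_dmr), rc$bh_alpha, 100 * rc$min_divergence)
say("%d DMGs (>%.0f%% of the genic region covered by DMRs).",
    sum(st$dmr$dmgs$is_dmg), 100 * rc$dmg_threshold)
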