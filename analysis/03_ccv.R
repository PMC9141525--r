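# Conservative clade-specific variants: high-impact annotations that are
# homozygous-fixed in every sample of the carrier clade and absent (fixed
# reference) in every sample of the reference clade, for all configured
# clade pairs, with genomic context.

source("analysis/00_common.R")

rc <- study_config()
st <- run_pipeline(rc, stages = c("io", "ccv"))

ccv <- st$ccv
say("%d CCV records across %d clade pairs (a variant fixed in one clade can",
    nrow(ccv), length(unique(paste(ccv$carrier_clade, ccv$reference_clade))))
say("  legitimately appear against several reference clades).")
say("%.1f%% of CCVs fall in gene bodies.", 100 * mean(ccv$context == "genic"))
print(table(ccv$impact_class))
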