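# Genetic-epigenetic integration: CG-loss classification of every CG locus,
# methylation-variability categories, the Eigenstrat-corrected cis-driver
# scan over called DMRs (+-500 bp, threshold grid down from 5e-5), and the
# DMG x selection-class chi-square association table.

source("analysis/00_common.R")

rc <- study_config()
st <- run_pipeline(rc, stages = c("io", "popgen", "dmr", "integrate"))
ig <- st$integrate

say("%.1f%% of CG loci carry a CG-loss variation.",
    100 * mean(ig$cg_loss$carrying))
print(table(ig$variability$category))
s <- ig$driver_summary
for (i in seq_len(nrow(s)))
  say("cis-associated DMRs at p < %g: %.1f%%", s$threshold[i],
      100 * s$associated_fraction[i])
say("DMG x selection association (unadjusted chi-square p):")
print(ig$association)
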