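# Shared setup for the numbered analysis drivers. Each driver is a thin
# narrative layer over the radiadiv package: all computation lives in R/.
# Run the drivers from the repository root, in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_popgen.R
#   ...
# Results land under results/study/.

suppressMessages(library(radiadiv))

study_seed <- as.integer(Sys.getenv("RADIADIV_SEED", "1"))
study_dir <- "results/study"

study_config <- function() {
  run_config(sim = sim_config(seed = study_seed), out_dir = study_dir)
}

say <- function(...) cat(sprintf(...), "\n")
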