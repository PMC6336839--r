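#!/usr/bin/env Rscript

# Generate the synthetic tissue-trio study used by the downstream
# analysis scripts: 9 case + 10 control donors, three specimens each,
# planted low-VAF somatic variants with a C>T-heavy spectrum, two noisy
# pseudo-caller call sets, and a germline concordance panel. All input
# files land in results/sim_study/ in exactly the formats the pipeline
# consumes.

suppressMessages(library(mosaicscan))

seed <- 1
cfg <- sim_config(seed = seed)
sim <- simulate_study(cfg)
write_simulation(sim, "results/sim_study")

cat(sprintf("Simulated %d donors / %d specimens (seed %d)\n",
            nrow(sim$donors), nrow(sim$specimens), seed))
cat(sprintf("Planted %d somatic variant observations (%d shared across both brain tissues)\n",
            nrow(sim$truth), sum(sim$truth$shared)))
cat(sprintf("Pseudo-caller candidate rows: %d (including private false positives and shared artifacts)\n",
            nrow(sim$calls)))
both <- sim$truth$detected_mutect_like & sim$truth$detected_strelka_like
cat(sprintf("Detected by both callers (eligible for consensus): %d / %d\n",
            sum(both), nrow(sim$truth)))
cat("wrote results/sim_study/\n")
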