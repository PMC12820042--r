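#!/usr/bin/env Rscript
# Simulate the desk-scale associative-inference EEG study and store the
# epochs in the native container. All later steps read from results/.

library(waversa)

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- run_config("desk", seed = seed)
design <- build_design(cfg$n_triads, cfg$n_repetitions, cfg$sample_rate_hz,
                       cfg$n_channels)
params <- simulation_params(seed = seed, n_participants = cfg$n_participants)
epochs <- generate_epochs(design, params)
print(design)
print(epochs)

write_epochs(epochs, "results/epochs")
utils::write.csv(epochs$trials, "results/trial_table.csv", row.names = FALSE)

tab <- table(epochs$trials$role, epochs$trials$repetition)
cat("trials per role x repetition (one participant in", cfg$n_participants,
    "):\n")
print(tab / cfg$n_participants)
cat("planted similarity range (BC trials):",
    round(range(epochs$trials$planted_similarity[epochs$trials$role == "BC"]), 2),
    "\n")
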