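#!/usr/bin/env Rscript
# Temporal state dynamics per subject: occurrence rate of each state,
# pairwise Markov transition probabilities (self-transitions included), and
# the global transition probability (distinct-state switches per 10-s
# window step).

library(conndyn)

seqs <- read.csv("scratch/run/state_sequences.csv")
by_sub <- split(seqs, seqs$subject_id)
by_sub <- lapply(by_sub, function(s) {
  class(s) <- c("state_sequence", "data.frame"); s
})

dyn <- cohort_dynamics(by_sub)
write.csv(dyn, "results/dynamics.csv", row.names = FALSE)

message(sprintf("%d subjects", nrow(dyn)))
message(sprintf("mean global transition probability: %.1f%% (sd %.1f)",
                100 * mean(dyn$gtp), 100 * sd(dyn$gtp)))
occ_cols <- paste0("occ_", c("S1", "S2", "S3", "S4", "S5"))
message(sprintf("mean occurrence: %s",
                paste(sprintf("%s %.2f", sub("occ_", "", occ_cols),
                              colMeans(dyn[occ_cols])), collapse = ", ")))
message(sprintf("mean self-transition probability: %.2f",
                mean(as.matrix(dyn[paste0("T_S", 1:5, "_S", 1:5)]),
                     na.rm = TRUE)))
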