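#!/usr/bin/env Rscript
# Surrogate-corrected wPLI features per 30-s window (10-s steps): multitaper
# cross-spectra (nw = 2, 3 tapers) over 2-s half-overlapping sub-windows,
# wPLI on the 0.5-35 Hz grid, 20 trial-shuffled surrogates subtracted,
# averaged over the 6 prefrontal-frontal and 9 frontal-parietal pairs.

library(conndyn)

seed <- 42
rec_dir <- "scratch/run/recordings"
meta <- read.csv("results/meta.csv")

feats <- list()
for (sid in meta$subject_id) {
  rec <- read_recording(file.path(rec_dir, paste0(sid, ".tsv")), "tabular",
                        events_path = file.path(rec_dir,
                                                paste0(sid, ".events")),
                        subject_id = sid)
  ep <- extract_maintenance(rec, "incision", "maintenance_end",
                            start_offset = 0)
  feats[[sid]] <- connectivity_features(
    ep, seed = derive_seed(seed, sid, "surrogate"))
  message(sprintf("%s: %d windows", sid, nrow(feats[[sid]])))
}
features <- do.call(rbind, feats)
write.csv(features, "scratch/run/features.csv", row.names = FALSE)

f <- spectral_config()$f_grid
fpf <- colMeans(feature_matrix(features)[, 1:70])
fp <- colMeans(feature_matrix(features)[, 71:140])
message(sprintf("%d windows x 140 features", nrow(features)))
message(sprintf("grand prefrontal-frontal wPLI peaks at %.1f Hz (%.3f)",
                f[which.max(fpf)], max(fpf)))
message(sprintf("grand frontal-parietal wPLI peaks at %.1f Hz (%.3f)",
                f[which.max(fp)], max(fp)))
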