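#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-study takeover dataset (30 x 4 x 4 +
# 28 x 2 x 4 = 704 takeover attempts) with the default post-takeover dynamics,
# and persist the event log and the analytic ground-truth stabilization times.
# The recordings themselves are regenerated deterministically by later stages
# from the same seed, so only the small tables are written here.

suppressPackageStartupMessages(library(takeoverstab))

seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- default_study_config(seed = seed)
params <- default_signal_params()
ds <- generate_study(cfg, params, seed = seed)

write_event_log(ds$events, file.path(out, "events.csv"))
write_ground_truth(ds$ground_truth, file.path(out, "ground_truth.csv"))

cat(sprintf("generated %d takeover events (%d + %d)\n", nrow(ds$events),
            sum(ds$events$study == 1), sum(ds$events$study == 2)))
cat(sprintf("gradual-braking attempts (deceleration measurable): %d (%.1f%%)\n",
            sum(ds$events$gradual_brake),
            100 * mean(ds$events$gradual_brake)))
cat("ground-truth stabilization times (s):\n")
print(ds$ground_truth, row.names = FALSE)

# one example recording written in the documented CSV schema
write_recording(ds$recordings[[1]], file.path(out, "example_recording"))
cat("example recording written to", file.path(out, "example_recording"), "\n")
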