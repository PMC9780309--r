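#!/usr/bin/env Rscript
# Simulate one half-day of a preschool badge deployment and export it in the
# field folder layout, together with the ground-truth bundle every later
# stage is scored against.
#
# A scaled deployment (3 classes x 8 children + 3 adults) keeps the whole
# analysis chain under a couple of minutes; the code paths are identical to
# the full-school configuration.

suppressMessages(library(proxinet))

out_root <- "results/deployment"
unlink(out_root, recursive = TRUE)

cfg <- sim_config(
  n_classes = 3, class_sizes = 8, n_adults = 3, seed = 20260920,
  artifacts = list(unworn_rate = 0.12, unworn_dur = c(600, 1500),
                   pile_prob = 0.5, pile_size = c(2, 3),
                   pile_dur = c(300, 600), burst_frac = 0.35, burst_s = 120,
                   silent_rate = 0.04, deaf_rate = 0.04))
sim <- simulate_half_day(cfg, day = 1, session = "M")
wk <- write_deployment(sim, out_root, "1_WEEK01")

cat("Simulated Monday morning, 3 classes:\n")
cat(sprintf("  roster: %d children, %d adults, %d RX badges\n",
            sum(sim$roster$kind == "child"), sum(sim$roster$kind == "adult"),
            sum(sim$roster$kind == "rx")))
cat(sprintf("  true contact events: %d (%.0f s of dyadic interaction)\n",
            nrow(sim$truth$events), sum(sim$truth$events$delta)))
cat(sprintf("  raw beacon records: %d\n", nrow(sim$signals)))
print(table(sim$truth$artifact_intervals$cause))
cat("  written to", wk, "\n")
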