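#!/usr/bin/env Rscript
# Simulate the study cohort: a multi-session visual Go/No-Go learning
# dataset with 10 regions, planted directed connectivity, region-specific
# stimulus latencies and an early -> expert learning trajectory.
#
# The analysis cohort is deliberately desk-scale (2 units/region, 3
# sessions of 240 trials) so the full pipeline in 03_pipeline.R runs in
# minutes; the statistical properties of every stage are established at
# larger sizes by the test suite and scripts/acceptance.R. Session roles:
#   s1 - error-rich early session (d' ~ 0.5; supplies early-stage trials
#        and passes the >= 5-trials-per-outcome inclusion rule for the
#        encoding analysis)
#   s2 - near-perfect expert session (supplies d' > 3 expert trials for
#        the rank-stage contrasts)
#   s3 - proficient-but-imperfect late session (d' ~ 3; enough Miss/FA
#        trials to pass encoding inclusion while still labelled expert by
#        session majority)

library(mesorank)

sim <- sim_config(n_units_per_region = 2, n_trials = 240, n_sessions = 3,
                  hit_rates = c(0.9, 0.995, 0.93),
                  fa_rates = c(0.7, 0.01, 0.07))
coh <- generate_learning_dataset(sim, seed = 20260922)

dir.create("results", showWarnings = FALSE)
write_cohort(coh, "results/cohort")

message("cohort written to results/cohort/")
message(sprintf("  units: %d   spikes: %d   trials: %d (%d sessions)",
                nrow(coh$spikes$units), nrow(coh$spikes$spikes),
                nrow(coh$trials), sim$n_sessions))
for (s in names(coh$truth)) {
  tr <- coh$truth[[s]]
  message(sprintf("  %s: stage %-6s  %2d planted edges  latency span %.0f-%.0f ms",
                  s, tr$stage, nrow(tr$planted_edges),
                  min(tr$region_latency), max(tr$region_latency)))
}
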