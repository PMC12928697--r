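#!/usr/bin/env Rscript
# Behavioral staging: assign outcomes from lick records, discard trials
# after the session's last lick, compute the 21-trial sliding d' and label
# each trial early (d' < 2), expert (d' > 3) or excluded.

library(mesorank)

trials <- read_trial_table("results/cohort/trials.csv")
labeled <- label_behavior(trials)

dir.create("results/behavior", recursive = TRUE, showWarnings = FALSE)
write_trial_table(labeled, "results/behavior/trials_labeled.csv")

tab <- table(labeled$session_id, labeled$stage)
message("stage counts per session:")
print(tab)
for (s in unique(labeled$session_id)) {
  dp <- labeled$dprime[labeled$session_id == s]
  message(sprintf("  %s: median d' = %.2f  (CR rate %.2f)", s,
                  median(dp, na.rm = TRUE),
                  mean(labeled$outcome[labeled$session_id == s &
                                         labeled$stimulus == "NoGo"] == "CR")))
}
message("labeled trials written to results/behavior/trials_labeled.csv")
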