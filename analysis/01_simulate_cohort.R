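#!/usr/bin/env Rscript
# Simulate the synthetic cohorts all later stages analyse:
#  - a full-effect cohort (3 subjects x 2 sessions per group, 14
#    delayed-alternation trials per session) carrying every planted
#    effect, written as session directories;
#  - a well-separated 4-class cohort with short sessions for the
#    decoding stage.
# Sessions land under scratch/cohort/ and scratch/decoding_cohort/
# (runtime artifacts, not part of the repository).

suppressPackageStartupMessages(library(thetadyn))

seed <- 1L
out_main <- "scratch/cohort"
out_dec <- "scratch/decoding_cohort"

message("simulating full-effect cohort...")
cfg <- cohort_config(n_subjects = c(control = 3, STZ = 3),
                     n_sessions_per_subject = 2, n_trials = 14, seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, out_main)
message(length(cohort), " sessions -> ", out_main)

message("simulating separable decoding cohort...")
dec <- generate_cohort(cohort_config(
  n_subjects = c(control = 3, STZ = 3), n_sessions_per_subject = 2,
  n_trials = 2, phenotypes = separable_phenotypes(), seed = seed + 1000L))
write_cohort(dec, out_dec)
message(length(dec), " sessions -> ", out_dec)

for (nm in names(cohort)[1:2]) print(cohort[[nm]])
tt <- build_trial_table(cohort[[1]]$events)
message("first session: ", nrow(tt), " trials, ",
        sum(tt$delay_category == "short"), " short / ",
        sum(tt$delay_category == "long"), " long, ",
        sum(tt$outcome == "error"), " errors")
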