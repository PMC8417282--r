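#!/usr/bin/env Rscript
# Behavior stage: trial tables, accuracy by delay length and group,
# running speed linearized onto the 35-bin maze. Writes
# results/trials.csv, results/accuracy_by_delay.csv,
# results/bin_speed.csv.

suppressPackageStartupMessages(library(thetadyn))

cohort <- read_cohort("scratch/cohort")
dir.create("results", showWarnings = FALSE)

trials <- do.call(rbind, lapply(names(cohort), function(nm) {
  tt <- build_trial_table(cohort[[nm]]$events)
  tt$session_id <- nm
  tt$group <- cohort[[nm]]$leads$group[1]
  tt
}))
write.csv(trials, "results/trials.csv", row.names = FALSE)

acc <- accuracy_by_delay(trials)
write.csv(acc, "results/accuracy_by_delay.csv", row.names = FALSE)
print(acc)

bin_rows <- lapply(names(cohort), function(nm) {
  lin <- linearize_and_bin(cohort[[nm]]$positions)
  cbind(session_id = nm, group = cohort[[nm]]$leads$group[1], lin$bin_speed)
})
bin_speed <- do.call(rbind, bin_rows)
write.csv(bin_speed, "results/bin_speed.csv", row.names = FALSE)
message("speed profile: delay-box bin mean ",
        round(mean(bin_speed$mean_speed_cm_s[bin_speed$bin == 1], na.rm = TRUE), 1),
        " cm/s vs circuit max ",
        round(max(tapply(bin_speed$mean_speed_cm_s, bin_speed$bin, mean,
                         na.rm = TRUE), na.rm = TRUE), 1), " cm/s")
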