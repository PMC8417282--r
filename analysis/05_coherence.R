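#!/usr/bin/env Rscript
# Coherence stage: per-trial delay-period ACC-hippocampus theta
# coherence (last 10 s of the delay + first 2 s of the run, averaged
# over ipsilateral pairs), error/correct difference scores per session
# (pooled and split by delay length with the >= 3-trials-per-cell
# filter), and one peri-event cohereogram per group. Writes
# results/trial_coherence.csv, results/difference_scores*.csv,
# results/cohereogram_<group>_<outcome>.csv.

suppressPackageStartupMessages(library(thetadyn))

cohort <- read_cohort("scratch/cohort")
dir.create("results", showWarnings = FALSE)

tc <- do.call(rbind, lapply(names(cohort), function(nm) {
  t1 <- session_trial_coherence(cohort[[nm]])
  t1$session_id <- nm
  t1$group <- cohort[[nm]]$leads$group[1]
  t1
}))
write.csv(tc, "results/trial_coherence.csv", row.names = FALSE)

ds <- difference_scores(tc)
grp <- sapply(ds$scores$session_id, function(x) tc$group[tc$session_id == x][1])
ds$scores$group <- grp
write.csv(ds$scores, "results/difference_scores.csv", row.names = FALSE)
message(sprintf("difference scores: control median %.2f, STZ median %.2f (excluded: %s)",
                median(ds$scores$score[grp == "control"]),
                median(ds$scores$score[grp == "STZ"]),
                if (length(ds$excluded)) paste(ds$excluded, collapse = ", ") else "none"))

dss <- difference_scores(tc, split_by_delay = TRUE)
if (nrow(dss$scores)) {
  dss$scores$group <- sapply(dss$scores$session_id,
                             function(x) tc$group[tc$session_id == x][1])
}
write.csv(dss$scores, "results/difference_scores_by_delay.csv", row.names = FALSE)
message(length(dss$excluded), " of ", length(cohort),
        " sessions excluded by the 3-trials-per-cell filter")

for (g in c("control", "STZ")) {
  nm <- names(cohort)[sapply(cohort, function(s) s$leads$group[1]) == g][1]
  ses <- cohort[[nm]]
  pairs <- ipsilateral_pairs(ses$leads)
  pec <- peri_event_cohereogram(ses, pairs$acc[1], pairs$hpc[1])
  for (oc in names(pec$c)) {
    if (is.null(pec$c[[oc]])) next
    tab <- expand.grid(freq_hz = pec$freqs, t_s = pec$t)
    tab$coherence <- as.vector(pec$c[[oc]])
    write.csv(tab, sprintf("results/cohereogram_%s_%s.csv", g, oc),
              row.names = FALSE)
  }
}
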