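#!/usr/bin/env Rscript
# Statistics stage: speed-power correlation distributions per group,
# Kruskal-Wallis group comparisons, and the running one-way F of
# peri-event hippocampal TD ratios at 500 ms steps with Bonferroni
# correction. Writes results/speed_correlations.csv,
# results/kruskal.csv, results/running_F.csv.

suppressPackageStartupMessages(library(thetadyn))

cohort <- read_cohort("scratch/cohort")
dir.create("results", showWarnings = FALSE)

corr_rows <- list()
for (nm in names(cohort)) {
  ses <- cohort[[nm]]
  sp <- running_speed(ses$positions)
  for (i in seq_len(nrow(ses$leads))) {
    fr <- compute_spectrogram(notch_60hz(ses$signals[i, ], ses$sample_rate),
                              ses$sample_rate)
    th <- band_power(fr, band_def("theta"))
    de <- band_power(fr, band_def("delta"))
    corr_rows[[ses$leads$lead_id[i]]] <- data.frame(
      session_id = nm, lead_id = ses$leads$lead_id[i],
      area = ses$leads$area[i], group = ses$leads$group[1],
      r_theta = speed_power_correlation(th, fr$frame_times, sp),
      r_delta = speed_power_correlation(de, fr$frame_times, sp),
      r_td = speed_power_correlation(td_ratio(th, de), fr$frame_times, sp))
  }
}
corrs <- do.call(rbind, c(corr_rows, list(make.row.names = FALSE)))
write.csv(corrs, "results/speed_correlations.csv", row.names = FALSE)
message(sprintf("theta-speed r > 0 in %.0f%% of leads; delta-speed r < 0 in %.0f%%",
                100 * mean(corrs$r_theta > 0), 100 * mean(corrs$r_delta < 0)))

kw_rows <- list()
for (v in c("r_theta", "r_delta", "r_td")) {
  kw <- kruskal_wallis(split(corrs[[v]], corrs$group))
  kw_rows[[v]] <- data.frame(measure = v, H = kw$H, df = kw$df, p = kw$p)
}
write.csv(do.call(rbind, c(kw_rows, list(make.row.names = FALSE))),
          "results/kruskal.csv", row.names = FALSE)

peri <- list()
for (nm in names(cohort)) {
  pe <- peri_event_td(cohort[[nm]], area = "HPC")
  g <- cohort[[nm]]$leads$group[1]
  peri[[g]] <- rbind(peri[[g]], pe$td)
  t_steps <- pe$t
}
rf <- running_group_F(peri, t_steps)
write.csv(rf, "results/running_F.csv", row.names = FALSE)
message(sum(rf$significant, na.rm = TRUE), " of ", nrow(rf),
        " peri-event steps significant after Bonferroni correction")
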