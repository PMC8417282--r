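#!/usr/bin/env Rscript
# Spectral stage: per-lead normalized session PSDs (1-100 Hz), band
# powers and theta/delta ratios; group comparison of hippocampal TD
# ratios. Writes results/spectral_leads.csv, results/session_td.csv and
# results/psd_by_group.csv.

suppressPackageStartupMessages(library(thetadyn))

cohort <- read_cohort("scratch/cohort")
dir.create("results", showWarnings = FALSE)

rows <- list(); psds <- list()
for (nm in names(cohort)) {
  prof <- session_spectral_profile(cohort[[nm]])
  s <- prof$summary
  s$session_id <- nm
  rows[[nm]] <- s
  psds[[nm]] <- prof$spectra
}
leads <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
write.csv(leads, "results/spectral_leads.csv", row.names = FALSE)

session_td <- aggregate(td_ratio ~ session_id + area + group, leads, mean)
write.csv(session_td, "results/session_td.csv", row.names = FALSE)

# mean normalized PSD per (group, area) for the summary figure tables
grid <- expand.grid(group = c("control", "STZ"), area = c("ACC", "HPC"),
                    stringsAsFactors = FALSE)
psd_tab <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  vals <- list()
  for (nm in names(cohort)) {
    li <- cohort[[nm]]$leads
    sel <- which(li$group == grid$group[i] & li$area == grid$area[i])
    for (k in sel) vals[[length(vals) + 1]] <- psds[[nm]][[k]]$norm_power
  }
  data.frame(group = grid$group[i], area = grid$area[i],
             freq_hz = psds[[1]][[1]]$freqs,
             norm_power = Reduce(`+`, vals) / length(vals))
}))
write.csv(psd_tab, "results/psd_by_group.csv", row.names = FALSE)

hpc <- session_td[session_td$area == "HPC", ]
kw <- kruskal_wallis(split(hpc$td_ratio, hpc$group))
message(sprintf("hippocampal TD ratio: control %.2f vs STZ %.2f (KW H = %.2f, p = %.2g)",
                mean(hpc$td_ratio[hpc$group == "control"]),
                mean(hpc$td_ratio[hpc$group == "STZ"]), kw$H, kw$p))
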