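#!/usr/bin/env Rscript
# Cross-frequency coupling stage: session modulation index per area for
# the delta->theta, theta->slow gamma and theta->fast gamma pairs, plus
# a comodulogram of one hippocampal lead per group. Writes
# results/pac_mi.csv, results/pac_kruskal.csv,
# results/comodulogram_<group>.csv.

suppressPackageStartupMessages(library(thetadyn))

cohort <- read_cohort("scratch/cohort")
dir.create("results", showWarnings = FALSE)

pac <- do.call(rbind, lapply(names(cohort), function(nm) {
  p <- session_pac_summary(cohort[[nm]])
  p$session_id <- nm
  p$group <- cohort[[nm]]$leads$group[1]
  p
}))
write.csv(pac, "results/pac_mi.csv", row.names = FALSE)

kw_rows <- list()
for (a in unique(pac$area)) for (pr in unique(pac$pair)) {
  sub <- pac[pac$area == a & pac$pair == pr, ]
  kw <- kruskal_wallis(split(sub$mi, sub$group))
  kw_rows[[paste(a, pr)]] <- data.frame(area = a, pair = pr, H = kw$H, p = kw$p)
  message(sprintf("%s %-18s control %.2e vs STZ %.2e  (H = %.2f, p = %.3g)",
                  a, pr, mean(sub$mi[sub$group == "control"]),
                  mean(sub$mi[sub$group == "STZ"]), kw$H, kw$p))
}
write.csv(do.call(rbind, c(kw_rows, list(make.row.names = FALSE))),
          "results/pac_kruskal.csv", row.names = FALSE)

for (g in c("control", "STZ")) {
  nm <- names(cohort)[sapply(cohort, function(s) s$leads$group[1]) == g][1]
  ses <- cohort[[nm]]
  lead <- which(ses$leads$area == "HPC")[1]
  x <- head(notch_60hz(ses$signals[lead, ], ses$sample_rate), 220000)
  cm <- comodulogram(x, ses$sample_rate)
  tab <- expand.grid(amp_freq_hz = cm$amp_freqs, phase_freq_hz = cm$phase_freqs)
  tab$mi <- as.vector(cm$mi)
  write.csv(tab, sprintf("results/comodulogram_%s.csv", g), row.names = FALSE)
}
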