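#!/usr/bin/env Rscript
# Spectral-phenotype decoding stage on the separable cohort: 1-50 Hz
# normalized PSD features, training-size sweep, shuffled null, and
# leave-one-subject/session-out designs. Writes
# results/decoding_sweep.csv, results/decoding_null.csv,
# results/decoding_confusion_40.csv, results/decoding_leave_one_out.csv
# and a protocol manifest.

suppressPackageStartupMessages(library(thetadyn))

seed <- 1L
cohort <- read_cohort("scratch/decoding_cohort")
dir.create("results", showWarnings = FALSE)

ds <- cohort_phenotype_dataset(cohort)
message(nrow(ds$features), " leads x ", ncol(ds$features), " features; classes: ",
        paste(levels(ds$labels), table(ds$labels), collapse = ", "))

sizes <- c(5, 15, 25, 40)
sw <- training_size_sweep(ds, sizes = sizes, n_iter = 100, seed = seed)
sweep_tab <- data.frame(
  size = sizes,
  mean_accuracy = sapply(sw, function(s) mean(s$accuracy)),
  sd_accuracy = sapply(sw, function(s) sd(s$accuracy)),
  wrong_group = sapply(sw, function(s) s$misclass[["wrong_group"]]),
  wrong_area = sapply(sw, function(s) s$misclass[["wrong_area"]]),
  wrong_both = sapply(sw, function(s) s$misclass[["wrong_both"]]))
write.csv(sweep_tab, "results/decoding_sweep.csv", row.names = FALSE)
print(sweep_tab[, 1:3])

conf <- as.data.frame(sw[["40"]]$confusion)
conf <- cbind(true_class = rownames(conf), conf)
write.csv(conf, "results/decoding_confusion_40.csv", row.names = FALSE)

nl <- shuffled_null(ds, size = 40, n_iter = 250, seed = seed)
write.csv(data.frame(mean_accuracy = nl$mean, ci_lo = nl$ci95[1],
                     ci_hi = nl$ci95[2], t(nl$misclass)),
          "results/decoding_null.csv", row.names = FALSE)
message(sprintf("shuffled null: %.1f%% (95%% interval %.1f-%.1f%%)",
                100 * nl$mean, 100 * nl$ci95[1], 100 * nl$ci95[2]))

lo_subj <- leave_one_group_out(ds, "subject_id", per_class = 30, n_iter = 25,
                               seed = seed)
lo_subj$design <- "leave_one_subject"
lo_sess <- leave_one_group_out(ds, "session_id", per_class = 30, n_iter = 25,
                               seed = seed)
lo_sess$design <- "leave_one_session"
write.csv(rbind(lo_subj, lo_sess), "results/decoding_leave_one_out.csv",
          row.names = FALSE)
message(sprintf("leave-one-subject-out: control %.1f%%, STZ %.1f%%",
                100 * mean(lo_subj$accuracy[lo_subj$group == "control"]),
                100 * mean(lo_subj$accuracy[lo_subj$group == "STZ"])))

writeLines(jsonlite::toJSON(list(sizes = sizes, n_iter_sweep = 100,
                                 n_iter_null = 250, per_class_logo = 30,
                                 n_iter_logo = 25, seed = seed),
                            auto_unbox = TRUE),
           "results/decoding_manifest.json")
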