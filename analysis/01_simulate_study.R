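#!/usr/bin/env Rscript

# Step 1: generate the synthetic multi-scorer rescoring study.
#
# 12 expert scorers re-score 5 recordings per task, for each of the four
# PSG scoring tasks (sleep staging, leg movements, respiratory events, EEG
# arousals), once manually and once by editing a shared automatic draft
# (semi-automatic condition). Active scoring times are drawn per exercise.
# The study is written to results/synthetic_study/ as one annotation file
# per cell plus a manifest and a timing log, so the downstream analysis
# consumes it exactly as it would consume a real exported study.

suppressPackageStartupMessages(library(psgagree))

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
out_dir <- "results/synthetic_study"

cfg <- study_config()  # full-scale defaults: 12 x 2 x 4 x 5
cat(sprintf("simulating %d scorers x 2 methods x %d tasks x %d recordings (seed %d)\n",
            cfg$n_scorers, length(cfg$tasks), cfg$n_recordings, seed))

sim <- suppressWarnings(generate_study(cfg, seed = seed))
print(sim$study)

write_study(sim, out_dir)
n_files <- length(list.files(out_dir, recursive = TRUE))
cat(sprintf("wrote %d files under %s\n", n_files, out_dir))

# quick look at the ground truth of one recording per task
for (key in names(sim$truths)[!duplicated(vapply(sim$truths, `[[`,
                                                 character(1), "task"))]) {
  truth <- sim$truths[[key]]
  cat("\ntruth ", key, ": ", sep = "")
  print(truth)
  if (!is.null(truth$context_hypnogram)) {
    print(summarize_hypnogram(truth$context_hypnogram,
                              tib = tib_seconds(truth)))
  }
}
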