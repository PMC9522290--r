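#!/usr/bin/env Rscript

# Step 3: the recording-selection stage of the study design.
#
# Study recordings are not drawn at random from the clinical database:
# for each task, every candidate recording gets a difficulty surrogate
# K_ac — Cohen's kappa between the automatic scoring and the existing
# clinical scoring — and the recordings sitting at the 12.5th, 37.5th,
# 50th, 62.5th and 87.5th percentiles of the K_ac distribution are chosen.
# This yields a difficulty-balanced sample while avoiding outliers.
#
# Here the candidate pool is simulated: each candidate gets its own
# patient-severity draw, a clinical scoring (the truth) and an automatic
# scoring (a corruption of it), and the selection runs on the resulting
# K_ac values.

suppressPackageStartupMessages(library(psgagree))

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
n_candidates <- 40
task <- "leg_movements"

cat(sprintf("scoring %d candidate recordings for task %s (seed %d)\n",
            n_candidates, task, seed))

auto_model <- scorer_model(event_sensitivity = 0.9,
                           false_positive_rate = 1.5,
                           boundary_jitter_sd = 0.4)
kac <- vapply(seq_len(n_candidates), function(i) {
  rid <- sprintf("cand-%02d", i)
  rec_model <- sample_recording_model(truth_model(), seed, rid)
  clinical <- generate_truth(rec_model, rid, task, seed = seed)
  clinical$scorer_id <- "clinical"
  auto <- corrupt_scoring(clinical, auto_model, scorer_id = "auto",
                          seed = seed)
  compute_kac(auto, clinical)$kappa
}, numeric(1))
names(kac) <- sprintf("cand-%02d", seq_len(n_candidates))

sel <- select_recordings(kac)
print(sel)

dir.create("results", showWarnings = FALSE)
write_selection(sel, "results/recording_selection.csv")
cat("\nK_ac distribution: median", round(median(kac), 3),
    "IQR", paste(round(quantile(kac, c(.25, .75)), 3), collapse = "-"), "\n")
cat("selected difficulty-balanced subset:",
    paste(sel$selected, collapse = ", "), "\n")
cat("written: results/recording_selection.csv\n")
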