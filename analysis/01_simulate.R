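#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# Simulates 21 patients and 25 controls completing both sessions of the
# probabilistic feedback-learning task (immediate and delayed feedback,
# counterbalanced), attaches trial-level prediction errors from the true
# generative parameters, and plants the single-trial ERP effect structure
# (valence effect on the FRN, a more negative FRN in patients, a feedback-
# timing effect in controls only, and unsigned-PE coding confined to
# positive feedback in controls). Everything downstream reads the tables
# written here.

library(rlerp)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
seed <- 1L

study <- simulate_study(n_patients = 21, n_controls = 25, seed = seed,
                        dir = "results")
saveRDS(study, "scratch/study.rds")  # binary intermediate for steps 2-5

ev <- study$events
cat("participants:", length(unique(ev$participant_id)),
    "| trials:", nrow(ev),
    "| valid:", sprintf("%.1f%%", 100 * mean(ev$valid)), "\n")
cat("sessions with a stimulus-set switch:",
    sum(tapply(ev$stimulus_set, interaction(ev$participant_id, ev$session),
               max) == 2), "of", 2 * length(unique(ev$participant_id)), "\n")
cat("sessions with a ninth block:",
    sum(tapply(ev$block, interaction(ev$participant_id, ev$session),
               max) == 9), "\n")
cat("positive feedback | learnable-correct trials:",
    sprintf("%.1f%%", 100 * mean(
      ev$feedback_valence[ev$learnability == "learnable" & ev$valid &
                            ev$correct %in% TRUE] == "positive")), "\n")
cat("positive feedback | distractor trials:",
    sprintf("%.1f%%", 100 * mean(
      ev$feedback_valence[ev$learnability == "unlearnable" &
                            !is.na(ev$feedback_valence)] == "positive")),
    "\n")
cat("wrote results/events.tsv and results/single_trial_erp.tsv\n")
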