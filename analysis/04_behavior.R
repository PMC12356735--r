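#!/usr/bin/env Rscript
# Step 4 — behavioral metrics and their mixed models.
#
# Computes block accuracy (valid learnable trials only) and single-trial
# choice switching, then fits the two behavioral mixed models: accuracy on
# group x feedback timing x block, and switching on group x timing x
# valence x response type x block, each with the maximal by-participant
# random structure and stepwise reduction on convergence failures.

library(rlerp)

study <- readRDS("scratch/study.rds")
ev <- study$events
tpl <- mlm_templates()

acc <- block_accuracy(ev)
acc <- merge(acc, unique(ev[, c("participant_id", "group", "session")]))
acc <- code_predictors(acc)
write.table(acc, "results/block_accuracy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sw <- choice_switching(ev)
sw <- merge(sw, unique(ev[, c("participant_id", "group")]))
sw <- code_predictors(sw[!is.na(sw$switch) & !is.na(sw$response_type), ])
write.table(sw, "results/choice_switching.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("mean accuracy, first vs last block:",
    sprintf("%.1f%% vs %.1f%%\n",
            mean(acc$accuracy[acc$block == 1], na.rm = TRUE),
            mean(acc$accuracy[acc$block == max(acc$block)], na.rm = TRUE)))
cat("switching after positive vs negative feedback (learnable):",
    sprintf("%.3f vs %.3f\n",
            mean(sw$switch[sw$feedback_valence > 0 & sw$learnability > 0]),
            mean(sw$switch[sw$feedback_valence < 0 & sw$learnability > 0])))

res_acc <- fit_mlm(acc, tpl$accuracy)
write_mlm_result(res_acc, "results/mlm_accuracy.tsv")
cat("\naccuracy model — realized random structure: (", res_acc$random,
    "| participant )\n")
print(round(res_acc$coefficients[c("group", "feedback_timing", "block_z"), ],
            3))

res_sw <- fit_mlm(sw, tpl$switching)
write_mlm_result(res_sw, "results/mlm_switching.tsv")
cat("\nswitching model — realized random structure: (", res_sw$random,
    "| participant )\n")
print(round(res_sw$coefficients[c("feedback_valence", "response_type"), ],
            3))
cat("\nwrote results/block_accuracy.tsv, results/choice_switching.tsv,",
    "results/mlm_accuracy.tsv, results/mlm_switching.tsv\n")
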