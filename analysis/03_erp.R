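#!/usr/bin/env Rscript
# Generate EEG epochs participant by participant, apply artifact
# rejection (|v| > 200 uV or ocular flags), and extract the three ERP
# window means (P3a 200-280 ms, CNV 1200-1500 ms at Cz after the
# preparation cue; 900-1100 ms after the incentive cue). Writes
# results/trials_with_erp.csv and results/erp_rejections.csv.

suppressPackageStartupMessages(library(vigoureeg))

cfg <- generator_config(seed = 1)
trials <- read_trial_table("results/trials.csv")

res <- vigoureeg:::extract_erp_measures(trials, cfg)
m <- match(trials$trial_id, res$measures$trial_id)
trials$p3a <- res$measures$p3a[m]
trials$cnv <- res$measures$cnv[m]
trials$pre_preparation <- res$measures$pre_preparation[m]

write_trial_table(trials, "results/trials_with_erp.csv")
write.csv(res$rejections, "results/erp_rejections.csv", row.names = FALSE)

kept <- sum(!res$rejections$rejected)
cat(sprintf("retained %d/%d trials (%.1f/120 per condition per person)\n",
            kept, nrow(trials), kept / (cfg$n_participants * 2 * 4)))
print(table(res$rejections$reason, useNA = "ifany"))
cat(sprintf("grand-mean CNV: %.2f uV; P3a: %.2f uV; pre-preparation: %.2f uV\n",
            mean(trials$cnv, na.rm = TRUE), mean(trials$p3a, na.rm = TRUE),
            mean(trials$pre_preparation, na.rm = TRUE)))
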