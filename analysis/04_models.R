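#!/usr/bin/env Rscript
# Single-trial mixed-effects models with z-scored factors:
# behaviour ~ 1 + incentive*distractor*thp + (1 | participant) for the
# three behavioural outcomes, the same factorial model for the three ERP
# window means, and the 3 x 3 ERP ~ behaviour matrix with a Bonferroni
# threshold of 0.05/9. Writes results/behaviour_lmm.csv,
# results/erp_lmm.csv and results/erp_behaviour_lmm.csv.

suppressPackageStartupMessages(library(vigoureeg))

trials <- read_trial_table("results/trials_with_erp.csv")
beh <- trials[trials$included %in% TRUE, ]
eeg <- trials[!is.na(trials$cnv), ]
both <- trials[trials$included %in% TRUE & !is.na(trials$cnv), ]

fits_beh <- list(
  residual_velocity = fit_single_trial_model(beh, "residual_velocity"),
  log_rt = fit_single_trial_model(beh, "rt_ms", transform = "log"),
  pull_deg = fit_single_trial_model(beh, "pull_deg"))
fits_erp <- list(
  cnv = fit_single_trial_model(eeg, "cnv"),
  p3a = fit_single_trial_model(eeg, "p3a"),
  pre_preparation = fit_single_trial_model(
    eeg[!is.na(eeg$pre_preparation), ], "pre_preparation"))

stack <- function(fits) do.call(rbind, lapply(names(fits), function(nm)
  cbind(outcome = nm, as.data.frame(fits[[nm]]))))
write.csv(stack(fits_beh), "results/behaviour_lmm.csv", row.names = FALSE)
write.csv(stack(fits_erp), "results/erp_lmm.csv", row.names = FALSE)

for (nm in names(fits_beh)) { cat("\n== ", nm, " ==\n"); print(fits_beh[[nm]]) }
for (nm in names(fits_erp)) { cat("\n== ", nm, " ==\n"); print(fits_erp[[nm]]) }

eb <- fit_erp_behaviour_models(both)
write.csv(as.data.frame(eb), "results/erp_behaviour_lmm.csv",
          row.names = FALSE)
cat(sprintf("\nERP ~ behaviour: %d of %d associations significant at alpha = %.4f\n",
            sum(eb$significant), nrow(eb), unique(eb$alpha_corrected)))
print(eb[, c("erp", "behaviour", "beta", "p", "significant")])
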