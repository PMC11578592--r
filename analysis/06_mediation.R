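#!/usr/bin/env Rscript
# Does the CNV explain the incentive effects? Four-step mediation of the
# incentive effect on log RT and on residual velocity by the CNV window
# mean, and mediated moderation of the drug x incentive interaction,
# each with a 2500-permutation within-participant null. Writes
# results/mediation.json.

suppressPackageStartupMessages(library(vigoureeg))

trials <- read_trial_table("results/trials_with_erp.csv")
med <- trials[trials$included %in% TRUE & !is.na(trials$cnv), ]
med$log_rt <- log(med$rt_ms)

rt <- mediation_test(med, outcome = "log_rt", n_perm = 2500, seed = 102)
vel <- mediation_test(med, outcome = "residual_velocity", n_perm = 2500,
                      seed = 103)
mod <- mediated_moderation_test(med, outcome = "log_rt", n_perm = 2500,
                                seed = 104)
print(rt); print(vel); print(mod)

strip <- function(x) { x$null <- NULL; unclass(x) }
jsonlite::write_json(list(rt = strip(rt), velocity = strip(vel),
                          rt_moderation = strip(mod)),
                     "results/mediation.json", auto_unbox = TRUE,
                     digits = NA, force = TRUE)
cat("wrote results/mediation.json\n")
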