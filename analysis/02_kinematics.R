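#!/usr/bin/env Rscript
# Validate the saccade parser against the generator on raw eye traces
# (one participant-session written to the ASC-like dialect and read
# back), and summarise distractor pull as per-condition kernel
# densities. Writes results/parser_validation.csv and
# results/pull_density.csv.

suppressPackageStartupMessages(library(vigoureeg))

cfg <- generator_config(seed = 1)
trials <- read_trial_table("results/trials.csv")

sub <- trials[trials$participant == "P01" & trials$session == 1 &
                !trials$missed, ][1:48, ]
traces <- generate_eye_traces(sub, cfg)
path <- file.path(tempdir(), "p01_s1.asc")
write_eye_traces(traces, sub, path)
traces <- read_eye_traces(path)

parsed <- do.call(rbind, lapply(sub$trial_id, function(id)
  cbind(trial_id = id,
        trial_kinematics(traces[[id]],
                         fixation_radius_deg = cfg$fixation_radius_deg))))
cmp <- merge(parsed, sub[, c("trial_id", "rt_ms", "amplitude",
                             "peak_velocity", "pull_deg")], by = "trial_id",
             suffixes = c("_parsed", "_planted"))
cmp$rt_err <- cmp$rt_ms_parsed - cmp$rt_ms_planted
cmp$vel_rel_err <- (cmp$peak_velocity_deg_s - cmp$peak_velocity) /
  cmp$peak_velocity
write.csv(cmp, "results/parser_validation.csv", row.names = FALSE)
cat(sprintf("parser vs generator over %d trials: RT err %.2f +/- %.2f ms, peak velocity rel. err %.2f%%\n",
            nrow(cmp), mean(cmp$rt_err), sd(cmp$rt_err),
            100 * mean(abs(cmp$vel_rel_err))))

beh <- trials[trials$included %in% TRUE, ]
dens <- kinematics_summary_density(
  beh$pull_deg, beh$participant,
  ifelse(beh$distractor == 1, "distractor", "no_distractor"))
out <- data.frame(angle = dens$grid, t(dens$mean))
write.csv(out, "results/pull_density.csv", row.names = FALSE)
cat("pull densities written to results/pull_density.csv\n")

# drug effect on the pull distribution (distractor-present trials),
# cluster-tested over angle bins with participant sign-flips
diffc <- pull_density_difference(beh, "drug", subset = beh$distractor == 1)
dc <- density_cluster_test(diffc$curves, n_perm = 2500, seed = 2)
print(dc)
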