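#!/usr/bin/env Rscript
# Window-free analysis: cluster-mass permutation regression of each
# behavioural variable on voltage at every electrode x time node,
# shuffling voltages within participant x condition cells. Run at a
# reduced grid (16 channels, 32 Hz effective time resolution, 10
# participants) so the demonstration completes in minutes; the test
# suite calibrates the same machinery. Writes results/cluster_<beh>.tsv
# and results/cluster_summary.csv.

suppressPackageStartupMessages(library(vigoureeg))

cfg <- generator_config(seed = 1)
trials <- read_trial_table("results/trials_with_erp.csv")
trials$log_rt <- ifelse(is.finite(trials$rt_ms), log(trials$rt_ms), NA)
use <- trials$participant %in% sprintf("P%02d", 1:10) &
  trials$included %in% TRUE & !is.na(trials$cnv)
sub <- trials[use, ]

# regenerate epochs for the participants in play, decimate time to 32 Hz
eps <- lapply(split(sub, sub$participant), function(s) {
  ep <- generate_eeg_epochs(s, cfg)
  ep <- epoch_and_baseline(ep, c(ep$times[1], 1500))
  keep <- seq(1, length(ep$times), by = 8)
  epoch_set(ep$voltages[, , keep, drop = FALSE], ep$channels, ep$positions,
            ep$sample_rate / 8, ep$times[keep], ep$t0_event, ep$trial_ids)
})
# stack the per-participant epoch sets along the trial axis
ntr <- sum(vapply(eps, function(e) dim(e$voltages)[1], 0L))
first <- eps[[1]]
volt <- array(0, c(ntr, dim(first$voltages)[2], dim(first$voltages)[3]))
ids <- character(0)
off <- 0L
for (e in eps) {
  k <- dim(e$voltages)[1]
  volt[off + seq_len(k), , ] <- e$voltages
  ids <- c(ids, e$trial_ids)
  off <- off + k
}
ep <- epoch_set(volt, first$channels, first$positions, first$sample_rate,
                first$times, first$t0_event, ids)

summ <- list()
for (behv in c("residual_velocity", "log_rt", "pull_deg")) {
  r <- cluster_permutation_test(ep, sub, behv, n_perm = 200, seed = 10)
  cat("\n== ", behv, " ==\n"); print(r)
  map <- data.frame(
    electrode = rep(ep$channels, length(ep$times)),
    time_ms = rep(ep$times, each = length(ep$channels)),
    t = as.numeric(r$t), cluster_id = as.integer(r$id))
  write.table(map, sprintf("results/cluster_%s.tsv", behv), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (nrow(r$clusters)) {
    summ[[behv]] <- cbind(behaviour = behv, r$clusters)
  }
}
if (length(summ)) {
  write.csv(do.call(rbind, summ), "results/cluster_summary.csv",
            row.names = FALSE)
}
cat("\nstat maps written to results/cluster_*.tsv\n")
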