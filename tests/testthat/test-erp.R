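test_that("preprocess re-references, notches and band-passes", {
  fs <- 1024
  t <- seq(0, 1 - 1 / fs, by = 1 / fs) * 1000
  chans <- c("C1", "C2", "A1", "A2")
  line <- 20 * sin(2 * pi * 50 * t / 1000)
  inband <- 20 * sin(2 * pi * 10 * t / 1000)
  v <- array(0, dim = c(2, 4, length(t)))
  v[1, 1, ] <- line          # pure 50 Hz on one channel
  v[1, 2, ] <- inband
  v[2, , ] <- 7              # constant offset on all channels incl. mastoids
  ep <- epoch_set(v, chans, cbind(1:4, 0), fs, t, trial_ids = c("a", "b"))
  out <- preprocess(ep, band = c(0.1, 80), line_freq = 50, target_rate = 256)
  expect_equal(out$channels, c("C1", "C2"))
  expect_equal(out$sample_rate, 256)
  rms <- function(x) sqrt(mean(x^2))
  mid <- 40:200   # avoid filter edge transients
  # 50 Hz attenuated by at least 20 dB
  expect_lt(rms(out$voltages[1, 1, mid]) / rms(line), 0.1)
  # 10 Hz passed essentially unchanged
  expect_gt(rms(out$voltages[1, 2, mid]) / rms(inband), 0.9)
  # common offset removed by re-referencing (and high-pass)
  expect_lt(max(abs(out$voltages[2, , mid])), 0.2)
  expect_error(preprocess(ep, mastoids = c("M1", "M2")), "mastoid")
  expect_error(preprocess(ep, band = c(0.1, 600)), "band upper edge")
})

test_that("band edges behave as designed on white noise", {
  set.seed(31)
  fs <- 1024
  t <- seq(0, 2 - 1 / fs, by = 1 / fs) * 1000
  v <- array(rnorm(4 * length(t)), dim = c(1, 4, length(t)))
  ep <- epoch_set(v, c("C1", "C2", "A1", "A2"), cbind(1:4, 0), fs, t)
  out <- preprocess(ep, target_rate = 512)   # keep spectrum up to 256 Hz
  x <- out$voltages[1, 1, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 512), plot = FALSE,
                          spans = 15)
  pow <- function(f1, f2) mean(sp$spec[sp$freq >= f1 & sp$freq <= f2])
  # stop band well below pass band
  expect_lt(pow(110, 200) / pow(5, 40), 0.05)
  expect_lt(pow(49, 51) / pow(5, 40), 0.5)
})

test_that("baselining subtracts the pre-event mean and is idempotent", {
  ep <- make_epochs(n_trials = 2, fill = 5)
  b <- epoch_and_baseline(ep)
  expect_true(all(abs(b$voltages) < 1e-12))
  # ramp crossing zero at the cue: closed form after baselining
  ep2 <- make_epochs(n_trials = 1)
  ramp <- ep2$times / 1000 * -6.67      # uV, negative slope from -200 ms on
  ep2$voltages[1, , ] <- rep(ramp, each = 2)
  b2 <- epoch_and_baseline(ep2, baseline = c(-100, 0))
  bl_times <- ep2$times[ep2$times >= -100 & ep2$times < 0]
  expected_last <- ramp[length(ramp)] - mean(bl_times / 1000 * -6.67)
  expect_equal(b2$voltages[1, 1, dim(b2$voltages)[3]], expected_last,
               tolerance = 1e-9)
  # idempotence
  b3 <- epoch_and_baseline(b2, baseline = c(-100, 0))
  expect_equal(b2$voltages, b3$voltages, tolerance = 1e-12)
  # incentive-cue epochs use their own window
  epi <- make_epochs(n_trials = 1, window = c(-200, 1100))
  bi <- epoch_and_baseline(epi, window = c(-200, 1100))
  expect_equal(range(bi$times), range(epi$times))
  expect_error(epoch_and_baseline(epi, window = c(-200, 1500)),
               "extends past")
})

test_that("window means follow the half-open sample convention", {
  ep <- make_epochs(n_trials = 3, fill = 5)
  expect_equal(unname(window_mean(ep, c(1200, 1500), "Cz")), rep(5, 3))
  # the CNV window at 256 Hz anchored at -200 ms holds 77 samples
  idx <- which(ep$times >= 1200 & ep$times < 1500)
  expect_equal(length(idx), 77)
  # ramp 0 uV at 0 ms to -10 uV at 1500 ms: window mean -9.0 uV
  ep2 <- make_epochs(n_trials = 1)
  ramp <- pmax(ep2$times, 0) / 1500 * -10
  ep2$voltages[1, , ] <- rep(ramp, each = 2)
  cnv <- window_mean(ep2, c(1200, 1500), "Cz")
  half_sample <- 10 / 1500 * (1000 / 256) / 2
  expect_lt(abs(unname(cnv) - (-9.0)), half_sample)
  # equivalently: a -6.67 uV/s ramp from 0 ms
  ep3 <- make_epochs(n_trials = 1)
  ep3$voltages[1, , ] <- rep(pmax(ep3$times, 0) / 1000 * -6.67, each = 2)
  expect_lt(abs(unname(window_mean(ep3, c(1200, 1500), "Cz")) - (-9.0)),
            0.02)
  # linearity: mean(aX + bY) = a mean(X) + b mean(Y)
  epx <- make_epochs(n_trials = 1); epy <- make_epochs(n_trials = 1)
  set.seed(4)
  epx$voltages[] <- rnorm(length(epx$voltages))
  epy$voltages[] <- rnorm(length(epy$voltages))
  epz <- epx; epz$voltages <- 2 * epx$voltages + 3 * epy$voltages
  expect_equal(window_mean(epz, c(200, 280), "Cz"),
               2 * window_mean(epx, c(200, 280), "Cz") +
                 3 * window_mean(epy, c(200, 280), "Cz"), tolerance = 1e-12)
  expect_error(window_mean(ep, c(1600, 1700), "Cz"), "no samples")
  expect_error(window_mean(ep, c(200, 280), "Pz"), "not present")
})

test_that("artifact rejection applies the voltage and ocular rules", {
  ep <- make_epochs(n_trials = 4)
  ep$voltages[2, 2, 100] <- 250     # one sample out of bounds
  flags <- data.frame(trial_id = ep$trial_ids,
                      ocular = c(FALSE, FALSE, TRUE, FALSE))
  r <- reject_artifacts(ep, flags)
  expect_equal(r$rejections$rejected, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(r$rejections$reason[2], "voltage")
  expect_equal(r$rejections$reason[3], "ocular")
  expect_equal(r$epochs$trial_ids, c("t001", "t004"))
  # exactly the bound is retained, beyond it is not
  ep2 <- make_epochs(n_trials = 2)
  ep2$voltages[1, 1, 5] <- 200
  ep2$voltages[2, 1, 5] <- -201
  r2 <- reject_artifacts(ep2)
  expect_equal(r2$rejections$rejected, c(FALSE, TRUE))
  # monotone: a tighter bound never retains a rejected trial
  r_loose <- reject_artifacts(ep, flags, voltage_bounds = c(-300, 300))
  r_tight <- reject_artifacts(ep, flags, voltage_bounds = c(-100, 100))
  expect_true(all(r_loose$rejections$rejected <= r_tight$rejections$rejected |
                    r_loose$rejections$reason %in% "ocular"))
})

test_that("difference waves recover planted condition differences", {
  cfg <- small_generator_config(seed = 33)
  sub <- generate_trial_table(cfg)
  ep <- generate_eeg_epochs(sub, cfg)
  ep <- epoch_and_baseline(ep, c(ep$times[1], 1500))
  dw <- difference_waves(ep, sub, "incentive")
  expect_equal(dim(dw$diff), c(6, length(ep$channels), length(ep$times)))
  # planted incentive effect on the CNV is negative: the late Cz
  # difference wave should be negative on average across participants
  czi <- which(dw$channels == "Cz")
  late <- dw$times >= 1200 & dw$times < 1500
  cz_late <- mean(dw$diff[, czi, late])
  planted <- 2 * cfg$effect_sizes$cnv[["incentive"]] * cfg$scales[["cnv"]]
  expect_lt(abs(cz_late - planted), 2.5)   # ~3 SEM at this size
  # missing level drops the participant with a message
  sub2 <- sub[!(sub$participant == "P01" & sub$incentive == 50), ]
  ep2 <- subset_epochs(ep, sub2$trial_id)
  expect_message(dw2 <- difference_waves(ep2, sub2, "incentive"), "dropped")
  expect_equal(dim(dw2$diff)[1], 5)
})

test_that("interaction wave of an additive generator is near zero", {
  # additive signal: incentive and drug shift the ramp independently
  set.seed(34)
  n <- 80
  d <- data.frame(participant = rep(c("Pa", "Pb"), each = 40),
                  incentive = rep(c(0, 50), 40),
                  thp = rep(c(0, 0, 1, 1), 20))
  d$trial_id <- sprintf("t%03d", seq_len(n))
  ep <- make_epochs(n_trials = n)
  base <- pmax(ep$times, 0) / 1000
  for (i in seq_len(n)) {
    amp <- -4 - 2 * (d$incentive[i] == 50) - 1 * d$thp[i]   # no interaction
    ep$voltages[i, , ] <- rep(amp * base, each = 2) +
      rnorm(length(ep$times), 0, 0.01)
  }
  ep$trial_ids <- d$trial_id
  dw <- difference_waves(ep, d, "incentive", interaction_of = "thp")
  expect_lt(max(abs(apply(dw$diff, c(2, 3), mean))), 0.05)
})
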