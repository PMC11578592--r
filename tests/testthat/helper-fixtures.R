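# Shared fixtures, all built in code.

# small factorial trial table with planted standardized effects;
# outcome is a unit-variance latent mapped through `scale`
make_factorial_data <- function(n_participants = 8, n_per_cell = 10,
                                beta = c(incentive = 0, distractor = 0,
                                         thp = 0),
                                participant_sd = 0.3, seed = 1,
                                scale = 1, offset = 0) {
  set.seed(seed)
  d <- expand.grid(rep = seq_len(n_per_cell),
                   incentive = c(0, 50), distractor = c(0, 1),
                   thp = c(0, 1),
                   participant = sprintf("P%02d", seq_len(n_participants)))
  n <- nrow(d)
  zi <- ifelse(d$incentive == 50, 1, -1)
  zd <- ifelse(d$distractor == 1, 1, -1)
  zt <- ifelse(d$thp == 1, 1, -1)
  lin <- beta[["incentive"]] * zi + beta[["distractor"]] * zd +
    beta[["thp"]] * zt
  u <- rnorm(n_participants, 0, participant_sd)
  resid_sd <- sqrt(1 - sum(beta^2) - participant_sd^2)
  d$y <- offset + scale * (lin + u[as.integer(factor(d$participant))] +
                             rnorm(n, 0, resid_sd))
  d$trial_id <- sprintf("t%05d", seq_len(n))
  d$drug <- ifelse(d$thp == 1, "THP", "placebo")
  d
}

# a minimum-jerk trace for one saccade (1 kHz, no noise unless asked)
make_minjerk_trace <- function(rt_ms = 200, amplitude = 10,
                               peak_velocity = 450, angle_deg = 0,
                               noise_sd = 0, t_end = NULL, seed = 1) {
  set.seed(seed)
  D <- 1.875 * amplitude / peak_velocity * 1000
  if (is.null(t_end)) t_end <- rt_ms + D + 150
  t <- seq(-100, t_end, by = 1)
  s <- numeric(length(t))
  during <- t >= rt_ms & t <= rt_ms + D
  s[during] <- 10 * ((t[during] - rt_ms) / D)^3 -
    15 * ((t[during] - rt_ms) / D)^4 + 6 * ((t[during] - rt_ms) / D)^5
  s[t > rt_ms + D] <- 1
  phi <- angle_deg * pi / 180
  data.frame(t = t,
             x = s * amplitude * cos(phi) + rnorm(length(t), 0, noise_sd),
             y = s * amplitude * sin(phi) + rnorm(length(t), 0, noise_sd),
             valid = TRUE)
}

# constant-signal epochs: one value per trial/channel, optional ramp
make_epochs <- function(n_trials = 4, channels = c("Cz", "Fz"),
                        sample_rate = 256, window = c(-200, 1500),
                        fill = 0) {
  dt <- 1000 / sample_rate
  times <- seq(window[1], window[2] - 1e-9, by = dt)
  v <- array(fill, dim = c(n_trials, length(channels), length(times)))
  epoch_set(v, channels, cbind(seq_along(channels), 0), sample_rate,
            times, trial_ids = sprintf("t%03d", seq_len(n_trials)))
}

small_generator_config <- function(seed = 1, ...) {
  generator_config(n_participants = 6, n_blocks = 4,
                   trials_per_condition_per_block = 3, seed = seed, ...)
}
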