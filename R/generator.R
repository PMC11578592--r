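## Synthetic incentivised-saccade / EEG data generator.
##
## Trials are built as a balanced 2x2 factorial (incentive x distractor)
## within each of two drug sessions. Every outcome is constructed as a
## unit-variance standardized latent (planted standardized betas on the
## +/-1 factor codes, a participant intercept where the analysis does not
## remove it, and residual noise), then mapped to physical units, so that
## the pipeline's z-score-then-fit step recovers the planted coefficients
## without attenuation.

TERMS3 <- c("incentive", "distractor", "thp",
            "incentive:distractor", "incentive:thp", "distractor:thp",
            "incentive:distractor:thp")

## term -> term * thp, for +/-1 coded factors (thp maps to the intercept,
## which is dropped; products of +/-1 columns are closed under this map)
mult_by_thp <- function(beta) {
  map <- c(incentive = "incentive:thp", distractor = "distractor:thp",
           thp = "(Intercept)",
           "incentive:distractor" = "incentive:distractor:thp",
           "incentive:thp" = "incentive", "distractor:thp" = "distractor",
           "incentive:distractor:thp" = "incentive:distractor")
  out <- stats::setNames(numeric(length(TERMS3)), TERMS3)
  for (nm in names(beta)) {
    tgt <- map[[nm]]
    if (tgt != "(Intercept)") out[tgt] <- out[tgt] + beta[[nm]]
  }
  out
}

default_effect_sizes <- function() {
  es <- function(...) stats::setNames(c(...), TERMS3)
  list(
    velocity        = es( 0.1266, -0.0158, -0.0001, -0.0067, -0.0216,  0.0023,  0.0052),
    log_rt          = es(-0.0767,  0.0348,  0.0244, -0.0035,  0.0218, -0.0117,  0.0076),
    pull            = es( 0.0023,  0.2446,  0.0283,  0.0028,  0.0030,  0.0226, -0.0039),
    cnv             = es(-0.0917, -0.0032, -0.0512, -0.0002,  0.0165, -0.0042, -0.0037),
    p3a             = es(-0.0186, -0.0088,  0.0004, -0.0042, -0.0002, -0.0095,  0.0054),
    pre_preparation = es(-0.0006,  0.0064, -0.0597, -0.0039, -0.0127, -0.0015, -0.0030)
  )
}

## Compact 16-channel layout (unit head radius, nose up); enough spatial
## structure for adjacency and falloff without full-montage cost.
default_layout <- function() {
  data.frame(
    label = c("Fp1", "Fp2", "AF7", "AF8", "F3", "Fz", "F4", "FC1", "FC2",
              "C3", "Cz", "C4", "CP1", "CP2", "Pz", "Oz"),
    x = c(-0.31, 0.31, -0.59, 0.59, -0.45, 0, 0.45, -0.22, 0.22,
          -0.60, 0, 0.60, -0.25, 0.25, 0, 0),
    y = c(0.95, 0.95, 0.81, 0.81, 0.55, 0.58, 0.55, 0.28, 0.28,
          0, 0, 0, -0.28, -0.28, -0.58, -0.95),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study conditions: 20 participants x 2 drug
#' sessions (placebo, THP) x 20 blocks x 24 trials (6 per condition per
#' block, 480 per session, 120 per condition), main-sequence-linked peak
#' velocities, lognormal reaction times, a bimodal distractor-pull angle
#' mixture, and Cz-dominant P3a + ramping CNV epochs. Planted
#' standardized effect sizes default to the published single-trial
#' regression tables; the mediation path (incentive -> CNV -> RT, with a
#' drug moderation of the b-path) is planted in standardized units.
#'
#' @param n_participants number of participants.
#' @param sessions drug labels, one per session (2 expected).
#' @param n_blocks blocks per session.
#' @param trials_per_condition_per_block trials of each of the 4
#'   conditions in a block.
#' @param seed integer seed; identical config + seed gives identical
#'   output.
#' @param effect_sizes named list of standardized betas per outcome (see
#'   `default_effect_sizes`), each a 7-vector over the factorial terms.
#' @param scales physical SDs: velocity residual (deg/s), log RT (log
#'   units), pull (deg), and the three ERP window means (uV).
#' @param participant_sd participant random-intercept SDs on the
#'   standardized scale (velocity fixed at 0: the within-session
#'   residualization removes it by construction).
#' @param mediation_path standardized path coefficients `b_rt`,
#'   `b_rt_thp`, `b_velocity`, `b_velocity_thp` from the CNV latent to
#'   the behavioural outcomes.
#' @param main_sequence list: slope ((deg/s)/deg), intercept (deg/s) and
#'   per-participant jitter SDs.
#' @param geometry list: eccentricity (deg) of target/distractor from
#'   fixation and angular separation (deg) between them.
#' @param capture distractor-capture mixture: base weight, added weight
#'   when the distractor is salient, drug gain on that weight, component
#'   means/SDs (deg).
#' @param rt_log_mean mean of log RT (log ms).
#' @param cnv,p3a,pre_preparation ERP morphology: ramp onset (ms), bump
#'   latency/width (ms), baseline amplitudes (uV).
#' @param eeg_noise_sd per-sample channel noise SD (uV).
#' @param spatial_falloff Gaussian falloff (layout units) of the Cz
#'   signal over the montage.
#' @param layout data.frame with channel `label`, `x`, `y`.
#' @param artifact_rate probability a trial carries an EEG artifact.
#' @param miss_rate probability a trial has no usable primary saccade.
#' @param sample_rate_eye,sample_rate_eeg Hz.
#' @param fixation_radius_deg radius used for the pull exit angle.
#' @param eye_noise_sd gaze position noise SD (deg).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 20,
                             sessions = c("placebo", "THP"),
                             n_blocks = 20,
                             trials_per_condition_per_block = 6,
                             seed = 1,
                             effect_sizes = default_effect_sizes(),
                             scales = c(velocity = 50, log_rt = 0.2,
                                        pull = 24, cnv = 9.95, p3a = 8,
                                        pre_preparation = 8),
                             participant_sd = c(velocity = 0, log_rt = 0.3,
                                                pull = 0.125, cnv = 0.3,
                                                p3a = 0.3,
                                                pre_preparation = 0.3),
                             mediation_path = c(b_rt = 0.1264,
                                                b_rt_thp = 0.0139,
                                                b_velocity = 0.0149,
                                                b_velocity_thp = 0),
                             main_sequence = list(slope = 30, intercept = 150,
                                                  slope_sd = 3,
                                                  intercept_sd = 15),
                             geometry = list(eccentricity = 11,
                                             separation = 60),
                             capture = list(base = 0.03, distractor = 0.18,
                                            thp_gain = 0.09,
                                            target_mean = -8, target_sd = 10,
                                            capture_sd = 10),
                             rt_log_mean = log(280),
                             cnv = list(onset_ms = 500, base_uv = -4),
                             p3a = list(latency_ms = 240, width_ms = 30,
                                        base_uv = 5),
                             pre_preparation = list(onset_ms = 300,
                                                    base_uv = -2),
                             eeg_noise_sd = 10,
                             spatial_falloff = 0.5,
                             layout = default_layout(),
                             artifact_rate = 0.134,
                             miss_rate = 0.032,
                             sample_rate_eye = 1000,
                             sample_rate_eeg = 256,
                             fixation_radius_deg = 1.5,
                             eye_noise_sd = 0.01) {
  cfg <- list(n_participants = n_participants, sessions = sessions,
              n_blocks = n_blocks,
              trials_per_condition_per_block = trials_per_condition_per_block,
              seed = as.integer(seed), effect_sizes = effect_sizes,
              scales = scales, participant_sd = participant_sd,
              mediation_path = mediation_path, main_sequence = main_sequence,
              geometry = geometry, capture = capture,
              rt_log_mean = rt_log_mean, cnv = cnv, p3a = p3a,
              pre_preparation = pre_preparation,
              eeg_noise_sd = eeg_noise_sd,
              spatial_falloff = spatial_falloff, layout = layout,
              artifact_rate = artifact_rate, miss_rate = miss_rate,
              sample_rate_eye = sample_rate_eye,
              sample_rate_eeg = sample_rate_eeg,
              fixation_radius_deg = fixation_radius_deg,
              eye_noise_sd = eye_noise_sd)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_participants < 1 || n_blocks < 1 ||
        trials_per_condition_per_block < 1)
      stop("counts must be positive")
    if (trials_per_condition_per_block != round(trials_per_condition_per_block))
      stop("non-balanced config: trials_per_condition_per_block must be an integer")
    if (length(sessions) != 2)
      stop("exactly two sessions (drug labels) are expected")
    if (artifact_rate < 0 || artifact_rate > 1 || miss_rate < 0 || miss_rate > 1)
      stop("rates must lie in [0, 1]")
    if (sample_rate_eye <= 0 || sample_rate_eeg <= 0)
      stop("sample rates must be positive")
    if (anyDuplicated(layout$label) || any(!is.finite(layout$x)) ||
        any(!is.finite(layout$y)))
      stop("channel layout inconsistent: labels must be unique, positions finite")
    if (!"Cz" %in% layout$label)
      stop("layout must contain Cz")
    for (nm in names(effect_sizes)) {
      if (!identical(names(effect_sizes[[nm]]), TERMS3))
        stop(sprintf("effect_sizes$%s must be named by the 7 factorial terms", nm))
    }
  })
  ## residual variances on the standardized scale must be positive
  for (v in standardized_variances(cfg)) {
    if (v <= 0)
      stop("planted effects, participant SD and mediation paths leave no ",
           "residual variance; reduce them")
  }
  invisible(cfg)
}

## residual (trial-level) variances of the standardized latents
standardized_variances <- function(cfg) {
  es <- cfg$effect_sizes
  mp <- cfg$mediation_path
  om <- cfg$participant_sd
  var_eta_m <- 1 - sum(es$cnv^2)            # non-factor part of the CNV latent
  tot_rt <- es$log_rt
  tot_v <- es$velocity
  list(
    cnv = 1 - sum(es$cnv^2) - om[["cnv"]]^2,
    p3a = 1 - sum(es$p3a^2) - om[["p3a"]]^2,
    pre_preparation = 1 - sum(es$pre_preparation^2) -
      om[["pre_preparation"]]^2,
    log_rt = 1 - sum(tot_rt^2) -
      (mp[["b_rt"]]^2 + mp[["b_rt_thp"]]^2) * var_eta_m - om[["log_rt"]]^2,
    velocity = 1 - sum(tot_v^2) -
      (mp[["b_velocity"]]^2 + mp[["b_velocity_thp"]]^2) * var_eta_m
  )
}

#' Generate a balanced synthetic trial table
#'
#' Produces one row per trial with factors, geometry, saccade kinematics
#' (main-sequence-linked peak velocity, lognormal RT, bimodal pull), the
#' planted ERP window means that [generate_eeg_epochs()] will realize,
#' and artifact/miss flags.
#'
#' @param config a [generator_config()].
#' @return data.frame with one row per trial; attribute `config` holds
#'   the generating configuration.
#' @export
generate_trial_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  set.seed(config$seed)
  np <- config$n_participants
  nb <- config$n_blocks
  tpc <- config$trials_per_condition_per_block
  per_block <- 4L * tpc
  per_session <- nb * per_block

  participants <- sprintf("P%02d", seq_len(np))
  rows <- vector("list", np * 2L)
  k <- 0L
  ## per-participant structure (shared across sessions)
  ms <- config$main_sequence
  pj <- list(slope = stats::rnorm(np, 0, ms$slope_sd),
             intercept = stats::rnorm(np, 0, ms$intercept_sd))
  om <- config$participant_sd
  u <- list(cnv = stats::rnorm(np, 0, om[["cnv"]]),
            p3a = stats::rnorm(np, 0, om[["p3a"]]),
            pre_preparation = stats::rnorm(np, 0, om[["pre_preparation"]]),
            log_rt = stats::rnorm(np, 0, om[["log_rt"]]),
            pull = stats::rnorm(np, 0, om[["pull"]] * config$scales[["pull"]]))

  for (i in seq_len(np)) {
    drug_order <- if (i %% 2L == 1L) config$sessions else rev(config$sessions)
    for (s in 1:2) {
      cond <- expand.grid(incentive = c(0, 50), distractor = c(0, 1))
      block_rows <- do.call(rbind, lapply(seq_len(nb), function(b) {
        idx <- sample(rep(seq_len(4L), tpc))
        data.frame(block = b, incentive = cond$incentive[idx],
                   distractor = cond$distractor[idx])
      }))
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant = participants[i], session = s,
        drug = drug_order[s], block = block_rows$block,
        trial = seq_len(per_session),
        incentive = block_rows$incentive,
        distractor = block_rows$distractor,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$thp <- as.numeric(tab$drug == "THP")
  tab$trial_id <- sprintf("%s_s%d_t%03d", tab$participant, tab$session,
                          tab$trial)
  n <- nrow(tab)
  pidx <- match(tab$participant, participants)

  ## +/-1 factor codes (exact population z-scores of the balanced design)
  zi <- ifelse(tab$incentive == 50, 1, -1)
  zd <- ifelse(tab$distractor == 1, 1, -1)
  zt <- ifelse(tab$thp == 1, 1, -1)
  Z <- cbind(zi, zd, zt, zi * zd, zi * zt, zd * zt, zi * zd * zt)
  colnames(Z) <- TERMS3

  es <- config$effect_sizes
  mp <- config$mediation_path
  rv <- standardized_variances(config)

  ## mediator (CNV) latent and the other ERP latents
  eta_m <- u$cnv[pidx] + stats::rnorm(n, 0, sqrt(rv$cnv))
  m_star <- drop(Z %*% es$cnv) + eta_m
  p_star <- drop(Z %*% es$p3a) + u$p3a[pidx] + stats::rnorm(n, 0, sqrt(rv$p3a))
  pp_star <- drop(Z %*% es$pre_preparation) + u$pre_preparation[pidx] +
    stats::rnorm(n, 0, sqrt(rv$pre_preparation))

  ## behavioural latents: direct coefficients keep the totals at the
  ## planted table values after the indirect (via-CNV) paths are added
  c_rt <- es$log_rt - mp[["b_rt"]] * es$cnv -
    mp[["b_rt_thp"]] * mult_by_thp(es$cnv)
  c_v <- es$velocity - mp[["b_velocity"]] * es$cnv -
    mp[["b_velocity_thp"]] * mult_by_thp(es$cnv)
  y_rt <- drop(Z %*% c_rt) + mp[["b_rt"]] * m_star +
    mp[["b_rt_thp"]] * m_star * zt + u$log_rt[pidx] +
    stats::rnorm(n, 0, sqrt(rv$log_rt))
  y_v <- drop(Z %*% c_v) + mp[["b_velocity"]] * m_star +
    mp[["b_velocity_thp"]] * m_star * zt + stats::rnorm(n, 0, sqrt(rv$velocity))

  ## geometry: fixation at the origin, target at `eccentricity` along a
  ## random direction, distractor rotated `separation` deg to a random side
  geo <- config$geometry
  th <- stats::runif(n, -180, 180)
  side <- sample(c(-1, 1), n, replace = TRUE)
  deg2rad <- pi / 180
  tab$target_angle_deg <- th
  tab$distractor_side <- side
  tab$fixation_x <- 0
  tab$fixation_y <- 0
  tab$target_x <- geo$eccentricity * cos(th * deg2rad)
  tab$target_y <- geo$eccentricity * sin(th * deg2rad)
  tab$distractor_x <- geo$eccentricity * cos((th + side * geo$separation) * deg2rad)
  tab$distractor_y <- geo$eccentricity * sin((th + side * geo$separation) * deg2rad)

  ## kinematics
  sc <- config$scales
  tab$amplitude <- stats::rnorm(n, geo$eccentricity, 0.4)
  tab$peak_velocity <- (ms$intercept + pj$intercept[pidx]) +
    (ms$slope + pj$slope[pidx]) * tab$amplitude + sc[["velocity"]] * y_v
  tab$rt_ms <- exp(config$rt_log_mean + sc[["log_rt"]] * y_rt)

  ## distractor pull: two-component mixture. Capture weight rises with
  ## the planted distractor effect and is modulated by the drug; the
  ## drug/interaction remainder not carried by the weights goes through a
  ## linear shift of the target component (first-order calibration).
  cap <- config$capture
  dmu <- geo$separation - cap$target_mean
  w <- cap$base + tab$distractor * cap$distractor * (1 + cap$thp_gain * zt)
  w <- pmin(pmax(w, 0), 1)
  wcontrib_d <- cap$distractor * dmu / (2 * sc[["pull"]])    # distractor term
  wcontrib_t <- cap$distractor * cap$thp_gain * dmu / (2 * sc[["pull"]])
  lin <- es$pull
  lin[["distractor"]] <- lin[["distractor"]] - wcontrib_d
  lin[["thp"]] <- lin[["thp"]] - wcontrib_t
  lin[["distractor:thp"]] <- lin[["distractor:thp"]] - wcontrib_t
  shift <- sc[["pull"]] * drop(Z %*% lin) + u$pull[pidx]
  captured <- stats::runif(n) < w
  tab$pull_deg <- shift + ifelse(
    captured,
    stats::rnorm(n, geo$separation, cap$capture_sd),
    stats::rnorm(n, cap$target_mean, cap$target_sd))

  ## ERP window means (uV) to be realized by generate_eeg_epochs()
  tab$cnv <- config$cnv$base_uv + sc[["cnv"]] * m_star
  tab$p3a <- config$p3a$base_uv + sc[["p3a"]] * p_star
  tab$pre_preparation <- config$pre_preparation$base_uv +
    sc[["pre_preparation"]] * pp_star

  ## validity flags
  tab$missed <- stats::runif(n) < config$miss_rate
  art <- stats::runif(n) < config$artifact_rate
  type <- ifelse(stats::runif(n) < 0.6, "ocular", "voltage")
  tab$eeg_ok <- !art
  tab$eeg_artifact_type <- ifelse(art, type, NA_character_)
  tab$rt_ms[tab$missed] <- NA_real_
  tab$peak_velocity[tab$missed] <- NA_real_
  tab$amplitude[tab$missed] <- NA_real_
  tab$pull_deg[tab$missed] <- NA_real_

  attr(tab, "config") <- config
  rownames(tab) <- NULL
  tab
}

## minimum-jerk position profile on [0, 1]
minjerk_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Generate eye-position traces for a set of trials
#'
#' Each trace holds fixation noise, a latency period equal to the trial's
#' RT, and a straight minimum-jerk saccade whose amplitude, peak velocity
#' (peak = 1.875 A / D) and initial direction reproduce the trial's
#' planted kinematics within discretisation error. Missed trials give a
#' fixation-only trace.
#'
#' @param trials rows of a [generate_trial_table()] result.
#' @param config the generating [generator_config()].
#' @return named list (by `trial_id`) of data.frames `t`, `x`, `y`,
#'   `valid`, each with attributes `geometry` (fixation/target/distractor
#'   xy) and `flagged` (TRUE when the requested peak velocity is
#'   incompatible with a minimum-jerk saccade of that amplitude).
#' @export
generate_eye_traces <- function(trials, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed((config$seed * 1009L + nrow(trials)) %% 2147483629L)
  dt <- 1000 / config$sample_rate_eye
  deg2rad <- pi / 180
  out <- vector("list", nrow(trials))
  for (j in seq_len(nrow(trials))) {
    tr <- trials[j, ]
    geom <- list(fixation = c(tr$fixation_x, tr$fixation_y),
                 target = c(tr$target_x, tr$target_y),
                 distractor = c(tr$distractor_x, tr$distractor_y))
    flagged <- FALSE
    if (isTRUE(tr$missed) || is.na(tr$rt_ms)) {
      tt <- seq(-100, 1000, by = dt)
      x <- tr$fixation_x + stats::rnorm(length(tt), 0, config$eye_noise_sd)
      y <- tr$fixation_y + stats::rnorm(length(tt), 0, config$eye_noise_sd)
    } else {
      A <- tr$amplitude
      V <- tr$peak_velocity
      D <- 1.875 * A / V * 1000          # ms
      if (!is.finite(D) || D < 8 || D > 200) {
        flagged <- TRUE
        D <- min(max(D, 8), 200)
      }
      phi <- (tr$target_angle_deg + tr$distractor_side * tr$pull_deg) * deg2rad
      endx <- tr$fixation_x + A * cos(phi)
      endy <- tr$fixation_y + A * sin(phi)
      tt <- seq(-100, tr$rt_ms + D + 100, by = dt)
      s <- numeric(length(tt))
      during <- tt >= tr$rt_ms & tt <= tr$rt_ms + D
      s[during] <- minjerk_s((tt[during] - tr$rt_ms) / D)
      s[tt > tr$rt_ms + D] <- 1
      x <- tr$fixation_x + s * (endx - tr$fixation_x) +
        stats::rnorm(length(tt), 0, config$eye_noise_sd)
      y <- tr$fixation_y + s * (endy - tr$fixation_y) +
        stats::rnorm(length(tt), 0, config$eye_noise_sd)
    }
    tra <- data.frame(t = tt, x = x, y = y, valid = TRUE)
    attr(tra, "geometry") <- geom
    attr(tra, "flagged") <- flagged
    attr(tra, "trial_id") <- tr$trial_id
    out[[j]] <- tra
  }
  names(out) <- trials$trial_id
  out
}

#' Generate EEG epochs realizing the planted ERP window means
#'
#' Builds Cz-dominant epochs: a P3a Gaussian bump plus a linear CNV ramp
#' (preparation-cue epochs) or a late negativity ramp (incentive-cue
#' epochs), spatially attenuated over the montage by a Gaussian falloff,
#' plus white channel noise. The ramp slope and bump amplitude are solved
#' per trial after the noise draw so that the baselined window means at
#' Cz equal the trial table's planted `cnv` / `p3a` /
#' `pre_preparation` values exactly. Trials flagged with a voltage
#' artifact get a >|200| uV excursion injected.
#'
#' @param trials rows of a [generate_trial_table()] result.
#' @param config the generating [generator_config()].
#' @param t0_event `"preparation"` (epoch -200:1500 ms, P3a + CNV) or
#'   `"incentive"` (epoch -200:1100 ms, late negativity).
#' @return an [epoch_set()].
#' @export
generate_eeg_epochs <- function(trials, config,
                                t0_event = c("preparation", "incentive")) {
  stopifnot(inherits(config, "generator_config"))
  t0_event <- match.arg(t0_event)
  lay <- config$layout
  set.seed((config$seed * 2003L + nrow(trials) +
              ifelse(t0_event == "preparation", 0L, 1L)) %% 2147483629L)

  dt <- 1000 / config$sample_rate_eeg
  win <- if (t0_event == "preparation") c(-200, 1500) else c(-200, 1100)
  times <- seq(win[1], win[2] - 1e-9, by = dt)
  ns <- length(times)
  nc <- nrow(lay)
  n <- nrow(trials)

  czi <- which(lay$label == "Cz")
  d2 <- (lay$x - lay$x[czi])^2 + (lay$y - lay$y[czi])^2
  falloff <- exp(-d2 / (2 * config$spatial_falloff^2))

  base_idx <- which(times >= -100 & times < 0)
  if (t0_event == "preparation") {
    ramp_onset <- config$cnv$onset_ms
    win_main <- which(times >= 1200 & times < 1500)
    target_main <- trials$cnv
    bump <- exp(-(times - config$p3a$latency_ms)^2 /
                  (2 * config$p3a$width_ms^2))
    win_p3a <- which(times >= 200 & times < 280)
    target_p3a <- trials$p3a
  } else {
    ramp_onset <- config$pre_preparation$onset_ms
    win_main <- which(times >= 900 & times < 1100)
    target_main <- trials$pre_preparation
    bump <- NULL
  }
  ramp <- pmax(times - ramp_onset, 0) / 1000    # seconds above onset
  ramp_gain <- mean(ramp[win_main])             # uV per (uV/s) in the window

  volt <- array(stats::rnorm(n * nc * ns, 0, config$eeg_noise_sd),
                dim = c(n, nc, ns))

  for (j in seq_len(n)) {
    nz <- volt[j, czi, ]
    nz_base <- mean(nz[base_idx])
    if (!is.null(bump)) {
      amp <- (target_p3a[j] - (mean(nz[win_p3a]) - nz_base)) /
        mean(bump[win_p3a])
      slope <- (target_main[j] - (mean(nz[win_main]) - nz_base) -
                  amp * mean(bump[win_main])) / ramp_gain
      sig <- slope * ramp + amp * bump
    } else {
      slope <- (target_main[j] - (mean(nz[win_main]) - nz_base)) / ramp_gain
      sig <- slope * ramp
    }
    volt[j, , ] <- volt[j, , ] + outer(falloff, sig)
  }

  ## voltage artifacts: 50 ms square excursion beyond the rejection bound
  bad <- which(!trials$eeg_ok &
                 trials$eeg_artifact_type %in% "voltage")
  for (j in bad) {
    ch <- sample(nc, 1)
    st <- sample(ns - ceiling(50 / dt), 1)
    sp <- sample(c(-1, 1), 1)
    volt[j, ch, st:(st + ceiling(50 / dt))] <-
      volt[j, ch, st:(st + ceiling(50 / dt))] + sp * 320
  }

  epoch_set(volt, channels = lay$label,
            positions = as.matrix(lay[, c("x", "y")]),
            sample_rate = config$sample_rate_eeg, times = times,
            t0_event = t0_event, trial_ids = trials$trial_id)
}
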