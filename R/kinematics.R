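## Saccade parsing and the three behavioural outcomes: residual peak
## velocity (vigour), log saccadic RT, and distractor pull.

#' Sliding-window gaze speed
#'
#' Central-difference velocity components averaged over a 4 ms window,
#' combined into speed (deg/s). Samples in segments faster than
#' `speed_max` or touching tracking loss are masked (NA). Acceleration
#' (deg/s^2) is the central difference of the masked speed.
#'
#' @param trace data.frame `t` (ms, uniform 1 ms steps expected), `x`,
#'   `y` (deg), `valid` (logical).
#' @param window_ms smoothing window width.
#' @param speed_max masking threshold in deg/s.
#' @return data.frame `t`, `speed`, `accel` (NA where masked).
#' @export
compute_velocity <- function(trace, window_ms = 4, speed_max = 3000) {
  t <- trace$t
  n <- length(t)
  dt <- diff(t)
  if (n < window_ms + 2) stop("trace shorter than the velocity window")
  if (any(abs(dt - dt[1]) > 1e-6)) stop("non-uniform sampling")
  dts <- dt[1] / 1000
  valid <- if (!is.null(trace$valid)) trace$valid else rep(TRUE, n)
  valid <- valid & is.finite(trace$x) & is.finite(trace$y)

  cdiff <- function(z) c(NA, (z[3:n] - z[1:(n - 2)]) / (2 * dts), NA)
  vx <- cdiff(trace$x)
  vy <- cdiff(trace$y)
  k <- max(3L, round(window_ms / dt[1]) + 1L)        # centered window
  if (k %% 2L == 0L) k <- k + 1L
  smooth <- function(z) as.numeric(stats::filter(z, rep(1 / k, k), sides = 2))
  speed <- sqrt(smooth(vx)^2 + smooth(vy)^2)

  ## a sample's estimate is valid only if every sample it touches is
  vok <- as.numeric(stats::filter(as.numeric(valid), rep(1, k + 2), sides = 2))
  speed[is.na(vok) | vok < (k + 2)] <- NA
  speed[speed > speed_max] <- NA
  accel <- c(NA, abs(speed[3:n] - speed[1:(n - 2)]) / (2 * dts), NA)
  data.frame(t = t, speed = speed, accel = accel)
}

#' Detect saccades by velocity/acceleration criteria
#'
#' Contiguous runs of samples exceeding the velocity threshold (and/or
#' the acceleration threshold, per `combine`) become events; amplitude
#' is the Euclidean start-to-end distance and peak velocity the maximum
#' masked speed within the event.
#'
#' @param trace data.frame as for [compute_velocity()].
#' @param velocity_threshold deg/s.
#' @param accel_threshold deg/s^2.
#' @param combine `"or"` (either criterion marks a saccade sample, the
#'   trackers' standard parser) or `"and"`.
#' @param min_duration_ms drop blips shorter than this.
#' @return data.frame of events: `onset_ms`, `offset_ms`,
#'   `amplitude_deg`, `peak_velocity_deg_s`, `start_x`, `start_y`,
#'   `end_x`, `end_y` (possibly 0 rows).
#' @export
detect_saccades <- function(trace, velocity_threshold = 30,
                            accel_threshold = 8000,
                            combine = c("or", "and"),
                            min_duration_ms = 3) {
  combine <- match.arg(combine)
  vel <- compute_velocity(trace)
  v <- !is.na(vel$speed) & vel$speed > velocity_threshold
  a <- !is.na(vel$accel) & vel$accel > accel_threshold
  above <- if (combine == "or") v | a else v & a
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  n <- nrow(trace)
  dt <- trace$t[2] - trace$t[1]
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    if (trace$t[e] - trace$t[s] < min_duration_ms) next
    ## the threshold crossing lags the true movement onset; speed rises
    ## ~ tau^2 at saccade start, so extrapolate back by 2 v / v'
    onset <- trace$t[s]
    if (s + 2L <= n && !anyNA(vel$speed[s:(s + 2L)])) {
      slope <- (vel$speed[s + 2L] - vel$speed[s]) / (2 * dt)
      if (is.finite(slope) && slope > 0) {
        onset <- onset - min(2 * vel$speed[s] / slope, 4 * dt)
      }
    }
    pk <- suppressWarnings(max(vel$speed[s:e], na.rm = TRUE))
    if (!is.finite(pk)) pk <- NA_real_
    out[[length(out) + 1L]] <- data.frame(
      onset_ms = onset, offset_ms = trace$t[e],
      amplitude_deg = sqrt((trace$x[e] - trace$x[s])^2 +
                             (trace$y[e] - trace$y[s])^2),
      peak_velocity_deg_s = pk,
      start_x = trace$x[s], start_y = trace$y[s],
      end_x = trace$x[e], end_y = trace$y[e])
  }
  if (!length(out)) {
    return(data.frame(onset_ms = numeric(), offset_ms = numeric(),
                      amplitude_deg = numeric(),
                      peak_velocity_deg_s = numeric(),
                      start_x = numeric(), start_y = numeric(),
                      end_x = numeric(), end_y = numeric()))
  }
  do.call(rbind, out)
}

#' Select the primary saccade of a trial
#'
#' The first saccade over `min_amplitude` deg in amplitude with onset in
#' `rt_window` ms after target onset. Trials without one are excluded
#' (`no_primary_saccade`); selected saccades with peak velocity outside
#' `velocity_bounds` are excluded (`velocity_bounds`).
#'
#' @param events data.frame from [detect_saccades()], sorted by onset.
#' @param rt_window ms window after target onset.
#' @param min_amplitude deg.
#' @param velocity_bounds deg/s inclusion bounds.
#' @return list: `event` (one-row data.frame or NULL), `included`
#'   (logical), `reason` (NA or the exclusion reason).
#' @export
select_primary_saccade <- function(events, rt_window = c(100, 900),
                                   min_amplitude = 1,
                                   velocity_bounds = c(50, 1600)) {
  cand <- events[events$amplitude_deg > min_amplitude &
                   events$onset_ms >= rt_window[1] &
                   events$onset_ms <= rt_window[2], , drop = FALSE]
  if (!nrow(cand)) {
    return(list(event = NULL, included = FALSE,
                reason = "no_primary_saccade"))
  }
  ev <- cand[1, , drop = FALSE]
  if (is.na(ev$peak_velocity_deg_s) ||
      ev$peak_velocity_deg_s < velocity_bounds[1] ||
      ev$peak_velocity_deg_s > velocity_bounds[2]) {
    return(list(event = ev, included = FALSE, reason = "velocity_bounds"))
  }
  list(event = ev, included = TRUE, reason = NA_character_)
}

## signed angle (deg) from vector u to vector v, in (-180, 180], ties at
## -180 mapped to +180
signed_angle <- function(u, v) {
  ang <- atan2(u[1] * v[2] - u[2] * v[1], u[1] * v[1] + u[2] * v[2]) * 180 / pi
  if (isTRUE(all.equal(ang, -180))) ang <- 180
  ang
}

#' Distractor pull angle at fixation exit
#'
#' Signed angle between the fixation-to-gaze vector at the moment gaze
#' first leaves the fixation circle and the fixation-to-target line;
#' positive values are biased toward the distractor.
#'
#' @param trace data.frame as for [compute_velocity()].
#' @param fixation_xy,target_xy,distractor_xy length-2 positions (deg).
#' @param fixation_radius_deg exit-circle radius.
#' @param from_ms only samples at or after this time are considered.
#' @return signed degrees in (-180, 180], or NA with attribute `reason =
#'   "no_exit"` if gaze never leaves the circle.
#' @export
distractor_pull <- function(trace, fixation_xy, target_xy, distractor_xy,
                            fixation_radius_deg = 1.5, from_ms = 0) {
  ok <- trace$t >= from_ms &
    (if (!is.null(trace$valid)) trace$valid else TRUE)
  dx <- trace$x - fixation_xy[1]
  dy <- trace$y - fixation_xy[2]
  outside <- ok & sqrt(dx^2 + dy^2) > fixation_radius_deg
  i <- which(outside)[1]
  if (is.na(i)) {
    return(structure(NA_real_, reason = "no_exit"))
  }
  vg <- c(dx[i], dy[i])
  vt <- target_xy - fixation_xy
  vd <- distractor_xy - fixation_xy
  raw <- signed_angle(vt, vg)
  side <- sign(signed_angle(vt, vd))
  if (side == 0) side <- 1
  ang <- raw * side
  if (isTRUE(all.equal(ang, -180))) ang <- 180
  ang
}

#' Parse one trial's trace into its kinematic outcomes
#'
#' @param trace a trace with a `geometry` attribute (as produced by
#'   [generate_eye_traces()]) or explicit geometry arguments.
#' @param fixation_xy,target_xy,distractor_xy positions (deg); default
#'   from the trace's geometry attribute.
#' @param fixation_radius_deg exit radius for the pull angle.
#' @param ... passed to [detect_saccades()] / [select_primary_saccade()].
#' @return one-row data.frame: `rt_ms`, `log_rt`, `amplitude_deg`,
#'   `peak_velocity_deg_s`, `pull_deg`, `included`, `exclusion_reason`.
#' @export
trial_kinematics <- function(trace, fixation_xy = NULL, target_xy = NULL,
                             distractor_xy = NULL,
                             fixation_radius_deg = 1.5, ...) {
  geom <- attr(trace, "geometry")
  if (is.null(fixation_xy)) fixation_xy <- geom$fixation
  if (is.null(target_xy)) target_xy <- geom$target
  if (is.null(distractor_xy)) distractor_xy <- geom$distractor
  ev <- select_primary_saccade(detect_saccades(trace, ...))
  row <- data.frame(rt_ms = NA_real_, log_rt = NA_real_,
                    amplitude_deg = NA_real_,
                    peak_velocity_deg_s = NA_real_, pull_deg = NA_real_,
                    included = ev$included,
                    exclusion_reason = ev$reason,
                    stringsAsFactors = FALSE)
  if (!is.null(ev$event)) {
    row$rt_ms <- ev$event$onset_ms
    row$log_rt <- log(ev$event$onset_ms)
    row$amplitude_deg <- ev$event$amplitude_deg
    row$peak_velocity_deg_s <- ev$event$peak_velocity_deg_s
    pull <- distractor_pull(trace, fixation_xy, target_xy, distractor_xy,
                            fixation_radius_deg,
                            from_ms = ev$event$onset_ms - 5)
    if (is.na(pull) && ev$included) {
      row$included <- FALSE
      row$exclusion_reason <- "no_exit"
    }
    row$pull_deg <- as.numeric(pull)
  }
  row
}

#' Residual peak velocity within participant x drug session
#'
#' Ordinary least-squares of peak velocity on amplitude (with intercept)
#' within each participant x session group, combining across incentive
#' and distractor levels; the per-trial residual is the vigour measure.
#' Group mean residuals are zero and residuals are orthogonal to
#' amplitude within every group. Groups with fewer than `min_trials`
#' usable trials are flagged and their trials excluded from velocity
#' analyses.
#'
#' @param trials trial table with `participant`, `drug`,
#'   `peak_velocity`, `amplitude` columns (NAs allowed).
#' @param min_trials minimum usable trials per group.
#' @return the table with a `residual_velocity` column added (NA where
#'   not computable).
#' @export
residual_velocity <- function(trials, min_trials = 3) {
  stopifnot(all(c("participant", "drug", "peak_velocity", "amplitude")
                %in% names(trials)))
  grp <- interaction(trials$participant, trials$drug, drop = TRUE)
  res <- rep(NA_real_, nrow(trials))
  for (g in levels(grp)) {
    sel <- which(grp == g & is.finite(trials$peak_velocity) &
                   is.finite(trials$amplitude))
    if (length(sel) < min_trials) {
      if (length(sel))
        message(sprintf("group %s has %d usable trials; flagged", g,
                        length(sel)))
      next
    }
    fit <- stats::lm.fit(cbind(1, trials$amplitude[sel]),
                         trials$peak_velocity[sel])
    res[sel] <- fit$residuals
  }
  trials$residual_velocity <- res
  trials
}

#' Per-condition kernel-smoothed densities of pull angles
#'
#' Per-participant Gaussian kernel densities on a fixed angle grid,
#' averaged per condition; each density integrates to 1 on the grid.
#'
#' @param values pull angles (deg).
#' @param participant participant ids aligned with `values`.
#' @param condition condition labels aligned with `values`.
#' @param grid evaluation grid (deg).
#' @param bw kernel bandwidth (deg).
#' @return list: `grid`, `mean` (conditions x bins matrix),
#'   `per_participant` (participants x conditions x bins array),
#'   `participants`, `conditions`.
#' @export
kinematics_summary_density <- function(values, participant, condition,
                                       grid = seq(-90, 90, by = 1),
                                       bw = 8) {
  ok <- is.finite(values)
  values <- values[ok]; participant <- participant[ok]
  condition <- condition[ok]
  parts <- sort(unique(participant))
  conds <- sort(unique(as.character(condition)))
  arr <- array(NA_real_, dim = c(length(parts), length(conds), length(grid)),
               dimnames = list(parts, conds, NULL))
  for (p in parts) {
    for (cc in conds) {
      v <- values[participant == p & condition == cc]
      if (length(v) < 2) stop(sprintf(
        "condition '%s' has fewer than 2 values for participant %s", cc, p))
      d <- stats::density(v, bw = bw, from = min(grid), to = max(grid),
                          n = length(grid))
      arr[p, cc, ] <- d$y / sum(d$y * mean(diff(grid)))
    }
  }
  list(grid = grid, mean = apply(arr, c(2, 3), mean),
       per_participant = arr, participants = parts, conditions = conds)
}

#' Per-participant difference of pull densities between factor levels
#'
#' @param trials trial table with `pull_deg`, `participant` and the
#'   factor column.
#' @param factor column name (two levels; higher minus lower).
#' @param subset optional logical selector (e.g. distractor-present
#'   trials only).
#' @inheritParams kinematics_summary_density
#' @return list: `grid`, `curves` (participants x bins difference
#'   matrix), `participants`.
#' @export
pull_density_difference <- function(trials, factor, subset = NULL,
                                    grid = seq(-90, 90, by = 1), bw = 8) {
  if (!is.null(subset)) trials <- trials[subset, , drop = FALSE]
  f <- trials[[factor]]
  lev <- sort(unique(f))
  if (length(lev) != 2) stop("factor must have two levels")
  dens <- kinematics_summary_density(trials$pull_deg, trials$participant,
                                     ifelse(f == lev[2], "hi", "lo"),
                                     grid = grid, bw = bw)
  curves <- dens$per_participant[, "hi", , drop = TRUE] -
    dens$per_participant[, "lo", , drop = TRUE]
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1)
  list(grid = grid, curves = curves, participants = dens$participants)
}
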