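#' EEG epoch container
#'
#' Trials x channels x samples voltage array (uV) with channel labels,
#' 2-D layout positions (used for spatial adjacency), timing metadata and
#' trial ids. All windows in this package are half-open `[start, end)` on
#' the sample times, with t = 0 at the epoching event.
#'
#' @param voltages numeric array, trials x channels x samples.
#' @param channels character channel labels.
#' @param positions numeric matrix (channels x 2) of layout coordinates.
#' @param sample_rate Hz.
#' @param times sample times in ms relative to the epoching event.
#' @param t0_event label of the epoching event.
#' @param trial_ids character ids aligning trials with the trial table.
#' @return list of class `EpochSet`.
#' @export
epoch_set <- function(voltages, channels, positions, sample_rate, times,
                      t0_event = "preparation", trial_ids = NULL) {
  stopifnot(length(dim(voltages)) == 3)
  if (dim(voltages)[2] != length(channels))
    stop("channel count inconsistent with voltage array")
  if (!is.null(positions) && nrow(positions) != length(channels))
    stop("channel positions inconsistent with layout")
  if (dim(voltages)[3] != length(times))
    stop("times inconsistent with voltage array")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (is.null(trial_ids)) trial_ids <- as.character(seq_len(dim(voltages)[1]))
  structure(list(voltages = voltages, channels = channels,
                 positions = positions, sample_rate = sample_rate,
                 times = times, t0_event = t0_event,
                 trial_ids = as.character(trial_ids)),
            class = "EpochSet")
}

#' @method print EpochSet
#' @export
print.EpochSet <- function(x, ...) {
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz (%s; %.1f..%.1f ms)\n",
              dim(x$voltages)[1], dim(x$voltages)[2], dim(x$voltages)[3],
              x$sample_rate, x$t0_event, min(x$times), max(x$times)))
  invisible(x)
}

#' Subset an EpochSet by trial id
#' @param epochs an [epoch_set()].
#' @param trial_ids ids to keep (order preserved).
#' @return an [epoch_set()].
#' @export
subset_epochs <- function(epochs, trial_ids) {
  idx <- match(trial_ids, epochs$trial_ids)
  if (anyNA(idx)) stop("unknown trial ids in subset")
  epoch_set(epochs$voltages[idx, , , drop = FALSE], epochs$channels,
            epochs$positions, epochs$sample_rate, epochs$times,
            epochs$t0_event, epochs$trial_ids[idx])
}

#' Pre-process raw epochs
#'
#' Mastoid-average re-referencing, zero-phase Butterworth band-pass
#' (high-pass + low-pass cascade applied with `filtfilt`), Butterworth
#' band-stop notch at the line frequency, then integer-factor
#' downsampling (the band-pass provides the anti-alias filtering).
#'
#' @param epochs raw [epoch_set()] including the mastoid channels.
#' @param band band-pass edges in Hz.
#' @param line_freq notch centre in Hz.
#' @param notch_width full width of the stop band in Hz.
#' @param target_rate output sampling rate (must divide the input rate).
#' @param mastoids labels of the two mastoid reference channels.
#' @return filtered, re-referenced, resampled [epoch_set()] without the
#'   mastoid channels.
#' @export
preprocess <- function(epochs, band = c(0.1, 80), line_freq = 50,
                       notch_width = 4, target_rate = 256,
                       mastoids = c("A1", "A2")) {
  fs <- epochs$sample_rate
  if (!all(mastoids %in% epochs$channels))
    stop("mastoid channels missing: cannot re-reference")
  if (2 * band[2] >= fs)
    stop("band upper edge incompatible with the sampling rate")
  dec <- fs / target_rate
  if (abs(dec - round(dec)) > 1e-9)
    stop("target_rate must divide the input sampling rate")
  dec <- as.integer(round(dec))

  nyq <- fs / 2
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  nt <- signal::butter(2, c(line_freq - notch_width / 2,
                            line_freq + notch_width / 2) / nyq,
                       type = "stop")

  mi <- match(mastoids, epochs$channels)
  keep <- setdiff(seq_along(epochs$channels), mi)
  v <- epochs$voltages
  n <- dim(v)[1]
  ref <- (v[, mi[1], , drop = FALSE] + v[, mi[2], , drop = FALSE]) / 2
  out_idx <- seq(1, dim(v)[3], by = dec)
  res <- array(0, dim = c(n, length(keep), length(out_idx)))
  for (i in seq_len(n)) {
    for (jc in seq_along(keep)) {
      x <- v[i, keep[jc], ] - ref[i, 1, ]
      x <- signal::filtfilt(hp, x)
      x <- signal::filtfilt(lp, x)
      x <- signal::filtfilt(nt, x)
      res[i, jc, ] <- x[out_idx]
    }
  }
  epoch_set(res, epochs$channels[keep],
            if (is.null(epochs$positions)) NULL else
              epochs$positions[keep, , drop = FALSE],
            target_rate, epochs$times[out_idx], epochs$t0_event,
            epochs$trial_ids)
}

#' Window and baseline epochs
#'
#' Restricts the epochs to `window` and subtracts, per trial and channel,
#' the mean voltage over the `baseline` window. Both windows are
#' half-open on sample times. Applying the operation twice equals
#' applying it once.
#'
#' @param epochs an [epoch_set()].
#' @param window epoch window `c(start, end)` in ms.
#' @param baseline baseline window `c(start, end)` in ms (must lie inside
#'   the epoch).
#' @return baselined [epoch_set()].
#' @export
epoch_and_baseline <- function(epochs, window = c(-200, 1500),
                               baseline = c(-100, 0)) {
  tms <- epochs$times
  dt <- 1000 / epochs$sample_rate
  if (window[1] < tms[1] - dt / 2 || window[2] > tms[length(tms)] + dt)
    stop("requested window extends past the recorded epoch")
  widx <- which(tms >= window[1] & tms < window[2])
  bidx <- which(tms >= baseline[1] & tms < baseline[2])
  if (!length(bidx)) stop("baseline window contains no samples")
  v <- epochs$voltages
  bmean <- apply(v[, , bidx, drop = FALSE], c(1, 2), mean)
  v <- sweep(v, c(1, 2), bmean, `-`)[, , widx, drop = FALSE]
  epoch_set(v, epochs$channels, epochs$positions, epochs$sample_rate,
            tms[widx], epochs$t0_event, epochs$trial_ids)
}

#' Reject artifact trials
#'
#' A trial is dropped iff any channel sample lies outside
#' `voltage_bounds`, or the trial carries an ocular (blink/saccade-
#' in-epoch) flag from the eye parser.
#'
#' @param epochs an [epoch_set()].
#' @param ocular_flags optional data.frame with columns `trial_id` and
#'   logical `ocular`.
#' @param voltage_bounds rejection bounds in uV.
#' @return list: `epochs` (retained trials) and `rejections` (data.frame
#'   `trial_id`, `rejected`, `reason`).
#' @export
reject_artifacts <- function(epochs, ocular_flags = NULL,
                             voltage_bounds = c(-200, 200)) {
  v <- epochs$voltages
  bad_volt <- apply(v, 1, function(tr)
    any(tr < voltage_bounds[1] | tr > voltage_bounds[2]))
  bad_ocul <- rep(FALSE, length(epochs$trial_ids))
  if (!is.null(ocular_flags)) {
    m <- match(epochs$trial_ids, ocular_flags$trial_id)
    bad_ocul <- ocular_flags$ocular[m] %in% TRUE
  }
  reason <- rep(NA_character_, length(bad_volt))
  reason[bad_ocul] <- "ocular"
  reason[bad_volt] <- "voltage"
  rej <- data.frame(trial_id = epochs$trial_ids,
                    rejected = bad_volt | bad_ocul, reason = reason,
                    stringsAsFactors = FALSE)
  keep <- epochs$trial_ids[!rej$rejected]
  list(epochs = subset_epochs(epochs, keep), rejections = rej)
}

#' Mean amplitude in a time window at one electrode
#'
#' Arithmetic mean of the voltage over samples with `t` in
#' `[window[1], window[2])` at the named electrode.
#'
#' @param epochs an [epoch_set()].
#' @param window `c(start, end)` ms.
#' @param electrode channel label.
#' @return numeric vector named by trial id.
#' @export
window_mean <- function(epochs, window, electrode = "Cz") {
  ci <- match(electrode, epochs$channels)
  if (is.na(ci)) stop(sprintf("electrode '%s' not present", electrode))
  idx <- which(epochs$times >= window[1] & epochs$times < window[2])
  if (!length(idx)) stop("window contains no samples")
  if (window[1] < epochs$times[1] ||
      window[2] > epochs$times[length(epochs$times)] + 1000 / epochs$sample_rate)
    stop("window lies outside the epoch")
  v <- epochs$voltages[, ci, idx, drop = FALSE]
  m <- apply(v, 1, mean)
  stats::setNames(as.numeric(m), epochs$trial_ids)
}

#' Extract the three ERP window measures per trial
#'
#' P3a (200-280 ms) and CNV (1200-1500 ms) from preparation-cue epochs,
#' and the pre-preparation measure (900-1100 ms) from incentive-cue
#' epochs, all at Cz. Epochs are baselined to the 100 ms before their
#' own epoching event first.
#'
#' @param prep_epochs preparation-cue [epoch_set()].
#' @param incentive_epochs optional incentive-cue [epoch_set()].
#' @param electrode electrode for all windows.
#' @param baselined set TRUE if the epochs are already baselined.
#' @return data.frame `trial_id`, `p3a`, `cnv` and, when incentive
#'   epochs are given, `pre_preparation`.
#' @export
erp_measures <- function(prep_epochs, incentive_epochs = NULL,
                         electrode = "Cz", baselined = FALSE) {
  if (!baselined) {
    prep_epochs <- epoch_and_baseline(
      prep_epochs, c(prep_epochs$times[1], 1500))
  }
  out <- data.frame(trial_id = prep_epochs$trial_ids,
                    p3a = unname(window_mean(prep_epochs, c(200, 280), electrode)),
                    cnv = unname(window_mean(prep_epochs, c(1200, 1500), electrode)),
                    stringsAsFactors = FALSE)
  if (!is.null(incentive_epochs)) {
    if (!baselined) {
      incentive_epochs <- epoch_and_baseline(
        incentive_epochs, c(incentive_epochs$times[1], 1100))
    }
    pp <- window_mean(incentive_epochs, c(900, 1100), electrode)
    out$pre_preparation <- unname(pp[match(out$trial_id, names(pp))])
  }
  out
}

#' Per-participant condition difference waves
#'
#' For each participant, the mean ERP of the higher factor level minus
#' the lower (50p - 0p; THP - placebo), channels x time; optionally the
#' difference-of-differences across a second factor (interaction wave).
#'
#' @param epochs an [epoch_set()].
#' @param data trial table with `trial_id`, `participant` and factor
#'   columns.
#' @param factor factor column name.
#' @param interaction_of optional second factor for the
#'   difference-of-differences.
#' @return list: `diff` (participants x channels x samples array),
#'   `participants`, `channels`, `times`.
#' @export
difference_waves <- function(epochs, data, factor,
                             interaction_of = NULL) {
  m <- match(epochs$trial_ids, data$trial_id)
  if (anyNA(m)) stop("epochs contain trials absent from the table")
  d <- data[m, , drop = FALSE]
  f <- d[[factor]]
  lev <- sort(unique(f))
  if (length(lev) != 2) stop("factor must have two levels")
  parts <- sort(unique(d$participant))
  nd <- dim(epochs$voltages)
  cond_mean <- function(sel) {
    if (!any(sel)) return(NULL)
    apply(epochs$voltages[sel, , , drop = FALSE], c(2, 3), mean)
  }
  res <- list()
  kept <- character()
  for (p in parts) {
    if (is.null(interaction_of)) {
      hi <- cond_mean(d$participant == p & f == lev[2])
      lo <- cond_mean(d$participant == p & f == lev[1])
      if (is.null(hi) || is.null(lo)) {
        message(sprintf("participant %s missing a level of %s; dropped", p, factor))
        next
      }
      res[[p]] <- hi - lo
    } else {
      g <- d[[interaction_of]]
      glev <- sort(unique(g))
      ms <- lapply(list(c(2, 2), c(2, 1), c(1, 2), c(1, 1)), function(ij)
        cond_mean(d$participant == p & f == lev[ij[1]] & g == glev[ij[2]]))
      if (any(vapply(ms, is.null, TRUE))) {
        message(sprintf("participant %s missing a cell; dropped", p))
        next
      }
      res[[p]] <- (ms[[1]] - ms[[3]]) - (ms[[2]] - ms[[4]])
    }
    kept <- c(kept, p)
  }
  if (!length(res)) stop("no participant has both factor levels")
  arr <- array(0, dim = c(length(res), nd[2], nd[3]))
  for (i in seq_along(res)) arr[i, , ] <- res[[i]]
  list(diff = arr, participants = kept, channels = epochs$channels,
       times = epochs$times)
}
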