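## Plain-text file formats: trial-table CSV, an EyeLink-ASC-like eye
## trace dialect, and a binary float32 epochs container with a JSON
## sidecar. Units are stated once in the sidecar: ms, degrees, uV.

#' Write / read the trial table CSV
#' @param trials trial table.
#' @param path file path.
#' @return `read_trial_table` returns the data.frame.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write eye traces in the ASC-like text dialect
#'
#' One block per trial: `MSG` lines carry the trial id, factors and
#' geometry; sample lines are `t<TAB>x<TAB>y` (ms, deg) with `.` for
#' both coordinates where tracking was lost; `END` closes the trial.
#' Time 0 is target onset.
#'
#' @param traces named list of traces (see [generate_eye_traces()]).
#' @param trials matching trial-table rows (factor metadata for the MSG
#'   lines).
#' @param path output file.
#' @export
write_eye_traces <- function(traces, trials, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(traces)) {
    tr <- traces[[id]]
    row <- trials[trials$trial_id == id, , drop = FALSE]
    geom <- attr(tr, "geometry")
    writeLines(sprintf(
      "MSG\t0\tTRIALID %s PARTICIPANT %s SESSION %d INCENTIVE %d DISTRACTOR %d",
      id, row$participant, row$session, row$incentive, row$distractor), con)
    writeLines(sprintf(
      "MSG\t0\tGEOM FIX %.4f %.4f TARG %.4f %.4f DIST %.4f %.4f",
      geom$fixation[1], geom$fixation[2], geom$target[1], geom$target[2],
      geom$distractor[1], geom$distractor[2]), con)
    writeLines("MSG\t0\tTARGET_ONSET", con)
    ok <- tr$valid
    lines <- ifelse(ok,
                    sprintf("%.1f\t%.6f\t%.6f", tr$t, tr$x, tr$y),
                    sprintf("%.1f\t.\t.", tr$t))
    writeLines(lines, con)
    writeLines("END", con)
  }
  invisible(path)
}

#' Read eye traces from the ASC-like dialect
#'
#' @param path file written by [write_eye_traces()].
#' @return named list of traces (data.frames `t`, `x`, `y`, `valid`)
#'   with `geometry` and `meta` attributes. Malformed sample lines raise
#'   an error naming the line number; trials without a TARGET_ONSET
#'   message are skipped with a message.
#' @export
read_eye_traces <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  meta <- NULL
  geom <- NULL
  has_onset <- FALSE
  start_line <- NA_integer_
  flush <- function() {
    if (is.null(cur)) return()
    if (!has_onset) {
      message(sprintf(
        "trial starting at line %d has no TARGET_ONSET message; skipped",
        start_line))
      return()
    }
    tra <- do.call(rbind, cur)
    tra <- data.frame(t = tra[, 1], x = tra[, 2], y = tra[, 3],
                      valid = !is.na(tra[, 2]))
    attr(tra, "geometry") <- geom
    attr(tra, "meta") <- meta
    out[[meta$trial_id]] <<- tra
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line)) next
    if (startsWith(line, "MSG")) {
      parts <- strsplit(line, "\t")[[1]]
      body <- parts[length(parts)]
      if (startsWith(body, "TRIALID")) {
        flush()
        tok <- strsplit(body, " +")[[1]]
        meta <- list(trial_id = tok[2],
                     participant = tok[4],
                     session = as.integer(tok[6]),
                     incentive = as.integer(tok[8]),
                     distractor = as.integer(tok[10]))
        cur <- list()
        geom <- NULL
        has_onset <- FALSE
        start_line <- ln
      } else if (startsWith(body, "GEOM")) {
        tok <- as.numeric(strsplit(body, " +")[[1]][c(3, 4, 6, 7, 9, 10)])
        geom <- list(fixation = tok[1:2], target = tok[3:4],
                     distractor = tok[5:6])
      } else if (startsWith(body, "TARGET_ONSET")) {
        has_onset <- TRUE
      }
      next
    }
    if (identical(line, "END")) next
    tok <- strsplit(line, "\t")[[1]]
    if (length(tok) != 3)
      stop(sprintf("malformed sample line %d: '%s'", ln, line))
    tval <- suppressWarnings(as.numeric(tok[1]))
    if (is.na(tval))
      stop(sprintf("malformed sample line %d: '%s'", ln, line))
    xy <- suppressWarnings(as.numeric(tok[2:3]))
    if (any(is.na(xy)) && !all(tok[2:3] == "."))
      stop(sprintf("malformed sample line %d: '%s'", ln, line))
    cur[[length(cur) + 1L]] <- c(tval, xy)
  }
  flush()
  out
}

#' Write / read the binary epochs container
#'
#' Voltages are stored as little-endian 32-bit floats in sample-fastest
#' order (`<stem>.dat`); metadata (channel labels, positions, sample
#' rate, times, epoching event, trial ids, units, endianness) go to the
#' JSON sidecar (`<stem>.json`). The round trip is bit-exact at float32
#' precision.
#'
#' @param epochs an [epoch_set()].
#' @param stem path without extension.
#' @return `read_epochs` returns the [epoch_set()].
#' @export
write_epochs <- function(epochs, stem) {
  v <- aperm(epochs$voltages, c(3, 2, 1))   # sample, channel, trial
  con <- file(paste0(stem, ".dat"), "wb")
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  close(con)
  meta <- list(shape = dim(epochs$voltages),
               order = "trial_channel_sample",
               dtype = "float32", endian = "little",
               channel_labels = epochs$channels,
               positions = epochs$positions,
               sample_rate = epochs$sample_rate,
               time_of_first_sample = epochs$times[1],
               times = epochs$times,
               t0_event = epochs$t0_event,
               trial_ids = epochs$trial_ids,
               units = list(time = "ms", voltage = "uV", position = "deg"))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  jf <- paste0(stem, ".json")
  df <- paste0(stem, ".dat")
  if (!file.exists(jf) || !file.exists(df))
    stop(sprintf("missing epochs container at %s(.dat/.json)", stem))
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(df, "rb")
  raw <- readBin(con, numeric(), n = n + 1L, size = 4,
                 endian = meta$endian %||% "little")
  close(con)
  if (length(raw) != n)
    stop(sprintf("epochs array shape %s inconsistent with %d stored values",
                 paste(shape, collapse = "x"), length(raw)))
  v <- aperm(array(raw, dim = rev(shape)), c(3, 2, 1))
  pos <- if (!is.null(meta$positions)) as.matrix(meta$positions) else NULL
  epoch_set(v, meta$channel_labels, pos, meta$sample_rate,
            as.numeric(meta$times), meta$t0_event, meta$trial_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
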