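# Plain-text I/O: kinematic and EMG CSV with JSON sidecars, segment export.

#' Read a kinematic CSV file
#'
#' Two layouts are accepted: joint angles with header
#' `time,q0,...,q7` (degrees), or marker trajectories with columns
#' `time,<name>_x,<name>_y,<name>_z` (meters) for each named landmark. A JSON
#' sidecar `<path>.json` may declare `rate_hz` and `units`; otherwise the rate
#' is inferred from the time column.
#'
#' @param path CSV file path.
#' @return list with `time`, `rate`, and either `q` (n x 8 matrix, degrees) or
#'   `markers` (named list of n x 3 matrices), plus `meta` from the sidecar.
#' @export
read_kinematics_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("kinematic CSV must have a 'time' column")
  time <- df$time
  dt <- diff(time)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * mean(dt))
    stop("non-uniform timestamps in ", path, ": resample before loading")
  meta <- read_sidecar(path)
  rate <- meta$rate_hz %||% (1 / mean(dt))
  out <- list(time = time, rate = rate, meta = meta)
  qcols <- paste0("q", 0:7)
  if (all(qcols %in% names(df))) out$q <- as.matrix(df[qcols])
  xcols <- grep("_x$", names(df), value = TRUE)
  if (length(xcols)) {
    out$markers <- lapply(sub("_x$", "", xcols), function(nm) {
      as.matrix(df[paste0(nm, c("_x", "_y", "_z"))])
    })
    names(out$markers) <- sub("_x$", "", xcols)
  }
  if (is.null(out$q) && is.null(out$markers))
    stop("no q0..q7 columns and no <marker>_x columns in ", path)
  out
}

read_sidecar <- function(path) {
  side <- paste0(path, ".json")
  if (file.exists(side)) jsonlite::fromJSON(side) else list()
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

#' Write kinematic data as CSV (with JSON sidecar)
#'
#' @param time Time vector (s).
#' @param path Output CSV path.
#' @param q Optional n x 8 joint-angle matrix (degrees).
#' @param markers Optional named list of n x 3 marker matrices (meters).
#' @param rate Sampling rate recorded in the sidecar.
#' @export
write_kinematics_csv <- function(time, path, q = NULL, markers = NULL,
                                 rate = 1 / mean(diff(time))) {
  df <- data.frame(time = time)
  if (!is.null(q)) {
    q <- as.matrix(q)
    colnames(q) <- paste0("q", 0:7)
    df <- cbind(df, q)
  }
  for (nm in names(markers)) {
    m <- markers[[nm]]
    colnames(m) <- paste0(nm, c("_x", "_y", "_z"))
    df <- cbind(df, m)
  }
  utils::write.csv(df, path, row.names = FALSE)
  write_sidecar(path, list(rate_hz = rate,
                           units = list(time = "s", angles = "deg", positions = "m")))
  invisible(path)
}

#' Read a multi-channel surface-EMG CSV
#'
#' Channel-per-column layout with a `time` column and one column per muscle
#' (SENIAM names from [target_muscles()]); amplitudes in mV. A JSON sidecar may
#' declare `rate_hz` and `go_cue_s`.
#'
#' @param path CSV file path.
#' @return [emg_recording()] object.
#' @export
read_emg_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("EMG CSV must have a 'time' column")
  meta <- read_sidecar(path)
  rate <- meta$rate_hz %||% (1 / mean(diff(df$time)))
  chans <- setdiff(names(df), "time")
  emg_recording(as.matrix(df[chans]), rate = rate,
                go_cue_s = meta$go_cue_s %||% numeric(0))
}

#' Write an EMG recording as CSV (with JSON sidecar)
#' @param rec [emg_recording()].
#' @param path Output CSV path.
#' @export
write_emg_csv <- function(rec, path) {
  df <- data.frame(time = seq_len(nrow(rec$data)) / rec$rate - 1 / rec$rate)
  df <- cbind(df, as.data.frame(rec$data))
  utils::write.csv(df, path, row.names = FALSE)
  write_sidecar(path, list(rate_hz = rec$rate, units = "mV",
                           go_cue_s = rec$go_cue_s))
  invisible(path)
}

#' Export primitive segments as TSV or JSON
#'
#' The TSV layout is interval-style: `trial_id`, `start_s`, `end_s`,
#' `primitive`, `waypoint_from`, `waypoint_to`, `reached`.
#'
#' @param segments Segment data.frame from [segment_trial()].
#' @param path Output path (`.tsv` or `.json` by `format`).
#' @param trial_id Identifier written into each row.
#' @param format "tsv" or "json".
#' @export
write_segments <- function(segments, path, trial_id = "trial", format = c("tsv", "json")) {
  format <- match.arg(format)
  out <- cbind(trial_id = trial_id,
               segments[c("start_s", "end_s", "primitive",
                          "waypoint_from", "waypoint_to", "reached")])
  if (format == "tsv") {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
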