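# End-to-end benchmark pipeline: validate -> segment -> compute -> report,
# with a run manifest for reproducibility.

#' Run the full benchmark on a worksheet and recorded data
#'
#' Executes the protocol analysis in order: worksheet validation and echo,
#' target-layout construction, per-repetition trunk-validity check,
#' primitive segmentation, kinematic (and, when declared, EMG) indicator
#' computation, and report generation. A run manifest records input file
#' hashes, every tunable constant used, the package version and per-stage
#' timings.
#'
#' @param worksheet Path to a worksheet document or an [load_worksheet()]
#'   result.
#' @param kin_paths Character vector of kinematic CSV paths, one repetition
#'   each (marker layout with `end_effector` and `trunk`, and optionally
#'   q0..q7 columns).
#' @param emg_paths Optional EMG CSV paths matching `kin_paths`.
#' @param shoulder_height_m Shoulder height above the desk.
#' @param out_dir Optional directory for `report.json`, `report.txt`,
#'   `manifest.json` and per-repetition segment TSVs.
#' @param constants Tunable constants (see [default_constants()]).
#' @return list with `report` ([generate_report()]), `manifest`, and
#'   `repetitions` (per-repetition segments/validity/indicator tables).
#'   Mandatory indicators missing for a declared domain are reported in
#'   `report$missing_mandatory`; callers treating this as fatal should check
#'   it (the CLI exits nonzero).
#' @export
run_benchmark <- function(worksheet, kin_paths, emg_paths = NULL,
                          shoulder_height_m = 0.30, out_dir = NULL,
                          constants = default_constants()) {
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }
  ws <- stage("validate", if (inherits(worksheet, "ulb_worksheet")) worksheet
              else load_worksheet(worksheet))
  if ("emg" %in% ws$outcomes && is.null(emg_paths))
    stop("the worksheet declares the EMG outcome domain but no EMG files were given")
  geom <- worksheet_geometry(ws)
  mode <- if (grepl("shoulder_height", ws$skills[[1]]$name)) "shoulder_height"
          else "rest_height"
  layout <- stage("layout", build_target_layout(geom, shoulder_height_m, mode))
  skill <- ws$skills[[1]]$name
  reps <- stage("analyze", lapply(seq_along(kin_paths), function(r) {
    kin <- read_kinematics_csv(kin_paths[r])
    if (geom$evaluated_arm == "left") {
      # mirror about the sagittal plane so all indicators are side-agnostic
      kin$markers <- lapply(kin$markers, function(m) {
        m[, 3] <- -m[, 3]
        m
      })
    }
    pos <- kin$markers$end_effector
    if (is.null(pos)) stop("kinematic file ", kin_paths[r],
                           " lacks an end_effector marker")
    trial <- list(time = kin$time, rate = kin$rate, position = pos,
                  q = kin$q, trunk = kin$markers$trunk,
                  go_cue_s = kin$meta$go_cue_s %||% 0,
                  skill = skill, layout = layout, geom = geom)
    validity <- if (is.null(trial$trunk)) check_validity(NULL, NULL,
                  threshold_deg = constants$trunk_validity_threshold_deg)
      else {
        ta <- trunk_angle(trial$trunk, base = c(0, shoulder_height_m - 0.45, 0))
        check_validity(ta$sagittal_deg, ta$frontal_deg,
                       threshold_deg = constants$trunk_validity_threshold_deg)
      }
    segments <- segment_trial(
      trial, skill, layout,
      threshold_fraction = constants$onset_threshold_fraction,
      stability_threshold_s = constants$stability_threshold_s,
      capture_radius_m = constants$capture_radius_m,
      cutoff_hz = constants$kin_lowpass_hz)
    kin_pis <- compute_kin_pis(trial, segments, geom,
                               cutoff_hz = constants$kin_lowpass_hz)
    emg_pis <- NULL
    if (!is.null(emg_paths)) {
      rec <- read_emg_csv(emg_paths[r])
      cond <- condition_emg(rec, band = constants$emg_band_hz,
                            envelope_cutoff_hz = constants$emg_envelope_hz)
      emg_pis <- compute_emg_pis(cond, go_cue_s = trial$go_cue_s,
                                 agonist = ws$setup$agonist %||% "biceps_brachii",
                                 antagonist = ws$setup$antagonist %||% "triceps_brachii")
    }
    list(skill = skill, segments = segments, validity = validity,
         kin_pis = kin_pis, emg_pis = emg_pis)
  }))
  report <- stage("report", generate_report(ws, layout, reps, constants))
  inputs <- c(kin_paths, emg_paths)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ulbench")),
    input_hashes = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    constants = constants,
    stage_timings_s = timings,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (r in seq_along(reps))
      write_segments(reps[[r]]$segments,
                     file.path(out_dir, sprintf("rep%02d_segments.tsv", r)),
                     trial_id = sprintf("rep%02d", r))
  }
  list(report = report, manifest = manifest, repetitions = reps)
}
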