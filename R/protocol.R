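# The benchmarking worksheet as a validated configuration schema, the A-E
# target layout, performance-indicator selection and the benchmark report.

#' The eight robot training modalities accepted by the worksheet
#'
#' Patient-in-charge, transparent and resistive modes leave the arm's weight
#' to the user (gravity environment); the remaining modes provide assistance
#' or guidance and imply micro-gravity.
#' @return character vector of length 8.
#' @export
training_modalities <- function() {
  c("patient_in_charge", "robot_in_charge", "transparent", "resistive",
    "assistive", "corrective", "path_guidance", "error_augmentation")
}

worksheet_skill_names <- function() {
  c(motor_skills(), "hand_to_mouth")  # worksheet form lists hand-to-mouth undivided
}

#' Load and validate a benchmarking worksheet
#'
#' Reads a JSON or YAML worksheet document, applies defaults (8 repetitions,
#' the 0.5 l cylinder object with zero payload, no disturbance, kinematics
#' outcome domain) and validates every range and enumeration with field-path
#' error messages: actuated-DOF assistance in [-1, 1], passive-DOF gravity
#' compensation in [0, 1], the eight-member training-modality enumeration,
#' seatback angle (when given) in [100, 110] degrees, repetitions >= 1. The
#' worksheet form lists "hand_to_mouth" undivided; the loader expands it into
#' the with/without-object variants via the skill's `object_present` flag.
#'
#' @param document File path (`.json`, `.yaml`/`.yml`) or an R list.
#' @return Object of class `ulb_worksheet`.
#' @export
load_worksheet <- function(document) {
  ws <- if (is.character(document)) {
    ext <- tolower(tools::file_ext(document))
    if (ext %in% c("yaml", "yml")) yaml::read_yaml(document)
    else jsonlite::fromJSON(document, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else document
  errs <- character(0)
  bad <- function(path, msg) errs <<- c(errs, paste0(path, ": ", msg))

  ws$system <- ws$system %||% "subject_only"
  if (!ws$system %in% c("subject_only", "subject_plus_robot"))
    bad("system", "must be 'subject_only' or 'subject_plus_robot'")

  subj <- ws$subject %||% list()
  for (f in c("upper_arm_cm", "forearm_cm"))
    if (!is.null(subj[[f]]) && (!is.numeric(subj[[f]]) || subj[[f]] <= 0))
      bad(paste0("subject.", f), "must be a positive length in cm")
  subj$dominant_arm <- subj$dominant_arm %||% "right"
  subj$evaluated_arm <- subj$evaluated_arm %||% "right"
  for (f in c("dominant_arm", "evaluated_arm"))
    if (!subj[[f]] %in% c("left", "right"))
      bad(paste0("subject.", f), "must be 'left' or 'right'")
  ws$subject <- subj

  if (identical(ws$system, "subject_plus_robot") || !is.null(ws$robot)) {
    rb <- ws$robot %||% list()
    if (is.null(rb$training_modality))
      bad("robot.training_modality", "required when a robot is present")
    else if (!rb$training_modality %in% training_modalities())
      bad("robot.training_modality",
          paste0("must be one of: ", paste(training_modalities(), collapse = ", ")))
    for (i in seq_along(rb$actuated_dofs)) {
      lv <- rb$actuated_dofs[[i]]$level
      if (is.null(lv) || !is.numeric(lv) || lv < -1 || lv > 1)
        bad(sprintf("robot.actuated_dofs[%d].level", i),
            "assistance level must be in [-1, 1]")
    }
    for (i in seq_along(rb$passive_dofs)) {
      cp <- rb$passive_dofs[[i]]$compensation
      if (is.null(cp) || !is.numeric(cp) || cp < 0 || cp > 1)
        bad(sprintf("robot.passive_dofs[%d].compensation", i),
            "gravity compensation must be in [0, 1]")
    }
    ws$robot <- rb
  }

  if (!is.null(ws$seatback_deg) &&
      (ws$seatback_deg < 100 || ws$seatback_deg > 110))
    bad("seatback_deg", "seatback tilt must be in [100, 110] degrees")

  skills <- ws$skills %||% list(list(name = "anterior_reaching_rest_height"))
  expanded <- list()
  for (i in seq_along(skills)) {
    sk <- skills[[i]]
    if (is.character(sk)) sk <- list(name = sk)
    sk$repetitions <- sk$repetitions %||% 8L
    if (!is.numeric(sk$repetitions) || sk$repetitions < 1)
      bad(sprintf("skills[%d].repetitions", i), "must be >= 1 (default 8)")
    if (identical(sk$name, "hand_to_mouth")) {
      sk$name <- if (isTRUE(sk$object_present)) "hand_to_mouth_with_object"
                 else "hand_to_mouth_without_object"
    }
    if (!sk$name %in% motor_skills())
      bad(sprintf("skills[%d].name", i),
          paste0("must be one of: ", paste(worksheet_skill_names(), collapse = ", ")))
    expanded[[i]] <- sk[c("name", "repetitions")]
  }
  ws$skills <- expanded

  obj <- ws$object %||% list()
  obj$shape <- obj$shape %||% "cylinder"
  obj$volume_l <- obj$volume_l %||% 0.5
  obj$payload_kg <- obj$payload_kg %||% 0
  ws$object <- obj

  ws$disturbance <- validate_disturbance(ws$disturbance %||% list(kind = "none"),
                                         bad)
  ws$outcomes <- ws$outcomes %||% "kinematics"
  if (!all(ws$outcomes %in% c("kinematics", "emg")))
    bad("outcomes", "outcome domains must be among 'kinematics', 'emg'")

  setup <- ws$setup %||% list()
  if ("emg" %in% ws$outcomes) {
    setup$muscles <- setup$muscles %||% target_muscles()
    unknown <- setdiff(setup$muscles, target_muscles())
    if (length(unknown))
      bad("setup.muscles", paste0("unknown muscle(s): ",
                                  paste(unknown, collapse = ", ")))
    setup$agonist <- setup$agonist %||% "biceps_brachii"
    setup$antagonist <- setup$antagonist %||% "triceps_brachii"
  }
  ws$setup <- setup

  if (length(errs))
    stop("invalid worksheet:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  structure(ws, class = "ulb_worksheet")
}

validate_disturbance <- function(d, bad) {
  kinds <- c("none", "payload", "cognitive", "motor_perturbation", "other")
  d$kind <- d$kind %||% "none"
  if (!d$kind %in% kinds) {
    bad("disturbance.kind", paste0("must be one of: ", paste(kinds, collapse = ", ")))
    return(d)
  }
  # a declared disturbance must be quantitatively specified before the protocol
  if (d$kind == "payload" &&
      (is.null(d$payload_kg) || !is.numeric(d$payload_kg) || d$payload_kg <= 0))
    bad("disturbance.payload_kg", "payload mass (kg) must be specified and > 0")
  if (d$kind == "motor_perturbation") {
    for (f in c("direction", "magnitude", "frequency_hz"))
      if (is.null(d[[f]])) bad(paste0("disturbance.", f),
                               "motor perturbation must be quantitatively specified")
  }
  if (d$kind %in% c("cognitive", "other") &&
      (is.null(d$description) || !nzchar(d$description)))
    bad("disturbance.description", "must be specified for this disturbance kind")
  d
}

#' Disturbance specification helper
#' @param kind One of none, payload, cognitive, motor_perturbation, other.
#' @param ... Kind-specific parameters (`payload_kg`; `direction`,
#'   `magnitude`, `frequency_hz`, `waveform`; `description`).
#' @return validated disturbance list.
#' @export
disturbance_spec <- function(kind = "none", ...) {
  errs <- character(0)
  d <- validate_disturbance(c(list(kind = kind), list(...)),
                            function(path, msg) errs <<- c(errs, paste0(path, ": ", msg)))
  if (length(errs)) stop("invalid disturbance:\n  ", paste(errs, collapse = "\n  "),
                         call. = FALSE)
  d
}

#' @export
print.ulb_worksheet <- function(x, ...) {
  cat("Benchmarking worksheet\n")
  cat("  system:", x$system, "\n")
  if (!is.null(x$robot))
    cat("  robot modality:", x$robot$training_modality, "\n")
  cat("  skills:", paste(vapply(x$skills, function(s)
    sprintf("%s (n=%d)", s$name, as.integer(s$repetitions)), character(1)),
    collapse = "; "), "\n")
  cat("  outcomes:", paste(x$outcomes, collapse = ", "),
      "| disturbance:", x$disturbance$kind, "\n")
  invisible(x)
}

#' Write a worksheet back to JSON
#' @param ws [load_worksheet()] result.
#' @param path Output path.
#' @export
write_worksheet <- function(ws, path) {
  jsonlite::write_json(unclass(ws), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Geometry from a worksheet's subject section
#' @param ws [load_worksheet()] result with `subject$upper_arm_cm`,
#'   `subject$forearm_cm`.
#' @return [arm_geometry()] (lengths converted to meters).
#' @export
worksheet_geometry <- function(ws) {
  s <- ws$subject
  if (is.null(s$upper_arm_cm) || is.null(s$forearm_cm))
    stop("worksheet subject must declare upper_arm_cm and forearm_cm")
  arm_geometry(s$upper_arm_cm / 100, s$forearm_cm / 100,
               dominant_arm = s$dominant_arm, evaluated_arm = s$evaluated_arm)
}

#' Build the A-E target layout
#'
#' Ground frame: origin at the rest position A (hand on the desk, aligned with
#' the navel), X anterior, Y up, Z lateral toward the evaluated side. Targets
#' B (central), C (contralateral, rotated 45 degrees toward the midline) and D
#' (ipsilateral, 45 degrees lateral) are placed at the horizontal distance
#' corresponding to complete elbow extension at the target height:
#' `r = sqrt(arm_length^2 - h^2)` with `h` the vertical drop from the shoulder
#' to the target height (`h = 0` in shoulder-height mode, so `r` equals the
#' arm length). The 45-degree angles hold exactly in the horizontal plane.
#' The mouth point E defaults to 0.15 m anterior of and 0.25 m above the
#' sternal notch (taken at shoulder height above A).
#'
#' @param geom [arm_geometry()].
#' @param shoulder_height_m Shoulder height above the desk surface.
#' @param mode "rest_height" or "shoulder_height".
#' @param mouth_offset_m c(anterior, up) offset of E from the sternal notch.
#' @param object_offset_m Anterior offset of the graspable object from A for
#'   the drinking task.
#' @return Object of class `ulb_layout`: list with `points` (named list of
#'   3-vectors A-E), `reach_m`, `mode`.
#' @export
#' @examples
#' g <- arm_geometry(0.30, 0.25)
#' build_target_layout(g, 0.30)$reach_m  # sqrt(0.55^2 - 0.30^2)
build_target_layout <- function(geom, shoulder_height_m,
                                mode = c("rest_height", "shoulder_height"),
                                mouth_offset_m = c(0.15, 0.25),
                                object_offset_m = 0.06) {
  mode <- match.arg(mode)
  L <- geom$arm_length_m
  h <- if (mode == "rest_height") shoulder_height_m else 0
  if (h >= L)
    stop("infeasible layout: vertical drop ", h,
         " m is not smaller than arm length ", L, " m")
  r <- sqrt(L^2 - h^2)
  y_t <- if (mode == "rest_height") 0 else shoulder_height_m
  ang <- pi / 4
  # contralateral = toward the midline (-Z for a right-arm ground frame)
  pts <- list(
    A = c(0, 0, 0),
    B = c(r, y_t, 0),
    C = c(r * cos(ang), y_t, -r * sin(ang)),
    D = c(r * cos(ang), y_t, r * sin(ang)),
    E = c(mouth_offset_m[1], shoulder_height_m + mouth_offset_m[2], 0)
  )
  structure(list(points = pts, reach_m = r, mode = mode,
                 shoulder_height_m = shoulder_height_m,
                 object_offset_m = object_offset_m,
                 evaluated_arm = geom$evaluated_arm),
            class = "ulb_layout")
}

#' @export
print.ulb_layout <- function(x, ...) {
  cat(sprintf("Target layout (%s): reach %.4f m\n", x$mode, x$reach_m))
  for (nm in names(x$points))
    cat(sprintf("  %s: (%.3f, %.3f, %.3f)\n", nm, x$points[[nm]][1],
                x$points[[nm]][2], x$points[[nm]][3]))
  invisible(x)
}

#' Select the performance indicators implied by a worksheet
#'
#' Filters the registry by the worksheet's declared outcome domains and the
#' requested abilities; mandatory descriptors are always retained whenever
#' their domain is declared.
#'
#' @param ws [load_worksheet()] result.
#' @param abilities Optional subset of ability names.
#' @param mandatory_only Keep only mandatory descriptors.
#' @return Registry data.frame subset, in registry order.
#' @export
select_pis <- function(ws, abilities = NULL, mandatory_only = FALSE) {
  reg <- pi_registry()
  domains <- ws$outcomes
  if ("emg" %in% domains && is.null(ws$setup$muscles))
    stop("EMG indicators requested but the worksheet declares no EMG set-up")
  sel <- reg[reg$domain %in% domains, , drop = FALSE]
  if (!is.null(abilities)) {
    unknown <- setdiff(abilities, motor_abilities()$name)
    if (length(unknown))
      stop("unknown ability name(s): ", paste(unknown, collapse = ", "))
    missing <- setdiff(abilities, unique(sel$ability))
    if (length(missing))
      stop("configuration error: ability '", paste(missing, collapse = ", "),
           "' has no indicator in the declared outcome domain(s) (",
           paste(domains, collapse = ", "), ")")
    sel <- sel[sel$ability %in% abilities, , drop = FALSE]
  }
  if (mandatory_only) sel <- sel[sel$status == "mandatory", , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Generate the benchmark report for a set of repetitions
#'
#' Aggregates per-repetition performance indicators into per-skill
#' mean +/- SD tables, excluding repetitions that fail the trunk-validity
#' rule, and echoes the worksheet, the environment/function classification and
#' every tunable constant used. Mandatory indicators that could not be
#' computed are listed in a warning block.
#'
#' @param worksheet [load_worksheet()] result.
#' @param layout [build_target_layout()] result.
#' @param repetitions List of per-repetition results, each a list with
#'   `skill`, `segments`, `validity` ([check_validity()]), `kin_pis`
#'   (from [compute_kin_pis()]) and optionally `emg_pis`.
#' @param constants Named list of design constants to echo.
#' @return Object of class `ulb_report`.
#' @export
generate_report <- function(worksheet, layout, repetitions,
                            constants = default_constants()) {
  stopifnot(length(repetitions) >= 1L)
  valid <- vapply(repetitions, function(r) isTRUE(r$validity$valid), logical(1))
  excluded <- which(!valid)
  pool <- list()
  for (i in which(valid)) {
    r <- repetitions[[i]]
    kp <- r$kin_pis
    kp$repetition <- i
    kp$skill <- r$skill
    kp$domain <- "kinematics"
    kp$muscle <- NA_character_
    pool[[length(pool) + 1L]] <- kp[c("repetition", "skill", "domain", "muscle",
                                      "ability", "pi", "value", "units", "status")]
    if (!is.null(r$emg_pis)) {
      ep <- r$emg_pis
      ep$repetition <- i
      ep$skill <- r$skill
      ep$domain <- "emg"
      ep$step <- NA; ep$primitive <- NA; ep$waypoint <- NA
      pool[[length(pool) + 1L]] <- ep[c("repetition", "skill", "domain",
                                        "muscle", "ability", "pi", "value",
                                        "units", "status")]
    }
  }
  long <- do.call(rbind, pool)
  agg <- stats::aggregate(value ~ skill + domain + ability + pi + units + status,
                          data = long,
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              sd = stats::sd(v[!is.na(v)]),
                                              n = sum(!is.na(v))))
  agg <- do.call(data.frame, agg)
  names(agg) <- sub("^value\\.", "", names(agg))
  # variable error: SD of end-point error across valid repetitions
  epe <- long[long$pi == "end_point_error", , drop = FALSE]
  ve <- if (nrow(epe) >= 2L) stats::sd(epe$value) else NA_real_
  missing_mandatory <- with(agg, unique(pi[status == "mandatory" &
                                             (!is.finite(mean) | n == 0)]))
  classification <- classify_environment(worksheet)
  structure(list(
    worksheet = unclass(worksheet),
    layout = list(points = layout$points, reach_m = layout$reach_m,
                  mode = layout$mode),
    environment = classification,
    n_repetitions = length(repetitions),
    n_valid = sum(valid),
    exclusions = lapply(excluded, function(i) list(
      repetition = i, reasons = repetitions[[i]]$validity$reasons,
      max_sagittal_trunk_deg = repetitions[[i]]$validity$max_sagittal_trunk_deg,
      max_frontal_trunk_deg = repetitions[[i]]$validity$max_frontal_trunk_deg)),
    pi_table = agg,
    variable_error_m = ve,
    missing_mandatory = missing_mandatory,
    constants = constants
  ), class = "ulb_report")
}

default_constants <- function() {
  list(onset_threshold_fraction = 0.10, onset_sustain_s = 0.05,
       stability_threshold_s = 1, stillness_tol_m_s = 0.02,
       trunk_validity_threshold_deg = 20, capture_radius_m = 0.03,
       kin_lowpass_hz = 6, kin_butter_order = 4,
       emg_band_hz = c(20, 450), emg_envelope_hz = 5,
       sparc_fc_hz = 20, sparc_amplitude_threshold = 0.05,
       peak_min_separation_s = 0.10, mapr_threshold_fraction = 0.10,
       synergy_vaf_target = 0.90, repetitions_default = 8)
}

#' @export
print.ulb_report <- function(x, ...) {
  cat("Benchmark report\n")
  cat(sprintf("  environment: %s%s | repetitions: %d (%d valid)\n",
              x$environment$gravity_mode,
              if (x$environment$disturbance_present) " + disturbance" else "",
              x$n_repetitions, x$n_valid))
  if (length(x$exclusions))
    cat("  excluded repetitions:",
        paste(vapply(x$exclusions, function(e)
          sprintf("#%d (%s)", e$repetition, paste(e$reasons, collapse = ",")),
          character(1)), collapse = ", "), "\n")
  if (length(x$missing_mandatory))
    cat("  WARNING: mandatory indicator(s) not computable:",
        paste(x$missing_mandatory, collapse = ", "), "\n")
  cat(sprintf("  indicators aggregated: %d rows (mean +/- SD over valid repetitions)\n",
              nrow(x$pi_table)))
  invisible(x)
}

#' Write a report as JSON (and an optional human-readable text twin)
#' @param report [generate_report()] result.
#' @param path JSON output path.
#' @param text If TRUE, also write `<path>.txt` with the printed report.
#' @export
write_report <- function(report, path, text = TRUE) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  if (text) {
    con <- file(paste0(tools::file_path_sans_ext(path), ".txt"), "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(path)
}
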