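# Taxonomy of motor primitives, skills, abilities and the performance-indicator
# registry that every other module consumes.

#' Motor primitive registry
#'
#' The six elemental building blocks from which the protocol's functional tasks
#' are composed. Definitions follow the benchmarking scheme's primitive table.
#'
#' @return A data.frame with columns `name` and `definition` (six rows).
#' @export
#' @examples
#' motor_primitives()$name
motor_primitives <- function() {
  data.frame(
    name = c("idle", "stabilize", "point_to_point_reach", "reach_for_grasp",
             "transport", "reposition"),
    definition = c(
      "Holding the upper limb in a stable position without contact with any object",
      "Holding a target object still. There is the grasp of a target object throughout the minimal-motion",
      "Reaching a target point without contact with any object",
      "Reaching a target object and make contact with it through grasping",
      "Moving a target object in space",
      "Moving away from the target object toward the idle position, without contact with any other object"),
    stringsAsFactors = FALSE
  )
}

# Primitives that involve displacement of the end effector (vs holds).
movement_primitives <- function() {
  c("point_to_point_reach", "reach_for_grasp", "transport", "reposition")
}
hold_primitives <- function() c("idle", "stabilize")

#' Motor skill registry and primitive flows
#'
#' The six standardized motor skills of the assessment protocol, each an ordered
#' sequence of motor primitives through the A-E waypoint layout. `A` is the rest
#' position, `B`/`C`/`D` the central/contralateral/ipsilateral targets, `E` the
#' mouth.
#'
#' @param skill Optional skill name; if given, only that skill's flow is
#'   returned as a data.frame with columns `step`, `primitive`, `waypoint`.
#' @return A named list of flow data.frames, or a single flow when `skill` is
#'   given.
#' @export
#' @examples
#' nrow(motor_skill_flow("anterior_reaching_rest_height"))  # 7 steps
motor_skill_flow <- function(skill = NULL) {
  flow <- function(primitive, waypoint) {
    data.frame(step = seq_along(primitive), primitive = primitive,
               waypoint = waypoint, stringsAsFactors = FALSE)
  }
  reach_flow <- flow(
    c("idle", "point_to_point_reach", "reposition", "point_to_point_reach",
      "reposition", "point_to_point_reach", "reposition"),
    c("A", "B", "A", "C", "A", "D", "A"))
  move_flow <- flow(
    c("idle", "reach_for_grasp", "transport", "reposition",
      "idle", "reach_for_grasp", "transport", "reposition",
      "idle", "reach_for_grasp", "transport", "reposition"),
    c("A", "B", "C", "A", "A", "C", "D", "A", "A", "D", "B", "A"))
  flows <- list(
    anterior_reaching_rest_height     = reach_flow,
    anterior_reaching_shoulder_height = reach_flow,
    move_objects_rest_height          = move_flow,
    move_objects_shoulder_height      = move_flow,
    hand_to_mouth_without_object = flow(
      c("idle", "point_to_point_reach", "idle", "reposition"),
      c("A", "E", "E", "A")),
    hand_to_mouth_with_object = flow(
      c("idle", "reach_for_grasp", "transport", "stabilize", "transport",
        "reposition"),
      c("A", "A", "E", "E", "A", "A"))
  )
  if (is.null(skill)) return(flows)
  if (!skill %in% names(flows))
    stop("unknown motor skill '", skill, "'; valid skills: ",
         paste(names(flows), collapse = ", "))
  flows[[skill]]
}

#' @rdname motor_skill_flow
#' @export
motor_skills <- function() names(motor_skill_flow())

#' Motor ability registry
#'
#' The ten capacity dimensions quantified by the performance indicators,
#' with their outcome-measure domains (kinematics and/or surface EMG).
#'
#' @return data.frame with columns `name`, `description`, `kinematics`, `emg`.
#' @export
motor_abilities <- function() {
  data.frame(
    name = c("accuracy", "efficacy", "efficiency", "movement_amplitude",
             "muscular_effort", "intra_limb_coordination",
             "planning_predictability", "power", "smoothness", "speed"),
    description = c(
      "Spatial error of movements relative to optimal behavior",
      "Successful achievement of a targeted task goal",
      "Quality of how a targeted task goal is reached",
      "Maximally reachable area or volume with a specific joint and position-related aspects of single or multiple joints",
      "Muscular activation associated with the production of muscle tension while achieving a task",
      "Correlation and redundancies in upper limb joints that produce different strategies to complete the task",
      "Ability to perform goal-directed movements in a feedforward manner",
      "Ability to produce force or power while performing exercises",
      "Quality of feedforward control based on the deviation of the velocity profile to an optimal, bell-shaped velocity profile",
      "How fast movements are performed"),
    kinematics = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    emg        = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' The nine target muscles of the protocol
#'
#' Surface-EMG channel names are validated against this registry.
#' @return character vector of length 9.
#' @export
target_muscles <- function() {
  c("trapezius_descendens", "pectoralis_major", "anterior_deltoid",
    "medial_deltoid", "posterior_deltoid", "triceps_brachii",
    "biceps_brachii", "brachioradialis", "pronator_teres")
}

#' Performance-indicator registry
#'
#' Every performance indicator (PI) of the benchmarking scheme, grouped by
#' motor ability and outcome domain, with its mandatory/recommended status.
#' Exactly seven PIs are mandatory (one each for efficacy, efficiency,
#' movement amplitude, muscular effort, planning predictability, smoothness
#' and speed); accuracy, intra-limb coordination and power carry none because
#' the literature lacks evidence of a correlation with the Fugl-Meyer scale
#' strong enough to single one out.
#'
#' @return data.frame with columns `name`, `ability`, `domain`
#'   ("kinematics"/"emg"), `status` ("mandatory"/"recommended"), `description`,
#'   in registry order.
#' @export
#' @examples
#' sum(pi_registry()$status == "mandatory")  # 7
pi_registry <- function() {
  row <- function(name, ability, domain, status, description)
    data.frame(name = name, ability = ability, domain = domain, status = status,
               description = description, stringsAsFactors = FALSE)
  do.call(rbind, list(
    row("trajectory_absolute_error", "accuracy", "kinematics", "recommended",
        "Mean or maximal distance between ideal and actual trajectory between movement onset and end"),
    row("end_point_error", "accuracy", "kinematics", "recommended",
        "Euclidean distance between actual and target position at movement end"),
    row("variable_error", "accuracy", "kinematics", "recommended",
        "Standard deviation of the end-point error across repetitions of the movement"),
    row("area_index", "accuracy", "kinematics", "recommended",
        "Area between the desired straight line and the path actually performed"),
    row("success_rate", "efficacy", "kinematics", "recommended",
        "Number of accomplished objectives divided by the total number of attempts"),
    row("number_of_movement_stops", "efficacy", "kinematics", "mandatory",
        "Number of times the velocity curve dropped below a percentage of peak velocity after movement onset"),
    row("movement_time", "efficiency", "kinematics", "recommended",
        "Time from the onset to the end of a movement"),
    row("path_traveled", "efficiency", "kinematics", "recommended",
        "Path length covered between onset and end of a movement"),
    row("path_length_ratio", "efficiency", "kinematics", "mandatory",
        "Ratio between the path traveled and the shortest possible distance between movement onset and end"),
    row("trunk_compensation", "efficiency", "kinematics", "recommended",
        "Ratio between trunk displacement and hand displacement in the sagittal plane"),
    row("waveform_length", "efficiency", "emg", "recommended",
        "Cumulative length of the waveform of the EMG signal over the time segment"),
    row("average_amplitude_change", "efficiency", "emg", "recommended",
        "Mean of the cumulative waveform length of the EMG signal over the time segment"),
    row("dasdv", "efficiency", "emg", "recommended",
        "Standard deviation of the sample-to-sample amplitude change of the EMG signal"),
    row("joint_angle_correlation", "intra_limb_coordination", "kinematics", "recommended",
        "Correlation between shoulder elevation and elbow flexion/extension joint angle profiles"),
    row("elbow_peak_velocity", "intra_limb_coordination", "kinematics", "recommended",
        "Highest value of the elbow flexion/extension joint velocity profile during movement"),
    row("time_to_peak_elbow_extension", "intra_limb_coordination", "kinematics", "recommended",
        "Time to reach peak elbow extension angle, relative to the duration of the movement"),
    row("muscular_synergies", "intra_limb_coordination", "emg", "recommended",
        "Non-negative matrix factorization extracting spatial and temporal features from the EMG of the task muscles"),
    row("cocontraction_index", "intra_limb_coordination", "emg", "recommended",
        "Percentage of overlapping activity of EMG linear envelopes between agonist and antagonist muscles"),
    row("intermuscular_coherence", "intra_limb_coordination", "emg", "recommended",
        "Square of the cross-spectrum normalized by the auto-spectra of agonist and antagonist EMG"),
    row("joint_range_of_motion", "movement_amplitude", "kinematics", "mandatory",
        "Range of the anatomical joint angles between movement onset and end"),
    row("maximum_reached_distance", "movement_amplitude", "kinematics", "recommended",
        "Maximum distance reached from the starting position"),
    row("trunk_displacement", "movement_amplitude", "kinematics", "recommended",
        "Euclidean distance covered by the trunk between movement onset and end"),
    row("normalized_reaching_area", "movement_amplitude", "kinematics", "recommended",
        "Maximally reached position during a movement divided by the length of the user's arm"),
    row("integrated_emg", "muscular_effort", "emg", "recommended",
        "Summation of rectified EMG signal amplitude"),
    row("rms", "muscular_effort", "emg", "recommended",
        "Square root of the mean square of the EMG signal amplitude"),
    row("activation_level", "muscular_effort", "emg", "mandatory",
        "Average of the absolute value of the EMG signal amplitude in a segment"),
    row("variance_of_emg", "muscular_effort", "emg", "recommended",
        "Average of squared (mean-removed) EMG signal amplitude"),
    row("mean_absolute_value_slope", "muscular_effort", "emg", "recommended",
        "Differences between mean absolute values of adjacent EMG sub-segments"),
    row("time_to_peak_velocity", "planning_predictability", "kinematics", "recommended",
        "Time to reach peak velocity relative to the duration of the movement"),
    row("reaction_time", "planning_predictability", "kinematics", "mandatory",
        "Time between the go cue and the actual onset of the movement (10% of peak velocity)"),
    row("muscle_onset", "planning_predictability", "emg", "recommended",
        "Time between the go cue and the EMG onset detected by the Teager-Kaiser energy operator"),
    row("initial_movement_direction_error", "planning_predictability", "kinematics", "recommended",
        "Distance between ideal and actual trajectory at an initial time point right after movement onset"),
    row("aiming_angle", "planning_predictability", "kinematics", "recommended",
        "Angular difference between target direction and direction of travel up to the peak-speed point"),
    row("mean_frequency", "power", "emg", "recommended",
        "Power-spectrum-weighted mean frequency of the EMG signal"),
    row("median_frequency", "power", "emg", "recommended",
        "Frequency splitting the EMG power spectrum into two regions of equal power"),
    row("mean_power", "power", "emg", "recommended",
        "Average power of the power spectrum of the EMG signal"),
    row("power_spectral_density", "power", "emg", "recommended",
        "Amount of power per frequency interval of the EMG power spectrum"),
    row("frequency_ratio", "power", "emg", "recommended",
        "Ratio between low-frequency and high-frequency components of the EMG power spectrum"),
    row("power_spectrum_ratio", "power", "emg", "recommended",
        "Ratio between the energy near the spectral peak and the whole energy of the power spectrum"),
    row("number_of_velocity_peaks", "smoothness", "kinematics", "mandatory",
        "Number of maxima above a threshold in the velocity profile between movement onset and end"),
    row("speed_correlation_to_ideal", "smoothness", "kinematics", "recommended",
        "Correlation between actual speed profile and the idealized bell-shaped velocity profile"),
    row("movement_arrest_period_ratio", "smoothness", "kinematics", "recommended",
        "Proportion of time that movement speed exceeds a given percentage of peak speed"),
    row("peak_speed_ratio", "smoothness", "kinematics", "recommended",
        "Mean speed divided by the peak speed"),
    row("normalized_dimensionless_jerk", "smoothness", "kinematics", "recommended",
        "Time-integral of squared jerk normalized by movement duration^5 over movement length^2"),
    row("spectral_arc_length", "smoothness", "kinematics", "recommended",
        "Arc length of the magnitude-normalized frequency spectrum of the speed profile"),
    row("mean_acceleration", "smoothness", "kinematics", "recommended",
        "Mean value of the acceleration profile between movement onset and end"),
    row("emg_zero_crossing", "smoothness", "emg", "recommended",
        "Number of times the EMG signal amplitude crosses the zero level"),
    row("slope_sign_change", "smoothness", "emg", "recommended",
        "Number of times the slope of the EMG signal changes sign"),
    row("peak_velocity", "speed", "kinematics", "recommended",
        "Maximal value of the velocity profile between movement onset and end"),
    row("mean_velocity", "speed", "kinematics", "mandatory",
        "Mean value of the velocity profile between movement onset and end"),
    row("mean_velocity_variability", "speed", "kinematics", "recommended",
        "Difference between the participant's velocity profile and the ideal velocity profile")
  ))
}

#' Look up performance indicators for a motor ability
#'
#' @param ability One of the ten motor ability names.
#' @param mandatory_only If `TRUE`, return only the mandatory PI (may be empty:
#'   accuracy, intra-limb coordination and power have no mandatory PI).
#' @return data.frame of registry rows in registry order.
#' @export
#' @examples
#' registry_lookup("smoothness", mandatory_only = TRUE)$name
registry_lookup <- function(ability, mandatory_only = FALSE) {
  reg <- pi_registry()
  valid <- motor_abilities()$name
  if (!is.character(ability) || length(ability) != 1L || !ability %in% valid)
    stop("unknown motor ability '", ability, "'; valid abilities: ",
         paste(valid, collapse = ", "))
  out <- reg[reg$ability == ability, , drop = FALSE]
  if (mandatory_only) out <- out[out$status == "mandatory", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the function of a trial segment (stability vs transport)
#'
#' A segment counts as upper-limb *stability* when the arm location is held
#' unchanged for strictly more than `stability_threshold_s` (default 1 s, the
#' mean duration of upper-limb activities of daily living); otherwise it is
#' *transport*. Hold duration is the longest interval over which end-effector
#' speed stays below `stillness_tol` (m/s).
#'
#' @param segment A list with `position` (n x 3 matrix, m), `rate` (Hz) and
#'   optionally `object_manipulation` (logical); alternatively a single numeric
#'   hold duration in seconds.
#' @param stability_threshold_s Hold duration threshold in seconds (strict >).
#' @param stillness_tol End-effector speed tolerance in m/s defining stillness.
#' @return list with `goal` ("stability"/"transport"), `object_manipulation`,
#'   `hold_s`.
#' @export
classify_function <- function(segment, stability_threshold_s = 1,
                              stillness_tol = 0.02) {
  if (is.numeric(segment) && length(segment) == 1L) {
    hold <- segment
    object <- FALSE
  } else {
    pos <- segment$position
    if (is.null(pos) || NROW(pos) == 0L)
      stop("empty segment: no positional samples to classify")
    if (NROW(pos) < 2L) stop("segment too short to define a hold duration")
    rate <- segment$rate
    if (is.null(rate) || rate <= 0) stop("segment must carry a sampling rate")
    v <- apply(pos, 2, function(col) num_deriv(col, 1 / rate))
    speed <- sqrt(rowSums(v^2))
    still <- speed < stillness_tol
    runs <- true_runs(still)
    hold <- if (nrow(runs) == 0L) 0 else max(runs$end - runs$start) / rate
    object <- isTRUE(segment$object_manipulation)
  }
  list(goal = if (hold > stability_threshold_s) "stability" else "transport",
       object_manipulation = object,
       hold_s = hold)
}

#' Classify the task environment from a worksheet
#'
#' Without a robot (and without arm support) the environment is *gravity*.
#' With a robot it is *gravity* only under the patient-in-charge, transparent
#' or resistive training modality; any assistive or weight-supporting modality
#' yields *micro_gravity*. Any passive-DOF gravity compensation above
#' `compensation_threshold` (default 0: any compensation at all) also yields
#' *micro_gravity*, and the result is flagged.
#'
#' @param worksheet A worksheet as returned by [load_worksheet()].
#' @param compensation_threshold Gravity-compensation level above which passive
#'   support forces the micro-gravity classification.
#' @return list with `gravity_mode`, `disturbance_present`,
#'   `partial_compensation_flag` and `note`.
#' @export
classify_environment <- function(worksheet, compensation_threshold = 0) {
  disturbance <- !is.null(worksheet$disturbance) &&
    !identical(worksheet$disturbance$kind, "none")
  flag <- FALSE
  note <- NULL
  if (identical(worksheet$system, "subject_only") || is.null(worksheet$robot)) {
    mode <- "gravity"
  } else {
    robot <- worksheet$robot
    if (is.null(robot$training_modality))
      stop("configuration error: robot present but training modality missing")
    gravity_modes <- c("patient_in_charge", "transparent", "resistive")
    mode <- if (robot$training_modality %in% gravity_modes) "gravity"
            else "micro_gravity"
    comp <- vapply(robot$passive_dofs %||% list(),
                   function(d) as.numeric(d$compensation %||% 0), numeric(1))
    if (length(comp) && any(comp > compensation_threshold)) {
      if (mode == "gravity") {
        flag <- TRUE
        note <- paste0("passive gravity compensation ",
                       max(comp), " > ", compensation_threshold,
                       " forces micro_gravity")
      }
      mode <- "micro_gravity"
    }
  }
  list(gravity_mode = mode, disturbance_present = disturbance,
       partial_compensation_flag = flag, note = note)
}

#' Export the taxonomy as a machine-readable JSON registry
#'
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
taxonomy_json <- function(path = NULL) {
  tax <- list(
    motor_primitives = motor_primitives(),
    motor_skills = lapply(motor_skill_flow(), identity),
    motor_abilities = motor_abilities(),
    performance_indicators = pi_registry(),
    target_muscles = target_muscles()
  )
  js <- jsonlite::toJSON(tax, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
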