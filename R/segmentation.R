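# Movement onset/offset detection, taxonomy-driven trial segmentation into
# motor primitives, movement-stop counting and trial-validity rules.

#' Detect movement onset from a speed profile
#'
#' Onset is the first time at or after the go cue at which speed crosses
#' `threshold_fraction` x (peak speed after the go cue) upward and stays above
#' it for at least `sustain_s` (hysteresis against noise chatter). With
#' `threshold_fraction = 0` the onset degenerates to the go cue. If the
#' threshold is never crossed the outcome is "no movement detected" (a result,
#' not an error: it feeds the efficacy success rate).
#'
#' @param speed Nonnegative speed series (m/s).
#' @param rate Sampling rate (Hz).
#' @param go_cue_s Go-cue time (s, from recording start).
#' @param threshold_fraction Fraction of post-cue peak speed.
#' @param sustain_s Minimum supra-threshold dwell.
#' @param refine If `TRUE`, walk the detected crossing back to the nearest
#'   preceding speed minimum (used for segment-boundary placement).
#' @return list with `detected` (logical) and `onset_s` (NA when not detected).
#' @export
detect_onset <- function(speed, rate, go_cue_s = 0, threshold_fraction = 0.10,
                         sustain_s = 0.05, refine = FALSE) {
  stopifnot(all(speed >= 0), rate > 0)
  n <- length(speed)
  i_cue <- min(max(1L, floor(go_cue_s * rate) + 1L), n)
  if (threshold_fraction <= 0)
    return(list(detected = TRUE, onset_s = go_cue_s))
  peak <- max(speed[i_cue:n])
  thr <- threshold_fraction * peak
  if (peak <= 0 || !any(speed[i_cue:n] >= thr))
    return(list(detected = FALSE, onset_s = NA_real_))
  above <- speed >= thr
  above[seq_len(i_cue - 1L)] <- FALSE
  runs <- true_runs(above)
  need <- max(1L, round(sustain_s * rate))
  runs <- runs[(runs$end - runs$start + 1L) >= need, , drop = FALSE]
  if (!nrow(runs)) return(list(detected = FALSE, onset_s = NA_real_))
  i <- runs$start[1]
  if (refine) i <- walk_to_minimum(speed, i, -1L)
  list(detected = TRUE, onset_s = (i - 1L) / rate)
}

# Walk from index i toward direction (-1 backward, +1 forward) while speed
# keeps strictly decreasing, stopping at the nearest local minimum/plateau.
walk_to_minimum <- function(speed, i, direction) {
  n <- length(speed)
  while (i + direction >= 1L && i + direction <= n &&
         speed[i + direction] < speed[i]) {
    i <- i + direction
  }
  i
}

# Supra-threshold intervals of a speed series with two-sided hysteresis:
# drops shorter than sustain_s are bridged, bursts shorter than sustain_s
# discarded. Returns data.frame(start, end) of sample indices.
supra_threshold_intervals <- function(speed, thr, rate, sustain_s = 0.05) {
  need <- max(1L, round(sustain_s * rate))
  runs <- true_runs(speed >= thr)
  if (!nrow(runs)) return(runs)
  # bridge short gaps
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (k in 2:nrow(runs)) {
    gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
    if (gap < need) {
      merged$end[nrow(merged)] <- runs$end[k]
    } else {
      merged <- rbind(merged, runs[k, ])
    }
  }
  merged[(merged$end - merged$start + 1L) >= need, , drop = FALSE]
}

#' Segment a trial into its skill's motor-primitive sequence
#'
#' Cuts the end-effector speed profile into the ordered primitive flow of the
#' skill's template. Movement primitives are supra-threshold speed intervals
#' (10% of trial peak speed by default), with boundaries refined to the
#' nearest speed minima; sub-threshold gaps strictly longer than the stability
#' threshold (1 s) are holds and matched to idle/stabilize template entries.
#' When a movement splits into more intervals than the template expects
#' (within-movement stops), intervals separated by sub-stability gaps are
#' merged, smallest gap first. With fewer movement units than the template the
#' partial segmentation is returned with `incomplete = TRUE` (supporting
#' severely impaired users).
#'
#' @param trial A trial list with `position` (n x 3 end-effector trace, m),
#'   `rate` (Hz), and optionally `skill` and `layout`.
#' @param skill Skill name (defaults to `trial$skill`).
#' @param layout [build_target_layout()] result (defaults to `trial$layout`);
#'   used for the waypoint-arrival test.
#' @param threshold_fraction Speed threshold as a fraction of trial peak.
#' @param stability_threshold_s Hold duration separating primitives from
#'   within-movement stops (strict >, default 1 s).
#' @param capture_radius_m Waypoint capture radius for the arrival test.
#' @param sustain_s Hysteresis dwell on threshold crossings.
#' @param cutoff_hz Low-pass cutoff used when differentiating the trajectory.
#' @return Object of class `ulb_segments`: a data.frame with `step`,
#'   `primitive`, `start_s`, `end_s`, `waypoint_from`, `waypoint_to`,
#'   `reached`, and attribute `incomplete`.
#' @export
segment_trial <- function(trial, skill = trial$skill, layout = trial$layout,
                          threshold_fraction = 0.10, stability_threshold_s = 1,
                          capture_radius_m = 0.03, sustain_s = 0.05,
                          cutoff_hz = 6) {
  flow <- motor_skill_flow(skill)
  pos <- as.matrix(trial$position)
  rate <- trial$rate
  n <- nrow(pos)
  speed <- trajectory_speed(pos, rate, cutoff_hz = cutoff_hz)
  thr <- threshold_fraction * max(speed)
  iv <- supra_threshold_intervals(speed, thr, rate, sustain_s)
  m_steps <- which(flow$primitive %in% movement_primitives())
  m_total <- length(m_steps)
  # merge intervals separated by sub-stability gaps until the count matches
  while (nrow(iv) > m_total) {
    gaps <- (iv$start[-1] - iv$end[-nrow(iv)] - 1L) / rate
    mergeable <- which(gaps <= stability_threshold_s)
    k <- if (length(mergeable)) mergeable[which.min(gaps[mergeable])]
         else which.min(gaps)
    iv$end[k] <- iv$end[k + 1L]
    iv <- iv[-(k + 1L), , drop = FALSE]
  }
  incomplete <- nrow(iv) < m_total
  # refine movement boundaries to the nearest speed minima
  if (nrow(iv)) {
    iv$start <- vapply(iv$start, function(i) walk_to_minimum(speed, i, -1L), integer(1))
    iv$end <- vapply(iv$end, function(i) walk_to_minimum(speed, i, +1L), integer(1))
  }
  n_steps <- if (incomplete) {
    # keep template steps up to (and including holds before) the last detected movement
    if (nrow(iv) == 0L) 0L else m_steps[nrow(iv)]
  } else nrow(flow)
  segs <- flow[seq_len(n_steps), , drop = FALSE]
  start_s <- end_s <- rep(NA_real_, n_steps)
  mi <- 0L
  for (s in seq_len(n_steps)) {
    if (flow$primitive[s] %in% movement_primitives()) {
      mi <- mi + 1L
      start_s[s] <- (iv$start[mi] - 1L) / rate
      end_s[s] <- (iv$end[mi] - 1L) / rate
    }
  }
  # holds fill the span between neighboring movements (or recording edges)
  for (s in seq_len(n_steps)) {
    if (flow$primitive[s] %in% hold_primitives()) {
      start_s[s] <- if (s == 1L) 0 else end_s[s - 1L]
      end_s[s] <- if (s < n_steps) start_s[s + 1L] else (n - 1L) / rate
    }
  }
  waypoint_to <- segs$waypoint
  waypoint_from <- c("A", utils::head(waypoint_to, -1L))
  reached <- rep(NA, n_steps)
  if (!is.null(layout)) {
    for (s in seq_len(n_steps)) {
      tgt <- step_target(segs$primitive[s], segs$waypoint[s], layout)
      if (is.null(tgt) || is.na(end_s[s])) next
      p_end <- pos[min(n, round(end_s[s] * rate) + 1L), ]
      reached[s] <- vnorm(p_end - tgt) <= capture_radius_m
    }
  }
  out <- data.frame(step = segs$step, primitive = segs$primitive,
                    start_s = start_s, end_s = end_s,
                    waypoint_from = waypoint_from, waypoint_to = waypoint_to,
                    reached = reached, stringsAsFactors = FALSE)
  structure(out, incomplete = incomplete, skill = skill,
            class = c("ulb_segments", "data.frame"))
}

# Target point for a template step: the labeled waypoint, except that object
# interactions at the rest position (the grasp and put-down of the drinking
# task) aim at the object's spot, slightly anterior of A, so the final
# reposition to A is a real movement.
step_target <- function(primitive, waypoint, layout) {
  pts <- layout$points
  if (!waypoint %in% names(pts)) return(NULL)
  tgt <- pts[[waypoint]]
  if (primitive %in% c("reach_for_grasp", "transport") &&
      identical(waypoint, "A"))
    tgt <- tgt + c(layout$object_offset_m %||% 0.06, 0, 0)
  tgt
}

#' @export
print.ulb_segments <- function(x, ...) {
  cat(sprintf("Primitive segmentation (%s): %d segments%s\n",
              attr(x, "skill") %||% "?", nrow(x),
              if (isTRUE(attr(x, "incomplete"))) " [incomplete]" else ""))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Count movement stops inside a movement
#'
#' Number of maximal sub-intervals strictly inside `(onset_s, end_s)` where
#' speed drops below `threshold_fraction` of the within-movement peak speed.
#' The threshold is relative, so the count is invariant to uniform speed
#' rescaling. Sub-threshold runs touching the interval edges (the movement's
#' own start/stop ramps) are not stops.
#'
#' @param speed Speed series (m/s).
#' @param rate Sampling rate (Hz).
#' @param onset_s,end_s Movement interval bounds (s).
#' @param threshold_fraction Fraction of within-movement peak speed.
#' @return Integer count.
#' @export
count_movement_stops <- function(speed, rate, onset_s, end_s,
                                 threshold_fraction = 0.10) {
  stopifnot(onset_s < end_s)
  i0 <- max(1L, round(onset_s * rate) + 1L)
  i1 <- min(length(speed), round(end_s * rate) + 1L)
  s <- speed[i0:i1]
  thr <- threshold_fraction * max(s)
  runs <- true_runs(s < thr)
  if (!nrow(runs)) return(0L)
  interior <- runs$start > 1L & runs$end < length(s)
  sum(interior)
}

#' Trunk-compensation validity check
#'
#' A trial is invalid when the trunk lean exceeds the threshold (strictly
#' above, default 20 degrees) in the sagittal or frontal plane, or when no
#' trunk recording is available at all (trunk displacement must be recorded).
#'
#' @param sagittal_deg,frontal_deg Trunk angle series (degrees, relative to
#'   the first sample); pass `NULL` when not recorded.
#' @param threshold_deg Validity threshold (strict >).
#' @return Object of class `ulb_validity`: list with `valid`,
#'   `max_sagittal_trunk_deg`, `max_frontal_trunk_deg`, `reasons`.
#' @export
check_validity <- function(sagittal_deg = NULL, frontal_deg = NULL,
                           threshold_deg = 20) {
  reasons <- character(0)
  if (is.null(sagittal_deg) && is.null(frontal_deg)) {
    return(structure(list(valid = FALSE,
                          max_sagittal_trunk_deg = NA_real_,
                          max_frontal_trunk_deg = NA_real_,
                          reasons = "trunk_not_recorded"),
                     class = "ulb_validity"))
  }
  max_sag <- if (is.null(sagittal_deg)) NA_real_ else max(abs(sagittal_deg))
  max_fro <- if (is.null(frontal_deg)) NA_real_ else max(abs(frontal_deg))
  if (!is.na(max_sag) && max_sag > threshold_deg)
    reasons <- c(reasons, "trunk_sagittal")
  if (!is.na(max_fro) && max_fro > threshold_deg)
    reasons <- c(reasons, "trunk_frontal")
  structure(list(valid = length(reasons) == 0L,
                 max_sagittal_trunk_deg = max_sag,
                 max_frontal_trunk_deg = max_fro,
                 reasons = reasons),
            class = "ulb_validity")
}

#' @export
print.ulb_validity <- function(x, ...) {
  cat(sprintf("Trial validity: %s (max trunk sagittal %.1f deg, frontal %.1f deg)\n",
              if (x$valid) "VALID" else "INVALID",
              x$max_sagittal_trunk_deg, x$max_frontal_trunk_deg))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}
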