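# Kinematic performance indicators, grouped by motor ability. Low-level
# functions compute one ability's indicators on one movement segment;
# compute_kin_pis() runs the whole suite over a segmented trial.

pi_row <- function(ability, pi, value, units) {
  data.frame(ability = ability, pi = pi, value = as.numeric(value),
             units = units, stringsAsFactors = FALSE)
}

# distance from points to the straight line through start -> target
line_distance <- function(pos, start, target) {
  u <- unit(target - start)
  rel <- sweep(pos, 2, start)
  along <- rel %*% u
  perp <- rel - outer(as.numeric(along), u)
  sqrt(rowSums(perp^2))
}

#' Accuracy indicators for one movement segment
#'
#' Trajectory absolute error (mean and max pointwise distance from the ideal
#' straight line), end-point error (distance from target at movement end) and
#' area index (unsigned area enclosed between the chord and the actual path;
#' 3-D paths are projected onto their best-fit plane since the enclosed area
#' is only defined in a plane). The variable error (SD of end-point error
#' across repetitions) is a trial-set-level quantity: see
#' [variable_error()].
#'
#' @param position n x 3 end-effector positions over the segment (m).
#' @param ideal [ideal_path()] for the segment.
#' @return data.frame of (ability, pi, value, units) rows.
#' @export
accuracy_pis <- function(position, ideal) {
  position <- as.matrix(position)
  if (nrow(position) < 2L) stop("accuracy indicators need >= 2 samples")
  d <- line_distance(position, ideal$start, ideal$target)
  epe <- vnorm(position[nrow(position), ] - ideal$target)
  rbind(
    pi_row("accuracy", "trajectory_absolute_error_mean", mean(d), "m"),
    pi_row("accuracy", "trajectory_absolute_error_max", max(d), "m"),
    pi_row("accuracy", "end_point_error", epe, "m"),
    pi_row("accuracy", "area_index", area_index(position), "m^2")
  )
}

#' @rdname accuracy_pis
#' @param end_point_errors End-point errors from repetitions of the same
#'   movement (length >= 2, otherwise `NA` with a warning: not computable from
#'   a single repetition).
#' @export
variable_error <- function(end_point_errors) {
  if (length(end_point_errors) < 2L) {
    warning("variable_error is not computable from a single repetition")
    return(NA_real_)
  }
  stats::sd(end_point_errors)
}

# Unsigned area between the chord and the path: close the path polygon with
# the chord and apply the shoelace formula in the best-fit plane.
area_index <- function(position) {
  p <- as.matrix(position)
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  sv <- svd(pc, nu = 0, nv = 2)
  xy <- pc %*% sv$v
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Efficacy indicators for a segmented trial
#'
#' Success rate (reached targets over goal-directed attempts: reach, grasp and
#' transport segments) and the mandatory total number of movement stops summed
#' over all movement segments.
#'
#' @param segments [segment_trial()] result.
#' @param speed Trial speed series (m/s).
#' @param rate Sampling rate (Hz).
#' @param threshold_fraction Stop-counting threshold (fraction of per-movement
#'   peak speed).
#' @return data.frame of PI rows; success rate is `NA` with zero attempts.
#' @export
efficacy_pis <- function(segments, speed, rate, threshold_fraction = 0.10) {
  goal <- segments$primitive %in% c("point_to_point_reach", "reach_for_grasp",
                                    "transport")
  attempts <- sum(goal)
  success <- if (attempts == 0L) NA_real_
             else sum(segments$reached[goal], na.rm = TRUE) / attempts
  moves <- segments[segments$primitive %in% movement_primitives(), , drop = FALSE]
  stops <- sum(vapply(seq_len(nrow(moves)), function(i) {
    count_movement_stops(speed, rate, moves$start_s[i], moves$end_s[i],
                         threshold_fraction)
  }, integer(1)))
  rbind(pi_row("efficacy", "success_rate", success, "ratio"),
        pi_row("efficacy", "number_of_movement_stops", stops, "count"))
}

#' Efficiency indicators for one movement segment
#'
#' Movement time, path traveled (arc length), the mandatory path length ratio
#' (arc length over chord, >= 1) and trunk compensation (peak sagittal-plane
#' trunk displacement over peak sagittal-plane hand displacement).
#'
#' @param position n x 3 end-effector positions over the segment (m).
#' @param rate Sampling rate (Hz).
#' @param trunk Optional n x 3 trunk-marker positions over the segment.
#' @return data.frame of PI rows; path length ratio is `NA` for a zero chord.
#' @export
efficiency_pis <- function(position, rate, trunk = NULL) {
  position <- as.matrix(position)
  n <- nrow(position)
  mt <- (n - 1L) / rate
  arc <- sum(sqrt(rowSums(diff(position)^2)))
  chord <- vnorm(position[n, ] - position[1, ])
  plr <- if (chord < .Machine$double.eps) NA_real_ else arc / chord
  sag_excursion <- function(m) {
    rel <- sweep(m[, 1:2, drop = FALSE], 2, m[1, 1:2])
    max(sqrt(rowSums(rel^2)))
  }
  tc <- if (is.null(trunk)) NA_real_ else {
    hand <- sag_excursion(position)
    if (hand < .Machine$double.eps) NA_real_
    else sag_excursion(as.matrix(trunk)) / hand
  }
  rbind(pi_row("efficiency", "movement_time", mt, "s"),
        pi_row("efficiency", "path_traveled", arc, "m"),
        pi_row("efficiency", "path_length_ratio", plr, "ratio"),
        pi_row("efficiency", "trunk_compensation", tc, "ratio"))
}

#' Intra-limb coordination indicators for one movement segment
#'
#' Joint angle correlation (Pearson r between shoulder elevation `q2` and
#' elbow flexion/extension `q4`), elbow peak angular velocity, and time to
#' peak elbow extension (minimum flexion angle) relative to movement duration.
#'
#' @param q n x 8 joint-angle matrix over the segment (degrees).
#' @param rate Sampling rate (Hz).
#' @return data.frame of PI rows; correlation is `NA` for constant traces.
#' @export
coordination_pis <- function(q, rate) {
  q <- as.matrix(q)
  q2 <- q[, 3]; q4 <- q[, 5]
  r <- if (stats::sd(q2) < 1e-12 || stats::sd(q4) < 1e-12) NA_real_
       else stats::cor(q2, q4)
  dq4 <- differentiate(q4, rate, order = 1, cutoff_hz = 6)
  i_ext <- which.min(q4)
  ttpe <- (i_ext - 1L) / (nrow(q) - 1L)
  rbind(pi_row("intra_limb_coordination", "joint_angle_correlation", r, "r"),
        pi_row("intra_limb_coordination", "elbow_peak_velocity",
               max(abs(dq4)), "deg/s"),
        pi_row("intra_limb_coordination", "time_to_peak_elbow_extension",
               ttpe, "fraction"))
}

#' Movement-amplitude indicators for one movement segment
#'
#' The mandatory per-DOF joint range of motion, maximum reached distance from
#' the segment start point, trunk displacement (peak Euclidean trunk-marker
#' excursion) and normalized reaching area (maximum reached distance over arm
#' length).
#'
#' @param q n x 8 joint-angle matrix (degrees) or `NULL`.
#' @param position n x 3 end-effector positions (m).
#' @param geom [arm_geometry()].
#' @param trunk Optional n x 3 trunk-marker positions.
#' @return data.frame of PI rows (one `joint_range_of_motion_q<i>` per DOF).
#' @export
amplitude_pis <- function(q, position, geom, trunk = NULL) {
  position <- as.matrix(position)
  rel <- sweep(position, 2, position[1, ])
  mrd <- max(sqrt(rowSums(rel^2)))
  rows <- list()
  if (!is.null(q)) {
    q <- as.matrix(q)
    rom <- apply(q, 2, function(col) max(col) - min(col))
    rows <- lapply(seq_along(rom), function(i)
      pi_row("movement_amplitude", paste0("joint_range_of_motion_q", i - 1L),
             rom[i], "deg"))
  }
  td <- if (is.null(trunk)) NA_real_ else {
    tr <- sweep(as.matrix(trunk), 2, as.matrix(trunk)[1, ])
    max(sqrt(rowSums(tr^2)))
  }
  do.call(rbind, c(rows, list(
    pi_row("movement_amplitude", "maximum_reached_distance", mrd, "m"),
    pi_row("movement_amplitude", "trunk_displacement", td, "m"),
    pi_row("movement_amplitude", "normalized_reaching_area",
           mrd / geom$arm_length_m, "ratio"))))
}

#' Planning-predictability indicators for one movement segment
#'
#' Time to peak velocity (fraction of movement duration), the mandatory
#' reaction time (onset at 10% of peak speed minus go cue), initial movement
#' direction error (actual-vs-ideal distance at the 10%-of-peak-velocity
#' time) and aiming angle (angle between the target direction and the travel
#' direction from start to the peak-speed point).
#'
#' @param position n x 3 end-effector positions over the segment (m).
#' @param speed Segment speed series (m/s).
#' @param rate Sampling rate (Hz).
#' @param ideal [ideal_path()] for the segment.
#' @param go_cue_s Go-cue time in segment-relative seconds (may be negative if
#'   the cue preceded the segment start).
#' @param onset_s Movement onset in segment-relative seconds (10%-of-peak
#'   definition, from [detect_onset()]); defaults to detecting it here.
#' @return data.frame of PI rows.
#' @export
planning_pis <- function(position, speed, rate, ideal, go_cue_s = 0,
                         onset_s = NULL) {
  position <- as.matrix(position)
  n <- nrow(position)
  dur <- (n - 1L) / rate
  i_pk <- which.max(speed)
  ttpv <- (i_pk - 1L) / (n - 1L)
  if (is.null(onset_s)) {
    det <- detect_onset(speed, rate, go_cue_s = max(0, go_cue_s))
    onset_s <- det$onset_s
  }
  if (is.na(onset_s)) {
    return(rbind(
      pi_row("planning_predictability", "time_to_peak_velocity", NA, "fraction"),
      pi_row("planning_predictability", "reaction_time", NA, "s"),
      pi_row("planning_predictability", "initial_movement_direction_error", NA, "m"),
      pi_row("planning_predictability", "aiming_angle", NA, "deg")))
  }
  rt <- onset_s - go_cue_s
  i10 <- min(n, round(onset_s * rate) + 1L)
  ideal_p <- min_jerk_position(ideal$start, ideal$target,
                               (i10 - 1L) / (n - 1L))
  imde <- vnorm(position[i10, ] - ideal_p)
  travel <- position[i_pk, ] - position[1, ]
  tgt_dir <- ideal$target - ideal$start
  aim <- if (vnorm(travel) < 1e-12 || vnorm(tgt_dir) < 1e-12) NA_real_ else
    rad2deg(acos(clamp(sum(unit(travel) * unit(tgt_dir)), -1, 1)))
  rbind(
    pi_row("planning_predictability", "time_to_peak_velocity", ttpv, "fraction"),
    pi_row("planning_predictability", "reaction_time", rt, "s"),
    pi_row("planning_predictability", "initial_movement_direction_error",
           imde, "m"),
    pi_row("planning_predictability", "aiming_angle", aim, "deg"))
}

# Local maxima above threshold_fraction * peak with a minimum separation;
# when two peaks are closer than min_separation_s the smaller one is dropped.
count_velocity_peaks <- function(speed, rate, threshold_fraction = 0.10,
                                 min_separation_s = 0.10) {
  n <- length(speed)
  if (n < 3L) return(0L)
  thr <- threshold_fraction * max(speed)
  cand <- which(diff(sign(diff(speed))) < 0) + 1L
  # plateau maxima: rising then flat; keep first sample of flat tops
  cand <- cand[speed[cand] >= thr]
  if (!length(cand)) return(0L)
  ord <- cand[order(-speed[cand])]
  kept <- integer(0)
  min_sep <- min_separation_s * rate
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  length(kept)
}

#' Spectral arc length (SPARC) of a speed profile
#'
#' Negative arc length of the magnitude-normalized Fourier spectrum of the
#' speed profile: smoother movements have less high-frequency content and a
#' shorter (less negative) spectral trajectory. Invariant to amplitude
#' scaling. The FFT is zero-padded to four times the next power of two; the
#' spectrum is truncated at `fc` and, adaptively, at the last frequency whose
#' normalized magnitude exceeds `amp_threshold`.
#'
#' @param speed Speed series (m/s).
#' @param rate Sampling rate (Hz).
#' @param fc Frequency cutoff (Hz, default 20).
#' @param amp_threshold Adaptive amplitude cutoff on the normalized magnitude
#'   spectrum (default 0.05).
#' @return SPARC value (negative, dimensionless).
#' @export
sparc <- function(speed, rate, fc = 20, amp_threshold = 0.05) {
  n <- length(speed)
  nfft <- 4L * 2^ceiling(log2(n))
  sp <- abs(stats::fft(c(speed, rep(0, nfft - n))))
  f <- (seq_len(nfft) - 1L) * rate / nfft
  sel <- f <= fc
  f <- f[sel]
  v <- sp[sel] / sp[1]
  cut <- max(which(v >= amp_threshold))
  f <- f[1:cut]; v <- v[1:cut]
  if (length(f) < 2L) return(0)
  -sum(sqrt((diff(f) / (f[length(f)] - f[1]))^2 + diff(v)^2))
}

#' Normalized dimensionless jerk of one movement segment
#'
#' Time-integral of the squared jerk (third derivative of position) scaled by
#' duration^5 over movement length^2; equals 720 for a pure minimum-jerk
#' reach. Dimensionless, hence invariant to amplitude and time rescaling.
#'
#' @param position n x 3 positions over the segment (m).
#' @param rate Sampling rate (Hz).
#' @param cutoff_hz Optional low-pass cutoff applied before the fit; the
#'   default `NULL` relies on the Savitzky-Golay smoothing alone.
#' @return NDJ value (dimensionless).
#' @export
normalized_dimensionless_jerk <- function(position, rate, cutoff_hz = NULL) {
  position <- as.matrix(position)
  n <- nrow(position)
  if (n < 11L) stop("dimensionless jerk needs >= 11 samples")
  dur <- (n - 1L) / rate
  # Savitzky-Golay third derivative: its endpoint filters avoid the large
  # boundary error of repeated one-sided difference stencils, and the jerk
  # magnitude peaks exactly at the movement boundaries.
  smoothed <- apply(position, 2, lowpass_zero_phase, rate = rate,
                    cutoff_hz = cutoff_hz)
  jerk <- apply(smoothed, 2, function(col)
    signal::sgolayfilt(col, p = 5, n = 9, m = 3, ts = 1 / rate))
  j2 <- rowSums(jerk^2)
  integral <- sum((j2[-1] + j2[-n]) / 2) / rate
  arc <- sum(sqrt(rowSums(diff(position)^2)))
  if (arc < .Machine$double.eps) return(NA_real_)
  integral * dur^5 / arc^2
}

#' Smoothness indicators for one movement segment
#'
#' The mandatory number of velocity peaks (maxima above 10% of peak speed,
#' minimum separation 100 ms), speed correlation to the ideal minimum-jerk
#' profile, movement arrest period ratio (fraction of time speed exceeds 10%
#' of peak), peak speed ratio (mean over peak speed), normalized
#' dimensionless jerk, spectral arc length and mean acceleration magnitude.
#'
#' @param position n x 3 end-effector positions over the segment (m).
#' @param speed Segment speed series (m/s).
#' @param rate Sampling rate (Hz).
#' @param threshold_fraction Shared 10% peak-speed threshold (peak counting
#'   and arrest-period ratio).
#' @param min_separation_s Minimum peak separation.
#' @param cutoff_hz Low-pass cutoff for jerk/acceleration derivatives.
#' @return data.frame of PI rows.
#' @export
smoothness_pis <- function(position, speed, rate, threshold_fraction = 0.10,
                           min_separation_s = 0.10, cutoff_hz = 6) {
  if (length(speed) < 20L) stop("smoothness indicators need >= 20 samples")
  pk <- max(speed)
  if (pk < .Machine$double.eps) stop("degenerate zero-length movement")
  n <- length(speed)
  npeaks <- count_velocity_peaks(speed, rate, threshold_fraction,
                                 min_separation_s)
  chord <- vnorm(as.matrix(position)[n, ] - as.matrix(position)[1, ])
  vid <- min_jerk_speed_profile(chord, (n - 1L) / rate, n)
  rho <- if (stats::sd(speed) < 1e-12) NA_real_ else stats::cor(speed, vid)
  mapr <- mean(speed > threshold_fraction * pk)
  acc <- differentiate(as.matrix(position), rate, order = 2,
                       cutoff_hz = cutoff_hz)
  rbind(
    pi_row("smoothness", "number_of_velocity_peaks", npeaks, "count"),
    pi_row("smoothness", "speed_correlation_to_ideal", rho, "r"),
    pi_row("smoothness", "movement_arrest_period_ratio", mapr, "fraction"),
    pi_row("smoothness", "peak_speed_ratio", mean(speed) / pk, "ratio"),
    pi_row("smoothness", "normalized_dimensionless_jerk",
           normalized_dimensionless_jerk(position, rate), "1"),
    pi_row("smoothness", "spectral_arc_length", sparc(speed, rate), "1"),
    pi_row("smoothness", "mean_acceleration",
           mean(sqrt(rowSums(acc^2))), "m/s^2"))
}

#' Speed indicators for one movement segment
#'
#' Peak velocity, the mandatory mean velocity, and mean velocity variability
#' (RMS difference between the actual speed profile and the ideal
#' minimum-jerk profile of the same chord length and duration).
#'
#' @param speed Segment speed series (m/s).
#' @param rate Sampling rate (Hz).
#' @param ideal [ideal_path()] for the segment.
#' @return data.frame of PI rows.
#' @export
speed_pis <- function(speed, rate, ideal) {
  n <- length(speed)
  vid <- min_jerk_speed_profile(ideal$length_m, (n - 1L) / rate, n)
  rbind(
    pi_row("speed", "peak_velocity", max(speed), "m/s"),
    pi_row("speed", "mean_velocity", mean(speed), "m/s"),
    pi_row("speed", "mean_velocity_variability",
           sqrt(mean((speed - vid)^2)), "m/s"))
}

#' Compute all kinematic performance indicators of a segmented trial
#'
#' Runs the per-ability indicator functions over every movement segment and
#' the trial-level efficacy indicators, returning one tidy table.
#'
#' @param trial Trial list with `position`, `rate`, optionally `q`, `trunk`,
#'   `go_cue_s`, `geom`, `layout`.
#' @param segments [segment_trial()] result.
#' @param geom [arm_geometry()] (defaults to `trial$geom`).
#' @param cutoff_hz Low-pass cutoff for derivatives.
#' @return data.frame with columns `step`, `primitive`, `waypoint`, `ability`,
#'   `pi`, `value`, `units`, `status`.
#' @export
compute_kin_pis <- function(trial, segments, geom = trial$geom, cutoff_hz = 6) {
  rate <- trial$rate
  pos <- as.matrix(trial$position)
  speed <- trajectory_speed(pos, rate, cutoff_hz = cutoff_hz)
  moves <- segments[segments$primitive %in% movement_primitives(), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(moves))) {
    i0 <- max(1L, round(moves$start_s[i] * rate) + 1L)
    i1 <- min(nrow(pos), round(moves$end_s[i] * rate) + 1L)
    idx <- i0:i1
    p <- pos[idx, , drop = FALSE]
    sp <- speed[idx]
    tgt <- if (!is.null(trial$layout))
      step_target(moves$primitive[i], moves$waypoint_to[i], trial$layout)
    else p[nrow(p), ]
    ideal <- ideal_path(p[1, ], tgt %||% p[nrow(p), ],
                        (length(idx) - 1L) / rate)
    trunk <- if (!is.null(trial$trunk)) as.matrix(trial$trunk)[idx, , drop = FALSE]
    qseg <- if (!is.null(trial$q)) as.matrix(trial$q)[idx, , drop = FALSE]
    cue_rel <- (trial$go_cue_s %||% moves$start_s[i]) - moves$start_s[i]
    rows <- rbind(
      accuracy_pis(p, ideal),
      efficiency_pis(p, rate, trunk),
      if (!is.null(qseg)) coordination_pis(qseg, rate),
      amplitude_pis(qseg, p, geom, trunk),
      planning_pis(p, sp, rate, ideal, go_cue_s = cue_rel),
      smoothness_pis(p, sp, rate, cutoff_hz = cutoff_hz),
      speed_pis(sp, rate, ideal))
    rows$step <- moves$step[i]
    rows$primitive <- moves$primitive[i]
    rows$waypoint <- moves$waypoint_to[i]
    out[[length(out) + 1L]] <- rows
  }
  eff <- efficacy_pis(segments, speed, rate)
  eff$step <- NA_integer_; eff$primitive <- NA_character_
  eff$waypoint <- NA_character_
  out[[length(out) + 1L]] <- eff
  res <- do.call(rbind, out)
  reg <- pi_registry()
  base_pi <- sub("(_mean|_max|_q[0-9])$", "", res$pi)
  base_pi <- sub("^trajectory_absolute_error$", "trajectory_absolute_error",
                 base_pi)
  res$status <- reg$status[match(base_pi, reg$name)]
  res$status[is.na(res$status)] <- "recommended"
  rownames(res) <- NULL
  res[c("step", "primitive", "waypoint", "ability", "pi", "value", "units",
        "status")]
}
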