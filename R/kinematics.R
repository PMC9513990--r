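# 8-DOF upper-limb kinematic model (ISB convention), shoulder-convention
# conversion, numerical differentiation with zero-phase filtering, and trunk
# angles. Ground frame: X anterior, Y up, Z lateral toward the evaluated side.
# Angles are radians internally and degrees at every I/O boundary.

#' Arm geometry
#'
#' @param upper_arm_m Upper arm (shoulder to elbow) length in meters.
#' @param forearm_m Forearm (elbow to wrist/end-effector) length in meters.
#' @param dominant_arm,evaluated_arm "left" or "right".
#' @return object of class `ulb_geometry` with `arm_length_m = upper + forearm`.
#' @export
#' @examples
#' arm_geometry(0.30, 0.25)
arm_geometry <- function(upper_arm_m, forearm_m,
                         dominant_arm = "right", evaluated_arm = "right") {
  stopifnot(is.numeric(upper_arm_m), upper_arm_m > 0,
            is.numeric(forearm_m), forearm_m > 0)
  dominant_arm <- match.arg(dominant_arm, c("left", "right"))
  evaluated_arm <- match.arg(evaluated_arm, c("left", "right"))
  structure(list(upper_arm_m = upper_arm_m, forearm_m = forearm_m,
                 arm_length_m = upper_arm_m + forearm_m,
                 dominant_arm = dominant_arm, evaluated_arm = evaluated_arm),
            class = "ulb_geometry")
}

#' @export
print.ulb_geometry <- function(x, ...) {
  cat(sprintf("Arm geometry: upper %.3f m + forearm %.3f m = %.3f m (%s arm evaluated)\n",
              x$upper_arm_m, x$forearm_m, x$arm_length_m, x$evaluated_arm))
  invisible(x)
}

# Glenohumeral rotation matrix from ISB angles (Y-X'-Y'' sequence:
# plane of elevation about Y, elevation about the rotated X with negative
# sign so that positive elevation raises the arm, axial rotation about Y'').
shoulder_rotation_isb <- function(q1, q2, q3) {
  rot_y(q1) %*% rot_x(-q2) %*% rot_y(q3)
}

# Robotics-convention shoulder rotation: horizontal adduction/abduction about
# the vertical axis, flexion/extension about the (rotated) lateral axis, then
# humeral axial rotation about the humerus long axis (Y-Z'-Y'' sequence).
shoulder_rotation_robotics <- function(fe, haa, hr) {
  rot_y(haa) %*% rot_z(fe) %*% rot_y(hr)
}

#' Forward kinematics of the 8-DOF upper-limb chain
#'
#' Rigid chain thorax (q0, flexion/extension) -> glenohumeral ball-and-socket
#' (q1 plane of elevation, q2 elevation, q3 axial rotation; ISB Y-X'-Y'') ->
#' elbow (q4 flexion/extension, q5 pronation/supination) -> wrist (q6
#' flexion/extension, q7 ulnar/radial deviation). The hand is excluded from the
#' scheme, so the end-effector coincides with the wrist point; q5-q7 only set
#' the distal frame orientation. The zero posture is ISB neutral: arm hanging,
#' palm medial.
#'
#' @param q Numeric vector of 8 joint angles (degrees) or an n x 8 matrix.
#' @param geom [arm_geometry()].
#' @param trunk_height_m Navel-to-shoulder trunk length; the trunk pivots about
#'   a base point this far below the shoulder, so q0 translates the shoulder.
#' @return For a vector `q`, a list with 3-vectors `shoulder`, `elbow`,
#'   `wrist`, `end_effector` (meters, origin at the upright shoulder) and the
#'   distal rotation matrix `R_hand`; for a matrix, n x 3 matrices.
#' @export
#' @examples
#' g <- arm_geometry(0.30, 0.25)
#' forward_kinematics(c(0, 0, 0, 0, 90, 0, 0, 0), g)$end_effector
forward_kinematics <- function(q, geom, trunk_height_m = 0.45) {
  stopifnot(inherits(geom, "ulb_geometry"))
  if (is.matrix(q)) {
    out <- apply(q, 1, function(row) forward_kinematics(row, geom, trunk_height_m),
                 simplify = FALSE)
    grab <- function(field) t(vapply(out, `[[`, numeric(3), field))
    return(list(shoulder = grab("shoulder"), elbow = grab("elbow"),
                wrist = grab("wrist"), end_effector = grab("end_effector")))
  }
  if (length(q) != 8L || any(!is.finite(q)))
    stop("q must be 8 finite joint angles in degrees")
  q <- deg2rad(q)
  base <- c(0, -trunk_height_m, 0)               # trunk pivot, below shoulder
  R0 <- rot_z(-q[1])                             # positive q0 = forward lean
  shoulder <- base + R0 %*% c(0, trunk_height_m, 0)
  R_sh <- R0 %*% shoulder_rotation_isb(q[2], q[3], q[4])
  elbow <- shoulder + R_sh %*% c(0, -geom$upper_arm_m, 0)
  R_fa <- R_sh %*% rot_z(q[5])
  wrist <- elbow + R_fa %*% c(0, -geom$forearm_m, 0)
  R_hand <- R_fa %*% rot_y(q[6]) %*% rot_z(q[7]) %*% rot_x(q[8])
  list(shoulder = as.numeric(shoulder), elbow = as.numeric(elbow),
       wrist = as.numeric(wrist), end_effector = as.numeric(wrist),
       R_hand = R_hand)
}

# Decompose a rotation matrix as Ry(q1) Rx(-q2) Ry(q3) (ISB shoulder).
# Near the elevation singularity (sin q2 ~ 0) q1 is set to 0 by convention
# and the result is flagged.
decompose_isb <- function(R, tol = 1e-6) {
  q2 <- acos(clamp(R[2, 2], -1, 1))
  if (abs(sin(q2)) > tol) {
    q1 <- atan2(-R[1, 2], -R[3, 2])
    q3 <- atan2(-R[2, 1],  R[2, 3])
    singular <- FALSE
  } else {
    q1 <- 0
    q3 <- atan2(R[1, 3], R[1, 1])
    singular <- TRUE
  }
  list(q = c(q1, q2, q3), singular = singular)
}

# Decompose as Ry(haa) Rz(fe) Ry(hr) (robotics shoulder), fe in [0, pi].
decompose_robotics <- function(R, tol = 1e-6) {
  fe <- acos(clamp(R[2, 2], -1, 1))
  if (abs(sin(fe)) > tol) {
    haa <- atan2(R[3, 2], -R[1, 2])
    hr <- atan2(R[2, 3], R[2, 1])
    singular <- FALSE
  } else {
    haa <- 0
    hr <- atan2(R[1, 3], R[1, 1])
    singular <- TRUE
  }
  list(q = c(fe, haa, hr), singular = singular)
}

#' Convert robotics shoulder angles to ISB angles (and back)
#'
#' Both conventions describe the same humeral rotation matrix; the conversion
#' composes the source convention's rotations and decomposes the result in the
#' target convention's Euler sequence (ISB Y-X'-Y'': plane of elevation,
#' elevation, axial rotation; robotics Y-Z'-Y'': horizontal
#' adduction/abduction, flexion/extension, humeral rotation). At the elevation
#' singularity the plane of elevation is undefined and set to 0, with
#' `singular = TRUE`.
#'
#' @param flexion_extension,horizontal_adduction,humeral_rotation Robotics
#'   shoulder angles in degrees.
#' @return list with `q1`, `q2`, `q3` (degrees) and `singular`.
#' @export
#' @examples
#' isb_from_robotics(90, 0, 0)  # pure flexion: plane of elevation 90 deg
isb_from_robotics <- function(flexion_extension, horizontal_adduction = 0,
                              humeral_rotation = 0) {
  R <- shoulder_rotation_robotics(deg2rad(flexion_extension),
                                  deg2rad(horizontal_adduction),
                                  deg2rad(humeral_rotation))
  d <- decompose_isb(R)
  list(q1 = rad2deg(d$q[1]), q2 = rad2deg(d$q[2]), q3 = rad2deg(d$q[3]),
       singular = d$singular)
}

#' @rdname isb_from_robotics
#' @param q1,q2,q3 ISB shoulder angles in degrees (plane of elevation,
#'   elevation, axial rotation).
#' @export
robotics_from_isb <- function(q1, q2, q3) {
  R <- shoulder_rotation_isb(deg2rad(q1), deg2rad(q2), deg2rad(q3))
  d <- decompose_robotics(R)
  list(flexion_extension = rad2deg(d$q[1]),
       horizontal_adduction = rad2deg(d$q[2]),
       humeral_rotation = rad2deg(d$q[3]),
       singular = d$singular)
}

# First derivative with central differences and one-sided endpoint stencils.
num_deriv <- function(x, dt) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  d <- numeric(n)
  if (n == 2L) {
    d[] <- (x[2] - x[1]) / dt
    return(d)
  }
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * dt)
  d
}

#' Filtered numerical differentiation
#'
#' Zero-phase low-pass filtering (4th-order Butterworth, forward-backward)
#' followed by central differences applied `order` times; endpoints use
#' one-sided stencils so the output keeps the input length.
#'
#' @param x Numeric vector or matrix (one column per coordinate/channel).
#' @param rate Sampling rate in Hz (uniform sampling required).
#' @param order Derivative order: 1 (velocity), 2 (acceleration) or 3 (jerk).
#' @param cutoff_hz Low-pass cutoff; `NULL` or `Inf` disables filtering.
#' @param butter_order Butterworth order of the (pre-squaring) filter.
#' @param time Optional time stamps; if given, uniformity is checked.
#' @return Object of the same shape as `x`.
#' @export
differentiate <- function(x, rate, order = 1, cutoff_hz = 6, butter_order = 4,
                          time = NULL) {
  stopifnot(order %in% 1:3, rate > 0)
  if (!is.null(time)) {
    dt <- diff(time)
    if (length(dt) && (max(dt) - min(dt)) > 1e-6 * mean(dt))
      stop("non-uniform timestamps: resample to a uniform grid before differentiating")
  }
  if (is.matrix(x))
    return(apply(x, 2, differentiate, rate = rate, order = order,
                 cutoff_hz = cutoff_hz, butter_order = butter_order))
  if (length(x) < 9L) stop("need at least 9 samples")
  y <- lowpass_zero_phase(x, rate, cutoff_hz, butter_order)
  dt <- 1 / rate
  for (i in seq_len(order)) y <- num_deriv(y, dt)
  y
}

# Forward-backward filtering with odd-reflection end padding, so that edge
# transients fall in the (discarded) padding rather than the signal.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  padlen <- min(n - 1L, 3L * max(length(bf$b), length(bf$a)) * 4L)
  if (padlen < 1L) return(as.numeric(signal::filtfilt(bf, x)))
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(padlen + 1L):(padlen + n)]
}

# Zero-phase Butterworth low-pass; pass-through when cutoff is NULL/Inf or
# at/above Nyquist.
lowpass_zero_phase <- function(x, rate, cutoff_hz, butter_order = 4) {
  if (is.null(cutoff_hz) || !is.finite(cutoff_hz) || cutoff_hz >= rate / 2)
    return(x)
  bf <- signal::butter(butter_order, cutoff_hz / (rate / 2), type = "low")
  filtfilt_padded(bf, x)
}

# Speed (Euclidean norm of velocity) of a 3-D trajectory.
trajectory_speed <- function(position, rate, cutoff_hz = 6) {
  v <- differentiate(as.matrix(position), rate, order = 1, cutoff_hz = cutoff_hz)
  sqrt(rowSums(v^2))
}

#' Sagittal and frontal trunk angles
#'
#' Angles are relative to the trial's first-sample trunk orientation. The
#' sagittal angle is the lean in the anterior (X-Y) plane, the frontal angle
#' the lean in the lateral (Z-Y) plane.
#'
#' @param marker Optional n x 3 trunk-marker trace (meters) measured from the
#'   trunk pivot (or any fixed base passed as `base`).
#' @param q0 Optional trunk flexion/extension trace in degrees (used when no
#'   marker is given; frontal angle is then 0).
#' @param base Fixed trunk pivot point subtracted from `marker`.
#' @return data.frame with `sagittal_deg` and `frontal_deg`.
#' @export
trunk_angle <- function(marker = NULL, q0 = NULL, base = c(0, 0, 0)) {
  if (is.null(marker) && is.null(q0))
    stop("trunk data missing: supply a trunk `marker` trace or a `q0` trace")
  if (!is.null(marker)) {
    m <- sweep(as.matrix(marker), 2, base)
    sag <- rad2deg(atan2(m[, 1], m[, 2]))
    fro <- rad2deg(atan2(m[, 3], m[, 2]))
    data.frame(sagittal_deg = sag - sag[1], frontal_deg = fro - fro[1])
  } else {
    data.frame(sagittal_deg = q0 - q0[1], frontal_deg = rep(0, length(q0)))
  }
}
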