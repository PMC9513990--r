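# Protocol-conformant synthetic trials: minimum-jerk reaches through the A-E
# layout with ground-truth labels, inverse-kinematics-consistent joint angles,
# tunable impairment, amplitude-modulated band-limited synthetic EMG, and
# disturbance injection. The EMG synthesis is phenomenological (envelope x
# carrier noise), sufficient to exercise every EMG indicator; it is not a
# motor-unit model.

#' Impairment parameters for the trial simulator
#'
#' @param n_submovements Sub-movements per reach (>= 1); values above 1
#'   fragment each movement into that many bumps separated by short arrests
#'   (smoothness loss).
#' @param reaction_delay_s Delay between go cue and first movement start.
#' @param trunk_lean_deg Peak trunk compensation lean during reaches.
#' @param curvature_gain Lateral path deviation as a fraction of chord length.
#' @param speed_scale Multiplies movement speed (divides durations).
#' @param duration_jitter_s SD of the per-movement duration jitter
#'   (self-selected speed variability; 0 keeps movements canonical).
#' @param emg_cocontraction_gain Antagonist burst amplitude relative to the
#'   agonist (1 = identical envelopes).
#' @param emg_noise_sd Additive sensor-noise SD (mV).
#' @param emg_onset_latency_s Muscle-activation latency of the first movement
#'   relative to the go cue.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of class `ulb_impairment`.
#' @export
impairment_params <- function(n_submovements = 1, reaction_delay_s = 0,
                              trunk_lean_deg = 0, curvature_gain = 0,
                              speed_scale = 1, duration_jitter_s = 0,
                              emg_cocontraction_gain = 0.2,
                              emg_noise_sd = 0.01,
                              emg_onset_latency_s = 0.05, seed = 1) {
  p <- list(n_submovements = as.integer(n_submovements),
            reaction_delay_s = reaction_delay_s,
            trunk_lean_deg = trunk_lean_deg, curvature_gain = curvature_gain,
            speed_scale = speed_scale, duration_jitter_s = duration_jitter_s,
            emg_cocontraction_gain = emg_cocontraction_gain,
            emg_noise_sd = emg_noise_sd,
            emg_onset_latency_s = emg_onset_latency_s, seed = as.integer(seed))
  stopifnot(p$n_submovements >= 1L, p$speed_scale > 0,
            all(vapply(p, function(v) all(is.finite(v)), logical(1))))
  structure(p, class = "ulb_impairment")
}

# inverse kinematics of the 2-link arm: joint angles (deg, q0..q7) placing the
# end effector at world point p given the trunk lean q0 (deg).
ik_arm <- function(p, q0_deg, geom, shoulder_height_m, trunk_height_m = 0.45) {
  L1 <- geom$upper_arm_m; L2 <- geom$forearm_m
  q0 <- deg2rad(q0_deg)
  pivot <- c(0, shoulder_height_m - trunk_height_m, 0)
  R0 <- rot_z(-q0)
  shoulder <- pivot + as.numeric(R0 %*% c(0, trunk_height_m, 0))
  p_rel <- as.numeric(t(R0) %*% (p - shoulder))
  d <- vnorm(p_rel)
  if (!is.finite(d))
    stop("non-finite end-effector position in inverse kinematics")
  # targets sit at complete elbow extension, so impairment deviations can
  # nudge points marginally past the reachable sphere; tolerate (and project
  # back) up to 2% of arm length, error beyond that
  if (d > (L1 + L2) * 1.02)
    stop(sprintf("non-reachable point: distance %.3f m exceeds arm length %.3f m",
                 d, L1 + L2))
  d <- min(d, L1 + L2)
  u <- p_rel / d
  cos_q4 <- clamp((d^2 - L1^2 - L2^2) / (2 * L1 * L2), -1, 1)
  q4 <- acos(cos_q4)
  cos_a <- clamp((L1^2 + d^2 - L2^2) / (2 * L1 * d), -1, 1)
  a <- acos(cos_a)
  down <- c(0, -1, 0)
  w <- down - sum(down * u) * u
  if (vnorm(w) < 1e-9) {
    w <- c(1, 0, 0) - u[1] * u
  }
  w <- unit(w)
  h <- cos(a) * u + sin(a) * w          # humerus direction (elbow-down swivel)
  e_y <- -h
  f <- (p_rel - L1 * h) / L2            # forearm direction
  e_x <- if (sin(q4) > 1e-6) (f + cos_q4 * e_y) / sin(q4)
         else -sin(a) * u + cos(a) * w  # in-plane perpendicular for straight arm
  e_x <- unit(e_x)
  e_z <- c(e_x[2] * e_y[3] - e_x[3] * e_y[2],
           e_x[3] * e_y[1] - e_x[1] * e_y[3],
           e_x[1] * e_y[2] - e_x[2] * e_y[1])
  R <- cbind(e_x, e_y, e_z)
  sh <- decompose_isb(R)
  c(q0_deg, rad2deg(sh$q), rad2deg(q4), 0, 0, 0)
}

# Build the phase timeline of a skill execution.
build_timeline <- function(skill, layout, impair, movement_duration_s,
                           idle_dwell_s, inter_dwell_s) {
  flow <- motor_skill_flow(skill)
  pts <- layout$points
  phases <- list()
  cur <- pts$A
  t <- 0
  go_cue_s <- NA_real_
  prev_move <- FALSE
  for (s in seq_len(nrow(flow))) {
    prim <- flow$primitive[s]
    wp <- flow$waypoint[s]
    if (prim %in% hold_primitives()) {
      dur <- idle_dwell_s
      if (s == 1L) {
        go_cue_s <- idle_dwell_s
        dur <- dur + impair$reaction_delay_s
      }
      phases[[length(phases) + 1L]] <- list(step = s, type = "hold",
                                            primitive = prim, waypoint = wp,
                                            start = t, end = t + dur,
                                            from = cur, to = cur)
      t <- t + dur
      prev_move <- FALSE
    } else {
      if (prev_move) {               # brief inter-movement pause (< 1 s)
        phases[[length(phases) + 1L]] <- list(step = NA_integer_, type = "pause",
                                              primitive = NA_character_,
                                              waypoint = NA_character_,
                                              start = t, end = t + inter_dwell_s,
                                              from = cur, to = cur)
        t <- t + inter_dwell_s
      }
      tgt <- step_target(prim, wp, layout)
      L <- vnorm(tgt - cur)
      dur <- movement_duration_s / impair$speed_scale
      if (impair$duration_jitter_s > 0)
        dur <- max(0.3, dur + stats::rnorm(1, 0, impair$duration_jitter_s))
      # grasp micro-reaches scale with distance so speed stays plausible,
      # and are not fragmented (sub-movement decomposition is a property of
      # full reaches)
      micro <- L < 0.15
      if (micro) dur <- max(0.4, dur * L / 0.3)
      m <- if (micro) 1L else impair$n_submovements
      gap <- 0.12
      d_sub <- max(0.25, dur / m)
      total <- m * d_sub + (m - 1) * gap
      subs <- data.frame(
        start = t + (seq_len(m) - 1L) * (d_sub + gap),
        end = t + (seq_len(m) - 1L) * (d_sub + gap) + d_sub,
        frac0 = (seq_len(m) - 1L) / m, frac1 = seq_len(m) / m)
      phases[[length(phases) + 1L]] <- list(step = s, type = "move",
                                            primitive = prim, waypoint = wp,
                                            start = t, end = t + total,
                                            from = cur, to = tgt, subs = subs,
                                            n_submovements = m,
                                            bump_peak = 1.875 * (L / m) / d_sub)
      t <- t + total
      cur <- tgt
      prev_move <- TRUE
    }
  }
  # short settling tail
  phases[[length(phases) + 1L]] <- list(step = NA_integer_, type = "pause",
                                        primitive = NA_character_,
                                        waypoint = NA_character_,
                                        start = t, end = t + 0.5,
                                        from = cur, to = cur)
  list(phases = phases, go_cue_s = go_cue_s, total_s = t + 0.5)
}

# Evaluate end-effector position and trunk fraction at time t for a timeline.
eval_timeline <- function(tl, times, curvature_gain, trunk_lean_deg) {
  n <- length(times)
  pos <- matrix(NA_real_, n, 3)
  lean <- numeric(n)
  lean_from <- 0
  for (ph in tl$phases) {
    idx <- which(times >= ph$start & times <= ph$end)
    if (ph$type != "move") {
      if (length(idx)) {
        pos[idx, ] <- matrix(ph$from, length(idx), 3, byrow = TRUE)
        lean[idx] <- lean_from
      }
      next
    }
    lean_to <- if (vnorm(ph$to - tl$phases[[1]]$from) > 1e-9) 1 else 0
    if (length(idx)) {
      tt <- times[idx]
      chord <- ph$to - ph$from
      Lc <- vnorm(chord)
      frac <- numeric(length(tt))
      for (k in seq_len(nrow(ph$subs))) {
        s0 <- ph$subs$start[k]; s1 <- ph$subs$end[k]
        frac[tt > s1] <- ph$subs$frac1[k]
        inside <- tt >= s0 & tt <= s1
        frac[inside] <- ph$subs$frac0[k] +
          (ph$subs$frac1[k] - ph$subs$frac0[k]) * mj_s((tt[inside] - s0) / (s1 - s0))
      }
      p <- matrix(ph$from, length(tt), 3, byrow = TRUE) + outer(frac, chord)
      if (curvature_gain != 0 && Lc > 1e-9) {
        nvec <- c(chord[3], 0, -chord[1])      # horizontal normal to the chord
        nvec <- if (vnorm(nvec) < 1e-9) c(0, 0, 1) else unit(nvec)
        tau <- (tt - ph$start) / (ph$end - ph$start)
        # bell-shaped lateral bump: zero slope at the boundaries, so the
        # deviation does not blur movement onsets and offsets
        p <- p + outer(curvature_gain * Lc * sin(pi * tau)^2, nvec)
      }
      pos[idx, ] <- p
      tau_ph <- (tt - ph$start) / (ph$end - ph$start)
      lean[idx] <- lean_from + (lean_to - lean_from) * mj_s(tau_ph)
    }
    lean_from <- lean_to
  }
  # rounding can push the last grid sample past the final phase end
  for (i in seq_len(n)) {
    if (is.na(pos[i, 1]) && i > 1L) {
      pos[i, ] <- pos[i - 1L, ]
      lean[i] <- lean[i - 1L]
    }
  }
  list(position = pos, q0_deg = lean * trunk_lean_deg)
}

#' Simulate one protocol trial
#'
#' Concatenates minimum-jerk movement segments along the skill's primitive
#' flow, with 1.5 s idle/stabilize dwells (strictly above the 1 s stability
#' rule) and 0.35 s inter-movement pauses. Impairment injects sub-movement
#' fragmentation, reaction delay, trunk lean (which displaces the shoulder but
#' not the task path), lateral path curvature and speed scaling. Joint angles
#' q0-q7 consistent with the end-effector path are produced by inverse
#' kinematics (elbow-down swivel); ground-truth phase boundaries, the go cue
#' and analytic 10%-of-peak onset times are recorded.
#'
#' @param skill Motor skill name.
#' @param layout [build_target_layout()].
#' @param geom [arm_geometry()].
#' @param impair [impairment_params()].
#' @param rate Kinematic sampling rate (Hz, default 100).
#' @param movement_duration_s Base (self-selected) movement duration.
#' @param idle_dwell_s Idle/stabilize dwell duration (> 1 s).
#' @param inter_dwell_s Pause between chained movements (< 1 s).
#' @param trunk_height_m Trunk pivot to shoulder distance.
#' @return Object of class `ulb_trial`: list with `time`, `rate`, `position`,
#'   `q` (degrees), `trunk` (marker trace), `go_cue_s`, `skill`, `layout`,
#'   `geom`, `impairment`, `ground_truth`.
#' @export
synth_trial <- function(skill, layout, geom, impair = impairment_params(),
                        rate = 100, movement_duration_s = 1.0,
                        idle_dwell_s = 1.5, inter_dwell_s = 0.35,
                        trunk_height_m = 0.45) {
  stopifnot(inherits(layout, "ulb_layout"), inherits(geom, "ulb_geometry"))
  tl <- with_seed(impair$seed,
                  build_timeline(skill, layout, impair, movement_duration_s,
                                 idle_dwell_s, inter_dwell_s))
  n <- round(tl$total_s * rate) + 1L
  time <- (seq_len(n) - 1L) / rate
  ev <- eval_timeline(tl, time, impair$curvature_gain, impair$trunk_lean_deg)
  q <- t(vapply(seq_len(n), function(i)
    ik_arm(ev$position[i, ], ev$q0_deg[i], geom, layout$shoulder_height_m,
           trunk_height_m),
    numeric(8)))
  colnames(q) <- paste0("q", 0:7)
  # trunk marker: the shoulder point, leaning about the trunk pivot
  pivot <- c(0, layout$shoulder_height_m - trunk_height_m, 0)
  trunk <- t(vapply(deg2rad(ev$q0_deg), function(a)
    pivot + as.numeric(rot_z(-a) %*% c(0, trunk_height_m, 0)), numeric(3)))
  gt_rows <- Filter(function(ph) ph$type %in% c("hold", "move"), tl$phases)
  # analytic 10%-of-trial-peak crossing for each movement's first bump: the
  # onset-detection convention references the post-cue peak speed
  vmax <- max(vapply(gt_rows, function(ph) ph$bump_peak %||% 0, numeric(1)))
  gt <- do.call(rbind, lapply(gt_rows, function(ph) {
    onset <- NA_real_
    if (ph$type == "move") {
      rhs <- 0.10 * vmax / ph$bump_peak * 1.875
      if (rhs < 1.875) {
        tau <- stats::uniroot(function(x) 30 * x^2 * (1 - x)^2 - rhs,
                              c(1e-9, 0.5), tol = 1e-10)$root
        onset <- ph$subs$start[1] + tau * (ph$subs$end[1] - ph$subs$start[1])
      }
    }
    data.frame(step = ph$step, primitive = ph$primitive,
               waypoint = ph$waypoint, start_s = ph$start, end_s = ph$end,
               onset_10pct_s = onset,
               n_submovements = ph$n_submovements %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
  # template holds extend to the next movement start in the emitted series
  structure(list(time = time, rate = rate, position = ev$position, q = q,
                 trunk = trunk, trunk_pivot = pivot, go_cue_s = tl$go_cue_s,
                 skill = skill, layout = layout, geom = geom,
                 impairment = impair,
                 ground_truth = list(segments = gt, go_cue_s = tl$go_cue_s,
                                     params = unclass(impair))),
            class = "ulb_trial")
}

#' @export
print.ulb_trial <- function(x, ...) {
  cat(sprintf("Synthetic trial: %s, %.1f s @ %g Hz, go cue %.2f s%s\n",
              x$skill, max(x$time), x$rate, x$go_cue_s,
              if (!is.null(x$emg)) sprintf(", EMG %d ch @ %g Hz",
                                           ncol(x$emg$data), x$emg$rate) else ""))
  invisible(x)
}

# muscle roles for burst synthesis (phenomenological)
muscle_roles <- function() {
  list(agonist = c("anterior_deltoid", "pectoralis_major", "biceps_brachii",
                   "brachioradialis"),
       antagonist = c("triceps_brachii", "posterior_deltoid"),
       stabilizer = c("trapezius_descendens", "medial_deltoid", "pronator_teres"))
}

#' Synthesize surface EMG for a simulated trial
#'
#' Per-muscle activation envelopes (smooth raised-cosine bursts aligned to the
#' movement segments; antagonist bursts scaled by the co-contraction gain)
#' amplitude-modulate band-limited (20-450 Hz) Gaussian carrier noise.
#' Muscle-onset times are recorded in the ground truth; the output is
#' deterministic under the impairment seed.
#'
#' @param trial [synth_trial()] result.
#' @param muscles Channel subset of [target_muscles()].
#' @param impair [impairment_params()] (defaults to the trial's).
#' @param rate EMG sampling rate (Hz, default 1000).
#' @param burst_mv Burst amplitude (mV) of agonist bursts.
#' @param baseline Resting envelope level relative to the burst.
#' @param ramp_s Burst rise/fall time.
#' @return The trial with `$emg` ([emg_recording()]) attached;
#'   `trial$ground_truth$emg` holds the true envelopes (`muscles` x samples),
#'   onset times and parameters.
#' @export
synth_emg <- function(trial, muscles = target_muscles(),
                      impair = trial$impairment, rate = 1000, burst_mv = 0.5,
                      baseline = 0.05, ramp_s = 0.02) {
  unknown <- setdiff(muscles, target_muscles())
  if (length(unknown))
    stop("unknown muscle name(s): ", paste(unknown, collapse = ", "))
  gt <- trial$ground_truth$segments
  moves <- gt[gt$primitive %in% movement_primitives() & !is.na(gt$start_s), ,
              drop = FALSE]
  n <- round(max(trial$time) * rate) + 1L
  tt <- (seq_len(n) - 1L) / rate
  roles <- muscle_roles()
  ramp <- function(t, t0, t1) {
    # raised-cosine plateau burst on [t0, t1]
    y <- numeric(length(t))
    up <- t >= t0 & t < t0 + ramp_s
    y[up] <- (1 - cos(pi * (t[up] - t0) / ramp_s)) / 2
    y[t >= t0 + ramp_s & t <= t1 - ramp_s] <- 1
    dn <- t > t1 - ramp_s & t <= t1
    y[dn] <- (1 - cos(pi * (t1 - t[dn]) / ramp_s)) / 2
    y
  }
  onsets <- numeric(nrow(moves))
  env_unit <- matrix(baseline, n, 1)[, rep(1, length(muscles)), drop = FALSE]
  colnames(env_unit) <- muscles
  gain <- impair$emg_cocontraction_gain
  for (k in seq_len(nrow(moves))) {
    t0 <- if (k == 1L) trial$go_cue_s + impair$emg_onset_latency_s
          else moves$start_s[k] - 0.03
    t1 <- moves$end_s[k]
    onsets[k] <- t0
    b <- ramp(tt, t0, t1)
    # antagonists mix an in-phase burst (co-contraction) with an off-phase
    # braking burst just after the movement: gain 1 duplicates the agonist
    # envelope, gain 0 makes the two supports disjoint
    b_off <- ramp(tt, t1 + 0.02, min(t1 + 0.32, max(tt)))
    for (m in muscles) {
      bm <- if (m %in% roles$antagonist) gain * b + (1 - gain) * b_off
            else if (m %in% roles$stabilizer) 0.5 * b
            else b
      env_unit[, m] <- pmax(env_unit[, m], baseline + (1 - baseline) * bm)
    }
  }
  nyq <- rate / 2
  bf <- signal::butter(4, c(20, min(450, 0.95 * nyq)) / nyq, type = "pass")
  data <- with_seed(impair$seed + 7919L, {
    sapply(muscles, function(m) {
      carrier <- filtfilt_padded(bf, stats::rnorm(n))
      carrier <- carrier / stats::sd(carrier)
      env_unit[, m] * burst_mv * carrier + stats::rnorm(n, 0, impair$emg_noise_sd)
    })
  })
  colnames(data) <- muscles
  trial$emg <- emg_recording(data, rate = rate, go_cue_s = trial$go_cue_s)
  trial$ground_truth$emg <- list(
    envelopes = env_unit, rate = rate,
    muscle_onset_s = stats::setNames(onsets, paste0("movement_", seq_along(onsets))),
    burst_mv = burst_mv, baseline = baseline, ramp_s = ramp_s)
  trial
}

#' Apply a disturbance to a simulated trial
#'
#' Payload: transport-segment durations are stretched by 10% (a documented
#' toy model of added inertia) and, when EMG is attached, anti-gravity muscle
#' amplitudes are scaled up with the payload mass. Motor perturbation: an
#' additive waveform on the end-effector path per the spec parameters (joint
#' angles are recomputed by inverse kinematics). Cognitive disturbances are
#' metadata only. `kind = "none"` is the identity.
#'
#' @param trial [synth_trial()] result.
#' @param spec [disturbance_spec()].
#' @return The disturbed trial; `trial$disturbance` records the spec verbatim.
#' @export
apply_disturbance <- function(trial, spec) {
  spec <- disturbance_spec(spec$kind,
                           payload_kg = spec$payload_kg %||% NULL,
                           direction = spec$direction %||% NULL,
                           magnitude = spec$magnitude %||% NULL,
                           frequency_hz = spec$frequency_hz %||% NULL,
                           waveform = spec$waveform %||% NULL,
                           description = spec$description %||% NULL)
  if (identical(spec$kind, "none")) return(trial)
  trial$disturbance <- spec
  if (spec$kind == "payload") {
    trial <- warp_transports(trial, factor = 1.1)
    if (!is.null(trial$emg)) {
      anti_grav <- intersect(c("anterior_deltoid", "biceps_brachii",
                               "medial_deltoid"), colnames(trial$emg$data))
      trial$emg$data[, anti_grav] <-
        trial$emg$data[, anti_grav] * (1 + 0.5 * spec$payload_kg)
    }
  } else if (spec$kind == "motor_perturbation") {
    dir <- unit(as.numeric(spec$direction))
    dev <- spec$magnitude * sin(2 * pi * spec$frequency_hz * trial$time)
    trial$position <- trial$position + outer(dev, dir)
    trial$q <- t(vapply(seq_along(trial$time), function(i)
      ik_arm(trial$position[i, ], trial$q[i, 1], trial$geom,
             trial$layout$shoulder_height_m), numeric(8)))
    colnames(trial$q) <- paste0("q", 0:7)
  }
  trial
}

# piecewise-linear time warp stretching transport ground-truth segments
warp_transports <- function(trial, factor = 1.1) {
  gt <- trial$ground_truth$segments
  tr <- gt[gt$primitive == "transport" & !is.na(gt$start_s), , drop = FALSE]
  if (!nrow(tr)) return(trial)
  knots <- sort(unique(c(0, tr$start_s, tr$end_s, max(trial$time))))
  new_knots <- knots
  shift <- 0
  for (i in seq_len(nrow(tr))) {
    d <- tr$end_s[i] - tr$start_s[i]
    sel <- knots >= tr$end_s[i] - 1e-12
    new_knots[sel] <- new_knots[sel] + d * (factor - 1)
  }
  warp <- stats::approxfun(knots, new_knots, rule = 2)
  unwarp <- stats::approxfun(new_knots, knots, rule = 2)
  new_total <- warp(max(trial$time))
  new_time <- seq(0, new_total, by = 1 / trial$rate)
  old_at <- unwarp(new_time)
  resample <- function(m) apply(as.matrix(m), 2, function(col)
    stats::approx(trial$time, col, xout = old_at, rule = 2)$y)
  trial$position <- resample(trial$position)
  trial$q <- resample(trial$q)
  colnames(trial$q) <- paste0("q", 0:7)
  trial$trunk <- resample(trial$trunk)
  trial$time <- new_time
  gt$start_s <- warp(gt$start_s)
  gt$end_s <- warp(gt$end_s)
  gt$onset_10pct_s <- ifelse(is.na(gt$onset_10pct_s), NA, warp(gt$onset_10pct_s))
  trial$ground_truth$segments <- gt
  trial
}

#' Write a simulated trial set to disk (kinematics CSV, EMG CSV, ground truth
#' and worksheet JSON)
#'
#' @param dir Output directory (created if needed).
#' @param skill Motor skill.
#' @param n_repetitions Number of repetitions to simulate.
#' @param impair [impairment_params()]; repetition r uses `seed + r`.
#' @param geom,layout Geometry and layout (defaults: 0.30/0.25 m arm,
#'   shoulder 0.30 m above the desk, rest-height targets).
#' @param emg Attach synthetic EMG.
#' @return Invisibly, the list of written file paths.
#' @export
simulate_dataset <- function(dir, skill = "anterior_reaching_rest_height",
                             n_repetitions = 8,
                             impair = impairment_params(),
                             geom = arm_geometry(0.30, 0.25),
                             layout = build_target_layout(geom, 0.30),
                             emg = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (r in seq_len(n_repetitions)) {
    imp <- impair
    imp$seed <- impair$seed + r
    tr <- synth_trial(skill, layout, geom, imp)
    if (emg) tr <- synth_emg(tr)
    kin <- file.path(dir, sprintf("rep%02d_kin.csv", r))
    write_kinematics_csv(tr$time, kin, q = tr$q,
                         markers = list(end_effector = tr$position,
                                        trunk = tr$trunk),
                         rate = tr$rate)
    write_sidecar(kin, list(rate_hz = tr$rate, go_cue_s = tr$go_cue_s,
                            skill = skill,
                            units = list(time = "s", angles = "deg",
                                         positions = "m")))
    paths <- c(paths, kin)
    if (emg) {
      ep <- file.path(dir, sprintf("rep%02d_emg.csv", r))
      write_emg_csv(tr$emg, ep)
      paths <- c(paths, ep)
    }
    gtp <- file.path(dir, sprintf("rep%02d_truth.json", r))
    jsonlite::write_json(trial_truth_for_json(tr), gtp, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, gtp)
  }
  ws <- list(system = "subject_only",
             subject = list(upper_arm_cm = geom$upper_arm_m * 100,
                            forearm_cm = geom$forearm_m * 100,
                            dominant_arm = geom$dominant_arm,
                            evaluated_arm = geom$evaluated_arm),
             skills = list(list(name = skill, repetitions = n_repetitions)),
             outcomes = if (emg) c("kinematics", "emg") else "kinematics")
  wsp <- file.path(dir, "worksheet.json")
  jsonlite::write_json(ws, wsp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, wsp))
}

trial_truth_for_json <- function(tr) {
  gt <- tr$ground_truth
  list(segments = gt$segments, go_cue_s = gt$go_cue_s, params = gt$params,
       muscle_onset_s = gt$emg$muscle_onset_s %||% NULL)
}
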