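test_that("minimum-jerk segments are boundary-matched and symmetric", {
  mj <- min_jerk(c(0.1, 0, 0.2), c(0.4, 0.1, 0.2), duration = 1, rate = 100)
  n <- nrow(mj$position)
  expect_equal(mj$position[1, ], c(0.1, 0, 0.2))
  expect_equal(mj$position[n, ], c(0.4, 0.1, 0.2))
  # midpoint of the chord at tau = 0.5
  expect_equal(mj$position[(n + 1) / 2, ], c(0.25, 0.05, 0.2), tolerance = 1e-9)
  expect_equal(mj$speed[1], 0); expect_equal(mj$speed[n], 0)
  L <- vnorm_test(c(0.3, 0.1, 0))
  expect_equal(max(mj$speed), 1.875 * L, tolerance = 1e-4)
  # degenerate zero-length movement stays put
  still <- min_jerk(c(0, 0, 0), c(0, 0, 0), 1, 100)
  expect_true(all(still$position == 0))
})

test_that("the emitted joint angles are inverse-kinematics consistent", {
  tr <- clean_trial()
  idx <- seq(1, nrow(tr$position), by = 25)
  for (i in idx) {
    fk <- forward_kinematics(tr$q[i, ], tr$geom)
    # fk origin is the upright shoulder; world origin is A on the desk
    p_world <- fk$end_effector + c(0, tr$layout$shoulder_height_m, 0)
    expect_equal(p_world, unname(tr$position[i, ]), tolerance = 1e-6)
  }
})

test_that("a zero-impairment trial achieves the analytic indicator values", {
  tr <- clean_trial()
  seg <- segment_trial(tr)
  pis <- compute_kin_pis(tr, seg)
  val <- function(p) pis$value[pis$pi == p]
  expect_true(all(val("number_of_velocity_peaks") == 1))
  expect_true(all(abs(val("path_length_ratio") - 1) < 0.01))
  expect_true(all(abs(val("normalized_dimensionless_jerk") - 720) < 0.02 * 720))
  expect_true(all(abs(val("movement_arrest_period_ratio") - 0.827) < 0.01))
  expect_identical(val("number_of_movement_stops"), 0)
  expect_identical(val("success_rate"), 1)
})

test_that("sub-movement fragmentation yields the prescribed peaks and stops", {
  g <- std_geom(); lay <- std_layout()
  tr <- synth_trial("anterior_reaching_rest_height", lay, g,
                    impairment_params(n_submovements = 3, seed = 14))
  seg <- segment_trial(tr)
  expect_identical(nrow(seg), 7L)
  sp <- trajectory_speed(tr$position, tr$rate)
  reach <- seg[seg$step == 2, ]
  idx <- (round(reach$start_s * tr$rate) + 1):(round(reach$end_s * tr$rate) + 1)
  sm <- smoothness_pis(tr$position[idx, ], sp[idx], tr$rate)
  expect_identical(sm$value[sm$pi == "number_of_velocity_peaks"], 3)
  expect_identical(count_movement_stops(sp, tr$rate, reach$start_s,
                                        reach$end_s), 2L)
})

test_that("injected trunk lean shows up in the validity check", {
  g <- std_geom(); lay <- std_layout()
  tr <- synth_trial("anterior_reaching_rest_height", lay, g,
                    impairment_params(trunk_lean_deg = 25, seed = 15))
  ta <- trunk_angle(tr$trunk, base = tr$trunk_pivot)
  expect_equal(max(ta$sagittal_deg), 25, tolerance = 0.5)
  v <- check_validity(ta$sagittal_deg, ta$frontal_deg)
  expect_false(v$valid)
  expect_identical(v$reasons, "trunk_sagittal")
  # a modest lean stays valid
  tr2 <- synth_trial("anterior_reaching_rest_height", lay, g,
                     impairment_params(trunk_lean_deg = 10, seed = 15))
  ta2 <- trunk_angle(tr2$trunk, base = tr2$trunk_pivot)
  expect_true(check_validity(ta2$sagittal_deg, ta2$frontal_deg)$valid)
})

test_that("synthetic EMG reproduces co-contraction, onsets and determinism", {
  g <- std_geom(); lay <- std_layout()
  base <- synth_trial("anterior_reaching_rest_height", lay, g,
                      impairment_params(seed = 16, emg_cocontraction_gain = 1))
  tr <- synth_emg(base)
  env <- tr$ground_truth$emg$envelopes
  # gain 1: identical agonist/antagonist envelopes, CCI exactly 100
  expect_equal(cocontraction_index(env[, "biceps_brachii"],
                                   env[, "triceps_brachii"]), 100)
  # and the measured CCI from the conditioned recording is high
  cond <- condition_emg(tr$emg)
  cci <- cocontraction_index(cond$envelope[, "biceps_brachii"],
                             cond$envelope[, "triceps_brachii"])
  expect_gt(cci, 85)
  # gain 0: disjoint bursts push measured CCI far down
  tr0 <- synth_emg(synth_trial("anterior_reaching_rest_height", lay, g,
                               impairment_params(seed = 16,
                                                 emg_cocontraction_gain = 0)))
  cond0 <- condition_emg(tr0$emg)
  cci0 <- cocontraction_index(cond0$envelope[, "biceps_brachii"],
                              cond0$envelope[, "triceps_brachii"])
  expect_lt(cci0, cci / 2)
  # injected first-burst latency recovered by the TKEO detector
  lat <- impairment_params(seed = 17, emg_onset_latency_s = 0.12)
  trl <- synth_emg(synth_trial("anterior_reaching_rest_height", lay, g, lat))
  condl <- condition_emg(trl$emg)
  on <- muscle_onset(condl$filtered$data[, "anterior_deltoid"],
                     trl$emg$rate, go_cue_s = trl$go_cue_s)
  expect_true(on$detected)
  expect_lt(abs(on$latency_s - 0.12), 0.015)
  expect_error(synth_emg(base, muscles = c("biceps_brachii", "soleus")),
               "unknown muscle")
})

test_that("identical seeds give bit-identical trials; different seeds differ", {
  g <- std_geom(); lay <- std_layout()
  imp <- impairment_params(n_submovements = 2, curvature_gain = 0.05,
                           duration_jitter_s = 0.05, seed = 18)
  a <- synth_emg(synth_trial("move_objects_rest_height", lay, g, imp))
  b <- synth_emg(synth_trial("move_objects_rest_height", lay, g, imp))
  expect_identical(a$position, b$position)
  expect_identical(a$q, b$q)
  expect_identical(a$emg$data, b$emg$data)
  imp2 <- imp; imp2$seed <- 19L
  c <- synth_emg(synth_trial("move_objects_rest_height", lay, g, imp2))
  expect_false(identical(a$emg$data, c$emg$data))
})

test_that("payload disturbance stretches transports; perturbation leaves its tone", {
  g <- std_geom(); lay <- std_layout()
  tr <- synth_trial("move_objects_rest_height", lay, g,
                    impairment_params(seed = 20))
  # identity for kind = none
  same <- apply_disturbance(tr, disturbance_spec("none"))
  expect_identical(same$position, tr$position)
  # payload: transport durations x 1.1 (documented toy model)
  pay <- apply_disturbance(tr, disturbance_spec("payload", payload_kg = 0.5))
  gt0 <- tr$ground_truth$segments
  gt1 <- pay$ground_truth$segments
  is_tr <- gt0$primitive == "transport"
  d0 <- gt0$end_s[is_tr] - gt0$start_s[is_tr]
  d1 <- gt1$end_s[is_tr] - gt1$start_s[is_tr]
  expect_equal(d1, 1.1 * d0, tolerance = 1e-9)
  other <- gt0$primitive == "reach_for_grasp"
  expect_equal(gt1$end_s[other] - gt1$start_s[other],
               gt0$end_s[other] - gt0$start_s[other], tolerance = 1e-9)
  # segmentation still recovers the warped boundaries
  segw <- segment_trial(pay)
  expect_identical(nrow(segw), 12L)
  moves <- segw$primitive %in% c("reach_for_grasp", "transport", "reposition")
  expect_true(all(abs(segw$start_s[moves] - gt1$start_s[moves]) <= 0.06))
  # sinusoidal motor perturbation: FFT oracle finds the injected tone
  spec <- disturbance_spec("motor_perturbation", direction = c(0, 0, 1),
                           magnitude = 0.01, frequency_hz = 2)
  per <- apply_disturbance(tr, spec)
  resid <- per$position[, 3] - tr$position[, 3]
  n <- length(resid)
  amp <- Mod(stats::fft(resid))[1:(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) * tr$rate / n
  expect_lt(abs(freqs[which.max(amp)] - 2), 0.1)
  expect_error(apply_disturbance(tr, list(kind = "other")), "description")
})

test_that("simulated datasets are written as readable plain-text files", {
  dir <- withr::local_tempdir()
  paths <- simulate_dataset(dir, n_repetitions = 2,
                            impair = impairment_params(seed = 30))
  expect_true(file.exists(file.path(dir, "worksheet.json")))
  kin <- read_kinematics_csv(file.path(dir, "rep01_kin.csv"))
  expect_identical(ncol(kin$q), 8L)
  expect_true(all(c("end_effector", "trunk") %in% names(kin$markers)))
  rec <- read_emg_csv(file.path(dir, "rep01_emg.csv"))
  expect_identical(ncol(rec$data), 9L)
  expect_gt(rec$go_cue_s, 0)
  truth <- jsonlite::fromJSON(file.path(dir, "rep01_truth.json"))
  expect_identical(nrow(truth$segments), 7L)
})
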