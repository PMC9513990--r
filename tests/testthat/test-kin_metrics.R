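mj_fixture <- function(L = 0.3, D = 1, rate = 100) {
  fixture(sprintf("mj_%g_%g_%g", L, D, rate), function() {
    mj <- min_jerk(c(0, 0, 0), c(L, 0, 0), D, rate)
    mj$speed_measured <- trajectory_speed(mj$position, rate)
    mj
  })
}

semicircle <- function(r = 0.15, n = 400) {
  th <- seq(pi, 0, length.out = n)
  cbind(r + r * cos(th), r * sin(th), 0)
}

test_that("accuracy indicators vanish on the ideal path and match the shoelace oracle", {
  mj <- mj_fixture()
  ideal <- ideal_path(c(0, 0, 0), c(0.3, 0, 0), 1)
  acc <- accuracy_pis(mj$position, ideal)
  expect_equal(acc$value[acc$pi == "trajectory_absolute_error_max"], 0,
               tolerance = 1e-12)
  expect_equal(acc$value[acc$pi == "end_point_error"], 0, tolerance = 1e-12)
  expect_equal(acc$value[acc$pi == "area_index"], 0, tolerance = 1e-9)
  # semicircular detour of radius r: area pi r^2 / 2, against a dense-polygon
  # shoelace oracle
  r <- 0.15
  sc <- semicircle(r)
  oracle <- {
    x <- sc[, 1]; y <- sc[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  expect_equal(oracle, pi * r^2 / 2, tolerance = 1e-3)
  acc2 <- accuracy_pis(sc, ideal_path(sc[1, ], sc[nrow(sc), ], 1))
  expect_equal(acc2$value[acc2$pi == "area_index"], pi * r^2 / 2,
               tolerance = 1e-3)
  expect_equal(acc2$value[acc2$pi == "trajectory_absolute_error_max"], r,
               tolerance = 1e-4)
})

test_that("variable error is the SD of end-point errors and needs repetitions", {
  expect_equal(variable_error(rep(0.01, 8)), 0)
  expect_equal(variable_error(c(0.01, 0.03)), stats::sd(c(0.01, 0.03)))
  expect_warning(ve <- variable_error(0.02), "single repetition")
  expect_true(is.na(ve))
})

test_that("efficiency indicators: straight reach ratio 1, semicircle pi/2", {
  mj <- mj_fixture()
  eff <- efficiency_pis(mj$position, 100)
  expect_equal(eff$value[eff$pi == "path_length_ratio"], 1, tolerance = 1e-6)
  expect_equal(eff$value[eff$pi == "path_traveled"], 0.3, tolerance = 1e-6)
  expect_equal(eff$value[eff$pi == "movement_time"], 1, tolerance = 1e-9)
  # numeric arc-length oracle on the dense semicircle polygon
  sc <- semicircle()
  oracle_ratio <- sum(sqrt(rowSums(diff(sc)^2))) / vnorm_test(sc[nrow(sc), ] - sc[1, ])
  eff2 <- efficiency_pis(sc, 100)
  expect_equal(eff2$value[eff2$pi == "path_length_ratio"], oracle_ratio,
               tolerance = 1e-9)
  expect_equal(oracle_ratio, pi / 2, tolerance = 1e-4)
  # immobile trunk: zero compensation
  trunk <- matrix(rep(c(0, 0.45, 0), each = nrow(mj$position)), ncol = 3)
  eff3 <- efficiency_pis(mj$position, 100, trunk = trunk)
  expect_equal(eff3$value[eff3$pi == "trunk_compensation"], 0, tolerance = 1e-12)
  # zero chord: ratio not computable
  loop <- rbind(sc, sc[rev(seq_len(nrow(sc))), ])
  eff4 <- efficiency_pis(loop, 100)
  expect_true(is.na(eff4$value[eff4$pi == "path_length_ratio"]))
})

test_that("joint-angle correlation hits +/-1 on affinely related profiles", {
  rate <- 100
  t <- seq(0, 1, by = 1 / rate)
  q <- matrix(0, length(t), 8)
  q[, 3] <- 40 + 30 * sin(pi * t)
  q[, 5] <- 2.5 * q[, 3] + 7
  co <- coordination_pis(q, rate)
  expect_equal(co$value[co$pi == "joint_angle_correlation"], 1, tolerance = 1e-9)
  q[, 5] <- -0.8 * q[, 3] + 100
  co <- coordination_pis(q, rate)
  expect_equal(co$value[co$pi == "joint_angle_correlation"], -1, tolerance = 1e-9)
  q[, 5] <- 90
  co <- coordination_pis(q, rate)
  expect_true(is.na(co$value[co$pi == "joint_angle_correlation"]))
})

test_that("time to peak elbow extension matches the generator truth", {
  tr <- clean_trial()
  seg <- segment_trial(tr)
  reach <- seg[seg$step == 2, ]
  idx <- (round(reach$start_s * tr$rate) + 1):(round(reach$end_s * tr$rate) + 1)
  co <- coordination_pis(tr$q[idx, ], tr$rate)
  # full elbow extension is reached at the target, i.e. at the segment end
  ttpe <- co$value[co$pi == "time_to_peak_elbow_extension"]
  expect_gte(ttpe, 1 - 1 / length(idx) - 1e-9)
})

test_that("amplitude indicators: static limb zero, full reach normalizes by arm length", {
  g <- std_geom()
  static <- matrix(rep(c(0.1, 0, 0), each = 60), ncol = 3)
  qs <- matrix(15, 60, 8)
  amp <- amplitude_pis(qs, static, g)
  expect_true(all(amp$value[grepl("joint_range", amp$pi)] == 0))
  expect_equal(amp$value[amp$pi == "maximum_reached_distance"], 0)
  # full-extension reach to B at rest height: layout geometry oracle
  tr <- clean_trial()
  seg <- segment_trial(tr)
  reach <- seg[seg$step == 2, ]
  idx <- (round(reach$start_s * tr$rate) + 1):(round(reach$end_s * tr$rate) + 1)
  amp2 <- amplitude_pis(tr$q[idx, ], tr$position[idx, ], g,
                        trunk = tr$trunk[idx, ])
  oracle <- sqrt(0.55^2 - 0.30^2) / 0.55
  expect_equal(amp2$value[amp2$pi == "normalized_reaching_area"], oracle,
               tolerance = 0.01)
  expect_equal(amp2$value[amp2$pi == "trunk_displacement"], 0, tolerance = 1e-9)
  # elbow 90 -> 180 degrees is a 90 degree ROM
  q_elbow <- matrix(0, 50, 8); q_elbow[, 5] <- seq(90, 180, length.out = 50)
  amp3 <- amplitude_pis(q_elbow, static[1:50, ], g)
  expect_equal(amp3$value[amp3$pi == "joint_range_of_motion_q4"], 90)
})

test_that("planning indicators: symmetric profile peaks at midtime, straight aim is 0", {
  mj <- mj_fixture()
  ideal <- ideal_path(c(0, 0, 0), c(0.3, 0, 0), 1)
  pl <- planning_pis(mj$position, mj$speed_measured, 100, ideal, go_cue_s = 0)
  expect_equal(pl$value[pl$pi == "time_to_peak_velocity"], 0.5, tolerance = 0.01)
  expect_equal(pl$value[pl$pi == "aiming_angle"], 0, tolerance = 1e-6)
  expect_equal(pl$value[pl$pi == "initial_movement_direction_error"], 0,
               tolerance = 1e-6)
  # reaction time equals the 10%-of-peak crossing of the bump
  expect_lt(abs(pl$value[pl$pi == "reaction_time"] - mj_onset_tau_oracle(0.10)),
            0.01)
})

test_that("reaction delay injected by the generator is recovered", {
  g <- std_geom(); lay <- std_layout()
  tr <- synth_trial("anterior_reaching_rest_height", lay, g,
                    impairment_params(reaction_delay_s = 0.15, seed = 5))
  sp <- trajectory_speed(tr$position, tr$rate)
  det <- detect_onset(sp, tr$rate, go_cue_s = tr$go_cue_s)
  gt <- tr$ground_truth$segments
  truth_onset <- gt$onset_10pct_s[2]       # analytic 10% crossing
  expect_lt(abs(det$onset_s - truth_onset), 0.015)
  # and the latency exceeds the injected delay by exactly the crossing offset
  expect_lt(abs(det$onset_s - tr$go_cue_s -
                  (0.15 + mj_onset_tau_oracle(0.10) * 1.0)), 0.015)
})

test_that("smoothness of a pure minimum-jerk reach matches the analytic oracles", {
  mj <- mj_fixture()
  sm <- smoothness_pis(mj$position, mj$speed_measured, 100)
  expect_identical(sm$value[sm$pi == "number_of_velocity_peaks"], 1)
  # NDJ oracle: numeric integral of the squared analytic jerk of
  # 10 tau^3 - 15 tau^4 + 6 tau^5
  tau <- seq(0, 1, length.out = 100001)
  j <- 60 - 360 * tau + 360 * tau^2
  ndj_oracle <- mean(j^2)                 # = integral over [0,1] = 720
  expect_equal(ndj_oracle, 720, tolerance = 1e-3)
  expect_equal(sm$value[sm$pi == "normalized_dimensionless_jerk"], ndj_oracle,
               tolerance = 0.02)
  # MAPR oracle: root-finding on 30 tau^2 (1-tau)^2 = 0.1875
  lo <- stats::uniroot(function(x) 30 * x^2 * (1 - x)^2 - 0.1875, c(0, 0.5))$root
  hi <- stats::uniroot(function(x) 30 * x^2 * (1 - x)^2 - 0.1875, c(0.5, 1))$root
  mapr_oracle <- hi - lo
  expect_equal(mapr_oracle, 0.827, tolerance = 1e-3)
  expect_equal(sm$value[sm$pi == "movement_arrest_period_ratio"], mapr_oracle,
               tolerance = 0.01)
  expect_equal(sm$value[sm$pi == "speed_correlation_to_ideal"], 1,
               tolerance = 1e-4)
})

test_that("SPARC is amplitude-invariant and NDJ time-scale invariant", {
  mj <- mj_fixture()
  sp <- mj$speed_measured
  expect_equal(sparc(sp, 100), sparc(2 * sp, 100), tolerance = 1e-12)
  slow <- min_jerk(c(0, 0, 0), c(0.3, 0, 0), 2, 100)
  expect_equal(normalized_dimensionless_jerk(mj$position, 100),
               normalized_dimensionless_jerk(slow$position, 100),
               tolerance = 0.01)
  big <- min_jerk(c(0, 0, 0), c(0.9, 0, 0), 1, 100)
  expect_equal(normalized_dimensionless_jerk(mj$position, 100),
               normalized_dimensionless_jerk(big$position, 100),
               tolerance = 0.01)
})

test_that("fragmenting a movement raises NDJ and lowers SPARC monotonically", {
  g <- std_geom(); lay <- std_layout()
  vals <- lapply(c(1, 2, 3), function(m) {
    tr <- synth_trial("anterior_reaching_rest_height", lay, g,
                      impairment_params(n_submovements = m, seed = 3))
    seg <- segment_trial(tr)
    reach <- seg[seg$step == 2, ]
    idx <- (round(reach$start_s * tr$rate) + 1):(round(reach$end_s * tr$rate) + 1)
    sp <- trajectory_speed(tr$position, tr$rate)[idx]
    sm <- smoothness_pis(tr$position[idx, ], sp, tr$rate)
    c(ndj = sm$value[sm$pi == "normalized_dimensionless_jerk"],
      sparc = sm$value[sm$pi == "spectral_arc_length"],
      peaks = sm$value[sm$pi == "number_of_velocity_peaks"])
  })
  ndj <- vapply(vals, `[[`, numeric(1), "ndj")
  sal <- vapply(vals, `[[`, numeric(1), "sparc")
  peaks <- vapply(vals, `[[`, numeric(1), "peaks")
  expect_identical(peaks, c(1, 2, 3))
  expect_true(all(diff(ndj) > 0))
  expect_true(all(diff(sal) < 0))
})

test_that("smoothness bounds hold on every movement of an impaired trial", {
  g <- std_geom(); lay <- std_layout()
  tr <- synth_trial("move_objects_rest_height", lay, g,
                    impairment_params(n_submovements = 2, curvature_gain = 0.1,
                                      seed = 9))
  seg <- segment_trial(tr)
  sp <- trajectory_speed(tr$position, tr$rate)
  moves <- seg[seg$primitive %in% c("reach_for_grasp", "transport",
                                    "reposition"), ]
  for (i in seq_len(nrow(moves))) {
    idx <- (round(moves$start_s[i] * tr$rate) + 1):(round(moves$end_s[i] * tr$rate) + 1)
    sm <- smoothness_pis(tr$position[idx, ], sp[idx], tr$rate)
    mapr <- sm$value[sm$pi == "movement_arrest_period_ratio"]
    psr <- sm$value[sm$pi == "peak_speed_ratio"]
    expect_true(mapr >= 0 && mapr <= 1)
    expect_true(psr > 0 && psr <= 1)
    eff <- efficiency_pis(tr$position[idx, ], tr$rate)
    expect_gte(eff$value[eff$pi == "path_length_ratio"], 1)
  }
})

test_that("speed indicators match L/D arithmetic on the canonical reach", {
  mj <- mj_fixture()
  ideal <- ideal_path(c(0, 0, 0), c(0.3, 0, 0), 1)
  spd <- speed_pis(mj$speed_measured, 100, ideal)
  expect_equal(spd$value[spd$pi == "mean_velocity"], 0.3, tolerance = 0.01)
  expect_equal(spd$value[spd$pi == "peak_velocity"], 1.875 * 0.3,
               tolerance = 0.005)
  expect_equal(spd$value[spd$pi == "mean_velocity_variability"], 0,
               tolerance = 0.005)
})

test_that("the full kinematic suite covers the registry for a clean trial", {
  tr <- clean_trial()
  seg <- segment_trial(tr)
  pis <- compute_kin_pis(tr, seg)
  kin_reg <- pi_registry()
  kin_names <- kin_reg$name[kin_reg$domain == "kinematics"]
  base <- unique(sub("(_mean|_max|_q[0-9])$", "", pis$pi))
  missing <- setdiff(setdiff(kin_names, "variable_error"), base)
  expect_identical(missing, character(0))
  # mandatory indicators are present and computable
  mand <- pis[pis$status == "mandatory", ]
  expect_true(all(is.finite(mand$value)))
  # zero-impairment trial: unit success, no stops, straight paths
  expect_equal(pis$value[pis$pi == "success_rate"], 1)
  expect_equal(pis$value[pis$pi == "number_of_movement_stops"], 0)
  expect_true(all(abs(pis$value[pis$pi == "path_length_ratio"] - 1) < 0.01))
})
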