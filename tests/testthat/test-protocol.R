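minimal_sheet <- function() {
  list(system = "subject_only",
       subject = list(upper_arm_cm = 30, forearm_cm = 25),
       skills = list(list(name = "anterior_reaching_rest_height")))
}

test_that("worksheet loading applies defaults and validates ranges with field paths", {
  ws <- load_worksheet(minimal_sheet())
  expect_s3_class(ws, "ulb_worksheet")
  expect_identical(ws$skills[[1]]$repetitions, 8L)      # default repetitions
  expect_identical(ws$object$volume_l, 0.5)
  expect_identical(ws$object$payload_kg, 0)
  expect_identical(ws$disturbance$kind, "none")
  # assistance level outside [-1, 1]
  bad <- minimal_sheet()
  bad$system <- "subject_plus_robot"
  bad$robot <- list(training_modality = "transparent",
                    actuated_dofs = list(list(joint = "elbow", level = -1.5)))
  expect_error(load_worksheet(bad), "actuated_dofs\\[1\\].level.*\\[-1, 1\\]")
  # gravity compensation outside [0, 1]
  bad$robot <- list(training_modality = "transparent",
                    passive_dofs = list(list(joint = "shoulder",
                                             compensation = 1.2)))
  expect_error(load_worksheet(bad), "compensation")
  # unknown training modality
  bad$robot <- list(training_modality = "supervisory")
  expect_error(load_worksheet(bad), "training_modality")
  # seatback outside [100, 110]
  bad2 <- minimal_sheet(); bad2$seatback_deg <- 95
  expect_error(load_worksheet(bad2), "seatback")
  # robot sheet in transparent mode with zero assistance is valid
  ok <- minimal_sheet()
  ok$system <- "subject_plus_robot"
  ok$robot <- list(training_modality = "transparent",
                   actuated_dofs = list(list(joint = "elbow", level = 0)))
  wsr <- load_worksheet(ok)
  expect_identical(classify_environment(wsr)$gravity_mode, "gravity")
})

test_that("the undivided hand-to-mouth worksheet entry expands by object flag", {
  sh <- minimal_sheet()
  sh$skills <- list(list(name = "hand_to_mouth", object_present = TRUE))
  expect_identical(load_worksheet(sh)$skills[[1]]$name,
                   "hand_to_mouth_with_object")
  sh$skills <- list(list(name = "hand_to_mouth"))
  expect_identical(load_worksheet(sh)$skills[[1]]$name,
                   "hand_to_mouth_without_object")
})

test_that("worksheets round-trip through JSON and YAML", {
  ws <- load_worksheet(minimal_sheet())
  jp <- withr::local_tempfile(fileext = ".json")
  write_worksheet(ws, jp)
  back <- load_worksheet(jp)
  expect_equal(back, ws, tolerance = 1e-12)   # numeric fidelity; 30 vs 30L ok
  expect_identical(back$skills, ws$skills)
  yp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(minimal_sheet(), yp)
  expect_equal(load_worksheet(yp)$subject$upper_arm_cm, 30)
})

test_that("disturbance specifications must be quantitative", {
  expect_identical(disturbance_spec("none")$kind, "none")
  expect_identical(disturbance_spec("payload", payload_kg = 0.5)$payload_kg, 0.5)
  expect_error(disturbance_spec("payload"), "payload_kg")
  expect_error(disturbance_spec("motor_perturbation", direction = c(1, 0, 0)),
               "quantitatively")
  expect_error(disturbance_spec("other"), "description")
  ok <- disturbance_spec("motor_perturbation", direction = c(0, 0, 1),
                         magnitude = 0.01, frequency_hz = 2)
  expect_identical(ok$frequency_hz, 2)
})

test_that("target layout reproduces the protocol geometry", {
  g <- std_geom()
  lay <- build_target_layout(g, 0.30, mode = "rest_height")
  expect_equal(lay$reach_m, sqrt(0.55^2 - 0.30^2), tolerance = 1e-12)
  # shoulder-height mode: full arm length
  lay2 <- build_target_layout(g, 0.30, mode = "shoulder_height")
  expect_equal(lay2$reach_m, 0.55, tolerance = 1e-12)
  expect_equal(lay2$points$B[2], 0.30)
  # infeasible geometry
  expect_error(build_target_layout(g, 0.60, mode = "rest_height"),
               "infeasible")
})

test_that("layout angles and distances hold for 1000 random geometries", {
  set.seed(77)
  horiz_angle <- function(u, v) {
    u <- u[c(1, 3)]; v <- v[c(1, 3)]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  for (i in 1:1000) {
    up <- runif(1, 0.22, 0.38); fo <- runif(1, 0.18, 0.32)
    g <- arm_geometry(up, fo)
    h <- runif(1, 0.1, 0.9) * g$arm_length_m
    lay <- build_target_layout(g, h, mode = sample(c("rest_height",
                                                     "shoulder_height"), 1))
    p <- lay$points
    expect_equal(horiz_angle(p$B - p$A, p$C - p$A), 45, tolerance = 1e-9)
    expect_equal(horiz_angle(p$B - p$A, p$D - p$A), 45, tolerance = 1e-9)
    r <- lay$reach_m
    for (w in c("B", "C", "D")) {
      d_h <- sqrt(sum((p[[w]] - c(0, p[[w]][2], 0))^2))
      expect_equal(d_h, r, tolerance = 1e-12)
    }
  }
})

test_that("PI selection respects domains, abilities and mandatory status", {
  ws_kin <- load_worksheet(minimal_sheet())
  sel <- select_pis(ws_kin)
  expect_true(all(sel$domain == "kinematics"))
  kin_mand <- pi_registry()
  kin_mand <- kin_mand$name[kin_mand$status == "mandatory" &
                              kin_mand$domain == "kinematics"]
  expect_true(all(kin_mand %in% sel$name))
  # both domains, mandatory only: the scheme's seven
  both <- minimal_sheet(); both$outcomes <- c("kinematics", "emg")
  ws_both <- load_worksheet(both)
  expect_identical(nrow(select_pis(ws_both, mandatory_only = TRUE)), 7L)
  # power is EMG-only: requesting it on a kinematics-only sheet errors
  expect_error(select_pis(ws_kin, abilities = "power"), "configuration error")
  expect_error(select_pis(ws_kin, abilities = "strength"), "unknown ability")
})

test_that("reports aggregate valid repetitions and flag exclusions", {
  g <- std_geom(); lay <- std_layout()
  ws <- load_worksheet(minimal_sheet())
  make_rep <- function(seed, lean = 0) {
    tr <- synth_trial("anterior_reaching_rest_height", lay, g,
                      impairment_params(trunk_lean_deg = lean, seed = seed))
    seg <- segment_trial(tr)
    ta <- trunk_angle(tr$trunk, base = tr$trunk_pivot)
    list(skill = tr$skill, segments = seg,
         validity = check_validity(ta$sagittal_deg, ta$frontal_deg),
         kin_pis = compute_kin_pis(tr, seg))
  }
  reps <- c(lapply(1:3, make_rep), list(make_rep(4, lean = 25)))
  rep_report <- generate_report(ws, lay, reps)
  expect_identical(rep_report$n_repetitions, 4L)
  expect_identical(rep_report$n_valid, 3L)
  expect_identical(rep_report$exclusions[[1]]$repetition, 4L)
  expect_identical(rep_report$exclusions[[1]]$reasons, "trunk_sagittal")
  agg <- rep_report$pi_table
  expect_true(all(agg$n[agg$status == "mandatory"] >= 3))
  expect_identical(length(rep_report$missing_mandatory), 0L)
  # deterministic serialization: identical inputs, byte-identical reports
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep_report, f1, text = FALSE)
  write_report(generate_report(ws, lay, reps), f2, text = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})
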