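make_rec <- function(x, rate = 1000, muscle = "biceps_brachii") {
  m <- matrix(x, ncol = 1)
  colnames(m) <- muscle
  emg_recording(m, rate = rate)
}

test_that("EMG recordings validate channel names against the muscle registry", {
  m <- matrix(rnorm(200), 100, 2)
  colnames(m) <- c("biceps_brachii", "triceps_brachii")
  expect_s3_class(emg_recording(m, 1000), "ulb_emg")
  colnames(m) <- c("biceps_brachii", "quadriceps")
  expect_error(emg_recording(m, 1000), "unknown muscle")
  colnames(m) <- c("biceps_brachii", "biceps_brachii")
  expect_error(emg_recording(m, 1000), "duplicate")
})

test_that("conditioning notches mains power and warns on low rates", {
  rate <- 2000
  t <- seq(0, 2, by = 1 / rate)
  hum <- sin(2 * pi * 50 * t)
  rec <- make_rec(hum, rate)
  cond <- condition_emg(rec, notch_50hz = TRUE)
  p_in <- mean(hum^2)
  p_out <- mean(cond$filtered$data[, 1]^2)
  expect_lt(p_out / p_in, 0.01)
  # low sampling rate is recorded as a warning, not an error
  lowrec <- make_rec(rnorm(1000), rate = 800)
  cond2 <- condition_emg(lowrec)
  expect_true(any(grepl("below the recommended", cond2$filtered$meta$warnings)))
  # envelopes are nonnegative and peak-normalized by default
  noise <- make_rec(rnorm(4000), 2000)
  env <- condition_emg(noise)$envelope
  expect_true(all(env >= 0))
  expect_equal(max(env), 1, tolerance = 1e-9)
  expect_true(all(env[500:3500, ] > 0))
})

test_that("time-domain features match hand-computed tiny-case oracles", {
  tf <- time_features(c(1, -1, 1, -1))
  expect_equal(tf$waveform_length, 6)
  expect_identical(tf$zero_crossings, 3L)
  expect_equal(tf$average_amplitude_change, 6 / 4)
  expect_equal(tf$dasdv, sqrt(12 / 3))
  expect_equal(tf$rms, 1)
  expect_equal(tf$activation_level, 1)
  # constant signal: no variation at all
  tfc <- time_features(rep(2.5, 50))
  expect_equal(tfc$waveform_length, 0)
  expect_identical(tfc$zero_crossings, 0L)
  expect_identical(tfc$slope_sign_changes, 0L)
  expect_equal(tfc$rms, 2.5)
  expect_equal(tfc$activation_level, 2.5)
  expect_equal(tfc$variance_of_emg, 0)
  # dense sine over k integer periods: RMS -> A/sqrt(2), ZC -> 2k
  A <- 0.8; k <- 5; n <- 5000
  t <- seq(0, k, length.out = n + 1)[1:n]
  s <- A * sin(2 * pi * t + 0.1)          # phase offset avoids exact zeros
  tfs <- time_features(s)
  expect_equal(tfs$rms, A / sqrt(2), tolerance = 1e-3)
  expect_identical(tfs$zero_crossings, as.integer(2 * k))
  # RMS^2 equals VAR on zero-mean signals
  z <- rnorm(1000); z <- z - mean(z)
  tfz <- time_features(z)
  expect_equal(tfz$rms^2, tfz$variance_of_emg, tolerance = 1e-12)
})

test_that("frequency features locate tones and flat spectra correctly", {
  rate <- 2000
  t <- seq(0, 4, by = 1 / rate)
  tone <- sin(2 * pi * 120 * t)
  ff <- frequency_features(tone, rate)
  bin <- rate / 512
  expect_lt(abs(ff$mean_frequency - 120), bin)
  expect_lt(abs(ff$median_frequency - 120), bin)
  expect_gt(ff$power_spectrum_ratio, 0.9)
  # two equal-power tones: MNF at the midpoint (discrete-spectrum oracle)
  two <- sin(2 * pi * 100 * t) + sin(2 * pi * 300 * t)
  ff2 <- frequency_features(two, rate)
  expect_lt(abs(ff2$mean_frequency - 200), 2 * bin)
  # band-limited white noise: frequency ratio near the flat-spectrum integral
  # 40 / 390
  set.seed(33)
  bf <- signal::butter(4, c(20, 450) / (rate / 2), type = "pass")
  wn <- as.numeric(signal::filtfilt(bf, rnorm(rate * 30)))
  ff3 <- frequency_features(wn, rate)
  expect_lt(abs(ff3$frequency_ratio - 40 / 390) / (40 / 390), 0.3)
  # median frequency splits the spectrum into equal halves within one bin
  p <- ff3$power_spectral_density
  below <- sum(p$psd[p$freq <= ff3$median_frequency])
  expect_lt(abs(below / sum(p$psd) - 0.5), 0.02)
  expect_error(frequency_features(tone[1:100], rate), "256")
})

test_that("TKEO onset detection recovers injected burst latencies", {
  rate <- 1000
  set.seed(4)
  n <- 2000
  go_cue <- 0.5
  baseline_sd <- 0.02
  x <- rnorm(n, 0, baseline_sd)
  burst_start <- round((go_cue + 0.12) * rate)
  x[burst_start:(burst_start + 300)] <-
    rnorm(301, 0, 10 * baseline_sd)
  on <- muscle_onset(x, rate, go_cue_s = go_cue)
  expect_true(on$detected)
  expect_lt(abs(on$latency_s - 0.12), 0.015)
  # flat noise: no onset
  expect_false(muscle_onset(rnorm(n, 0, baseline_sd), rate, 0.5)$detected)
  # burst before the cue only: the search is post-cue
  y <- rnorm(n, 0, baseline_sd)
  y[100:300] <- rnorm(201, 0, 10 * baseline_sd)
  expect_false(muscle_onset(y, rate, go_cue_s = 0.5)$detected)
  expect_error(muscle_onset(x, rate, go_cue_s = 0.1), "baseline")
})

test_that("co-contraction index follows the overlap formula and its bounds", {
  e <- c(0.2, 0.8, 1.0, 0.4)
  expect_equal(cocontraction_index(e, e), 100)
  expect_equal(cocontraction_index(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # closed-form check: e2 = e1/2 gives 2*(sum e1/2)/(1.5 sum e1) = 66.7%
  expect_equal(cocontraction_index(e, e / 2), 100 * 2 / 3, tolerance = 1e-9)
  # symmetry
  set.seed(8)
  a <- runif(100); b <- runif(100)
  expect_equal(cocontraction_index(a, b), cocontraction_index(b, a))
  cc <- cocontraction_index(a, b)
  expect_true(cc >= 0 && cc <= 100)
  expect_warning(z <- cocontraction_index(rep(0, 5), rep(0, 5)), "zero")
  expect_true(is.na(z))
})

test_that("coherence is 1 for identical signals and bounded in [0, 1]", {
  rate <- 256
  set.seed(12)
  x <- rnorm(rate * 10)
  coh <- intermuscular_coherence(x, x, rate, segment_s = 1)
  expect_true(all(abs(coh$coherence - 1) < 1e-9))
  expect_equal(coh$band_mean, 1, tolerance = 1e-9)
  # shared band-limited component raises coherence in the shared band
  bf <- signal::butter(4, c(10, 30) / (rate / 2), type = "pass")
  shared <- as.numeric(signal::filtfilt(bf, rnorm(rate * 30)))
  s1 <- shared + 0.5 * rnorm(length(shared))
  s2 <- shared + 0.5 * rnorm(length(shared))
  coh2 <- intermuscular_coherence(s1, s2, rate, band = c(10, 30))
  out_band <- coh2$freq > 50
  expect_gt(coh2$band_mean, mean(coh2$coherence[out_band]))
  expect_true(all(coh2$coherence >= 0 & coh2$coherence <= 1))
  expect_error(suppressWarnings(intermuscular_coherence(x[1:300], x[1:300],
                                                        rate, segment_s = 2)),
               "2 Welch segments")
})

test_that("independent noises stay below the 95% coherence confidence level", {
  # Monte-Carlo oracle at fixed seed: with L = 30 segments the band mean of
  # two independent white noises should sit below 1 - 0.05^(1/(L-1)) in at
  # least 90% of runs
  rate <- 128
  set.seed(99)
  hits <- 0L
  runs <- 10L
  for (r in seq_len(runs)) {
    a <- rnorm(rate * 15.5)
    b <- rnorm(rate * 15.5)
    coh <- intermuscular_coherence(a, b, rate, band = c(5, 50), segment_s = 1)
    expect_gte(coh$n_segments, 30L)
    if (coh$band_mean < coh$confidence_level) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * runs)
})

test_that("the full EMG suite covers the registry on a synthetic recording", {
  tr <- emg_trial()
  cond <- condition_emg(tr$emg)
  pis <- compute_emg_pis(cond, go_cue_s = tr$go_cue_s)
  emg_reg <- pi_registry()
  emg_names <- emg_reg$name[emg_reg$domain == "emg"]
  # spectra and synergies are structured outputs, not scalar table rows
  missing <- setdiff(setdiff(emg_names,
                             c("power_spectral_density", "muscular_synergies")),
                     unique(pis$pi))
  expect_identical(missing, character(0))
  expect_true(all(pis$ability %in% motor_abilities()$name))
  mand <- pis[pis$status == "mandatory", ]
  expect_identical(unique(mand$pi), "activation_level")
  expect_true(all(is.finite(mand$value)))
})
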