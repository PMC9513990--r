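# Surface-EMG conditioning and the EMG performance-indicator suite:
# time-domain features, Welch-based frequency features, TKEO burst onset,
# co-contraction index and intermuscular coherence.

#' Multi-channel surface-EMG recording
#'
#' @param data n x m matrix of amplitudes (mV), one column per muscle; column
#'   names must be drawn from the nine-muscle registry ([target_muscles()])
#'   and be unique.
#' @param rate Sampling rate (Hz).
#' @param go_cue_s Go-cue times (s).
#' @return object of class `ulb_emg`.
#' @export
emg_recording <- function(data, rate, go_cue_s = numeric(0)) {
  data <- as.matrix(data)
  stopifnot(rate > 0)
  chans <- colnames(data)
  if (is.null(chans)) stop("EMG channels must be named")
  if (anyDuplicated(chans)) stop("duplicate EMG channel names")
  unknown <- setdiff(chans, target_muscles())
  if (length(unknown))
    stop("unknown muscle name(s): ", paste(unknown, collapse = ", "),
         "; valid muscles: ", paste(target_muscles(), collapse = ", "))
  structure(list(data = data, rate = rate, channels = chans,
                 go_cue_s = go_cue_s, meta = list()),
            class = "ulb_emg")
}

#' @export
print.ulb_emg <- function(x, ...) {
  cat(sprintf("EMG recording: %d channels x %d samples @ %g Hz (%s)\n",
              ncol(x$data), nrow(x$data), x$rate,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Condition raw EMG and extract linear envelopes
#'
#' Band-pass filtering (Butterworth order 4, zero-phase, 20-450 Hz by
#' default), optional 50 Hz mains notches (fundamental and harmonics), then
#' full-wave rectification and a 5 Hz zero-phase low-pass for the linear
#' envelope. All parameters are echoed into the recording metadata. Rates
#' below 1000 Hz trigger a recorded warning; the band upper edge is capped
#' below Nyquist.
#'
#' @param rec [emg_recording()].
#' @param band Band-pass edges in Hz.
#' @param notch_50hz If `TRUE`, notch out 50 Hz and its harmonics.
#' @param envelope_cutoff_hz Envelope low-pass cutoff.
#' @param normalization "peak" (per-channel peak of trial), "mvc" (requires
#'   `mvc`), or "none".
#' @param mvc Optional named vector of maximum-voluntary-contraction envelope
#'   amplitudes per channel (mV) for MVC normalization.
#' @return list with `filtered` (ulb_emg) and `envelope` (ulb_envelope: matrix
#'   with `normalization` attribute).
#' @export
condition_emg <- function(rec, band = c(20, 450), notch_50hz = FALSE,
                          envelope_cutoff_hz = 5,
                          normalization = c("peak", "mvc", "none"),
                          mvc = NULL) {
  stopifnot(inherits(rec, "ulb_emg"))
  normalization <- match.arg(normalization)
  warnings <- character(0)
  if (rec$rate < 1000)
    warnings <- c(warnings, sprintf(
      "sampling rate %g Hz below the recommended 1000 Hz", rec$rate))
  nyq <- rec$rate / 2
  hi <- min(band[2], 0.99 * nyq)
  if (hi < band[2])
    warnings <- c(warnings, sprintf(
      "band upper edge reduced from %g to %g Hz (Nyquist)", band[2], hi))
  bf <- signal::butter(4, c(band[1], hi) / nyq, type = "pass")
  filt <- apply(rec$data, 2, function(x) filtfilt_padded(bf, x))
  if (notch_50hz) {
    for (f0 in seq(50, floor(0.9 * nyq), by = 50)) {
      nf <- signal::butter(2, c(f0 - 2, f0 + 2) / nyq, type = "stop")
      filt <- apply(filt, 2, function(x) filtfilt_padded(nf, x))
    }
  }
  colnames(filt) <- rec$channels
  env <- apply(abs(filt), 2,
               lowpass_zero_phase, rate = rec$rate,
               cutoff_hz = envelope_cutoff_hz)
  env[env < 0] <- 0                      # filtering undershoot
  colnames(env) <- rec$channels
  env <- normalize_envelope(env, normalization, mvc)
  out_rec <- rec
  out_rec$data <- filt
  out_rec$meta <- list(band_hz = c(band[1], hi), notch_50hz = notch_50hz,
                       envelope_cutoff_hz = envelope_cutoff_hz,
                       butter_order = 4, zero_phase = TRUE,
                       normalization = normalization, warnings = warnings)
  list(filtered = out_rec, envelope = env)
}

normalize_envelope <- function(env, mode, mvc = NULL) {
  if (mode == "peak") {
    pk <- apply(env, 2, max)
    pk[pk == 0] <- 1
    env <- sweep(env, 2, pk, "/")
  } else if (mode == "mvc") {
    if (is.null(mvc)) stop("MVC normalization requires an `mvc` vector")
    env <- sweep(env, 2, mvc[colnames(env)], "/")
    env[env > 1] <- 1
  }
  attr(env, "normalization") <- mode
  env
}

#' Time-domain EMG features of one channel
#'
#' Waveform length, average amplitude change, difference absolute standard
#' deviation value, integrated EMG, RMS, the mandatory activation level (mean
#' absolute value), mean-removed variance, mean-absolute-value slope across
#' sub-segments, and deadbanded zero crossings and slope sign changes.
#'
#' @param x Filtered EMG signal of one channel (mV).
#' @param deadband Amplitude deadband in mV (default 0.01 mV = 10 uV) used by
#'   the zero-crossing and slope-sign-change counts to ignore noise-driven
#'   transitions.
#' @param n_subsegments Number of sub-segments for the MAV slope.
#' @return named list of features (`mavs` is a vector of length
#'   `n_subsegments - 1`).
#' @export
#' @examples
#' time_features(c(1, -1, 1, -1))[c("waveform_length", "zero_crossings")]
time_features <- function(x, deadband = 0.01, n_subsegments = 3) {
  n <- length(x)
  if (n < 2L) stop("need >= 2 samples")
  dx <- diff(x)
  wl <- sum(abs(dx))
  mav <- mean(abs(x))
  sub <- split(x, cut(seq_len(n), n_subsegments, labels = FALSE))
  mavs <- diff(vapply(sub, function(s) mean(abs(s)), numeric(1)))
  # hysteresis zero crossings: transitions between the > +deadband and
  # < -deadband states, so dense sampling of a slow crossing counts once
  st <- sign(x) * (abs(x) > deadband)
  st <- st[st != 0]
  zc <- if (length(st) < 2L) 0L else sum(st[-1] != st[-length(st)])
  d1 <- x[2:(n - 1)] - x[1:(n - 2)]
  d2 <- x[2:(n - 1)] - x[3:n]
  ssc <- if (n < 3L) 0L else
    sum(d1 * d2 > 0 & (abs(d1) > deadband | abs(d2) > deadband))
  list(
    waveform_length = wl,
    average_amplitude_change = wl / n,
    dasdv = sqrt(sum(dx^2) / (n - 1)),
    integrated_emg = sum(abs(x)),
    rms = sqrt(mean(x^2)),
    activation_level = mav,
    variance_of_emg = mean((x - mean(x))^2),
    mean_absolute_value_slope = unname(mavs),
    zero_crossings = zc,
    slope_sign_changes = ssc
  )
}

#' Welch power spectral density estimate
#'
#' Hann-windowed segments with 50% overlap; one-sided density scaled so that
#' the integral of the PSD over frequency equals the signal's mean power.
#'
#' @param x Signal.
#' @param rate Sampling rate (Hz).
#' @param nperseg Samples per segment (auto-shrunk to the signal length with a
#'   warning when the signal is shorter).
#' @param overlap Fractional overlap between segments.
#' @return list with `freq`, `psd`, `n_segments`.
#' @export
welch_psd <- function(x, rate, nperseg = 512, overlap = 0.5) {
  w <- welch_spectra(list(x), rate, nperseg, overlap)
  list(freq = w$freq, psd = Re(w$S[[1]]), n_segments = w$L)
}

# Averaged (cross-)spectra of a list of signals; S[[k]] for auto, attr "cross"
# for the cross-spectrum of two signals.
welch_spectra <- function(signals, rate, nperseg = 512, overlap = 0.5) {
  n <- length(signals[[1]])
  if (nperseg > n) {
    warning(sprintf("Welch segment length reduced from %d to %d (signal length)",
                    nperseg, n))
    nperseg <- n
  }
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  L <- length(starts)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1)) # Hann
  U <- sum(win^2)
  nf <- nperseg %/% 2L + 1L
  ffts <- lapply(signals, function(x) {
    sapply(starts, function(s0) {
      seg <- x[s0:(s0 + nperseg - 1L)]
      stats::fft((seg - mean(seg)) * win)[1:nf]
    })
  })
  scale <- 1 / (rate * U)
  one_sided <- function(S) {
    S <- S * scale
    if (nperseg %% 2L == 0L) {
      S[2:(nf - 1L)] <- 2 * S[2:(nf - 1L)]
    } else {
      S[2:nf] <- 2 * S[2:nf]
    }
    S
  }
  S_auto <- lapply(ffts, function(X) one_sided(rowMeans(abs(X)^2)))
  S_cross <- if (length(signals) == 2L)
    one_sided(rowMeans(ffts[[1]] * Conj(ffts[[2]]))) else NULL
  list(freq = (seq_len(nf) - 1L) * rate / nperseg, S = S_auto,
       cross = S_cross, L = L)
}

#' Frequency-domain EMG features of one channel
#'
#' From a Welch PSD: mean frequency (power-weighted), median frequency
#' (equal-power split), mean power, the exported spectrum, frequency ratio
#' (low-band over high-band power) and power spectrum ratio (power within
#' `psr_halfwidth_hz` of the spectral peak over total power).
#'
#' @param x Filtered EMG signal (mV).
#' @param rate Sampling rate (Hz).
#' @param nperseg,overlap Welch parameters.
#' @param low_band,high_band Frequency-ratio band split (Hz).
#' @param psr_halfwidth_hz Half-width of the peak neighborhood.
#' @return named list; `power_spectral_density` is a data.frame(freq, psd).
#' @export
frequency_features <- function(x, rate, nperseg = 512, overlap = 0.5,
                               low_band = c(20, 60), high_band = c(60, 450),
                               psr_halfwidth_hz = 10) {
  if (length(x) < 256L) stop("frequency features need >= 256 samples")
  w <- welch_psd(x, rate, nperseg, overlap)
  f <- w$freq; p <- w$psd
  tot <- sum(p)
  mnf <- sum(f * p) / tot
  cum <- cumsum(p) / tot
  mdf <- f[which(cum >= 0.5)[1]]
  band_power <- function(b) sum(p[f >= b[1] & f <= min(b[2], max(f))])
  fr <- band_power(low_band) / band_power(high_band)
  fpk <- f[which.max(p)]
  psr <- band_power(c(fpk - psr_halfwidth_hz, fpk + psr_halfwidth_hz)) / tot
  df <- f[2] - f[1]
  list(mean_frequency = mnf, median_frequency = mdf,
       mean_power = tot * df,
       power_spectral_density = data.frame(freq = f, psd = p),
       frequency_ratio = fr, power_spectrum_ratio = psr)
}

#' EMG burst onset via the Teager-Kaiser energy operator
#'
#' `psi[i] = x[i]^2 - x[i-1] x[i+1]` on the filtered signal, smoothed with a
#' 50 ms moving average; onset is the first post-cue time at which the energy
#' exceeds the pre-cue baseline mean + `k_sd` SD, sustained for at least
#' `sustain_s`. Returns the latency from the go cue, or a no-onset outcome.
#'
#' @param x Filtered single-channel EMG (mV).
#' @param rate Sampling rate (Hz).
#' @param go_cue_s Go-cue time (s); at least `baseline_s` of pre-cue baseline
#'   is required.
#' @param baseline_s Baseline window before the cue.
#' @param smooth_s Moving-average window on the energy.
#' @param k_sd Threshold in baseline SDs above the baseline mean.
#' @param sustain_s Minimum supra-threshold dwell.
#' @return list with `detected` and `latency_s` (NA when no onset).
#' @export
muscle_onset <- function(x, rate, go_cue_s, baseline_s = 0.2, smooth_s = 0.05,
                         k_sd = 3, sustain_s = 0.025) {
  if (go_cue_s < baseline_s)
    stop("need at least ", baseline_s, " s of pre-cue baseline")
  n <- length(x)
  psi <- c(0, x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n], 0)
  # causal (trailing) moving average: a centered window would leak burst
  # energy backwards and bias the onset early
  k <- max(1L, round(smooth_s * rate))
  cs <- cumsum(c(0, psi))
  i <- seq_len(n)
  lo <- pmax(i - k + 1L, 1L)
  psm <- (cs[i + 1L] - cs[lo]) / (i - lo + 1L)
  i_cue <- round(go_cue_s * rate) + 1L
  ib <- max(1L, i_cue - round(baseline_s * rate)):(i_cue - 1L)
  # SD of the raw (unsmoothed) energy: thresholding the smoothed trace
  # against it suppresses chance excursions of the correlated smoothed series
  thr <- mean(psm[ib]) + k_sd * stats::sd(psi[ib])
  above <- psm > thr
  above[seq_len(i_cue - 1L)] <- FALSE
  runs <- true_runs(above)
  need <- max(1L, round(sustain_s * rate))
  runs <- runs[(runs$end - runs$start + 1L) >= need, , drop = FALSE]
  if (!nrow(runs)) return(list(detected = FALSE, latency_s = NA_real_))
  list(detected = TRUE, latency_s = (runs$start[1] - 1L) / rate - go_cue_s)
}

#' Co-contraction index of an agonist/antagonist envelope pair
#'
#' Percentage of overlapping activity of the two EMG linear envelopes
#' (Falconer-Winter form): `CCI = 100 * 2 sum(min(e1, e2)) / sum(e1 + e2)`.
#' Symmetric in its arguments and bounded in `[0, 100]`. Both envelopes must
#' share the same normalization mode.
#'
#' @param env_agonist,env_antagonist Nonnegative envelope series.
#' @return Percentage in `[0, 100]`; `NA` (with warning) when both envelopes
#'   are identically zero.
#' @export
#' @examples
#' cocontraction_index(c(1, 1, 0, 0), c(0, 0, 1, 1))  # disjoint: 0
cocontraction_index <- function(env_agonist, env_antagonist) {
  stopifnot(length(env_agonist) == length(env_antagonist),
            all(env_agonist >= 0), all(env_antagonist >= 0))
  denom <- sum(env_agonist) + sum(env_antagonist)
  if (denom <= 0) {
    warning("co-contraction index not computable: both envelopes are zero")
    return(NA_real_)
  }
  100 * 2 * sum(pmin(env_agonist, env_antagonist)) / denom
}

#' Magnitude-squared intermuscular coherence
#'
#' `C(f) = |S12(f)|^2 / (S11(f) S22(f))` from Welch-averaged spectra (1-s Hann
#' segments, 50% overlap). Also reports the band-averaged coherence over
#' `band` and the 95% confidence level `1 - 0.05^(1/(L-1))` for L averaged
#' segments, below which coherence is not distinguishable from independence.
#'
#' @param sig1,sig2 Filtered EMG signals (mV).
#' @param rate Sampling rate (Hz).
#' @param band Frequency band (Hz) for the band-averaged value.
#' @param segment_s Welch segment duration (s).
#' @param overlap Fractional overlap.
#' @return list with `freq`, `coherence`, `band_mean`, `confidence_level`,
#'   `n_segments`.
#' @export
intermuscular_coherence <- function(sig1, sig2, rate, band = c(5, 50),
                                    segment_s = 1, overlap = 0.5) {
  nperseg <- round(segment_s * rate)
  w <- welch_spectra(list(sig1, sig2), rate, nperseg, overlap)
  if (w$L < 2L) stop("coherence needs at least 2 Welch segments")
  if (w$L < 8L)
    warning("fewer than 8 Welch segments: coherence estimate is unstable")
  C <- Mod(w$cross)^2 / (Re(w$S[[1]]) * Re(w$S[[2]]))
  C <- clamp(C, 0, 1)
  sel <- w$freq >= band[1] & w$freq <= band[2]
  list(freq = w$freq, coherence = C, band_mean = mean(C[sel]),
       confidence_level = 1 - 0.05^(1 / (w$L - 1)), n_segments = w$L)
}

#' Compute the full EMG indicator suite of a conditioned recording
#'
#' Time-domain and frequency-domain features per muscle, muscle onsets,
#' the agonist/antagonist co-contraction index and intermuscular coherence.
#'
#' @param conditioned Result of [condition_emg()].
#' @param go_cue_s Go-cue time (s) for onset latencies; `NULL` skips onsets.
#' @param agonist,antagonist Muscle pair for co-contraction and coherence
#'   (default biceps/triceps, the reaching pair).
#' @return data.frame with columns `muscle`, `ability`, `pi`, `value`, `units`,
#'   `status` (vector-valued spectra are omitted from the table).
#' @export
compute_emg_pis <- function(conditioned, go_cue_s = NULL,
                            agonist = "biceps_brachii",
                            antagonist = "triceps_brachii") {
  filt <- conditioned$filtered
  env <- conditioned$envelope
  reg <- pi_registry()
  rows <- list()
  add <- function(muscle, pi, value, units) {
    ab <- reg$ability[match(pi, reg$name)]
    st <- reg$status[match(pi, reg$name)]
    rows[[length(rows) + 1L]] <<- data.frame(
      muscle = muscle, ability = ab %||% NA_character_, pi = pi,
      value = as.numeric(value), units = units,
      status = st %||% "recommended", stringsAsFactors = FALSE)
  }
  for (m in filt$channels) {
    x <- filt$data[, m]
    tf <- time_features(x)
    add(m, "waveform_length", tf$waveform_length, "mV")
    add(m, "average_amplitude_change", tf$average_amplitude_change, "mV")
    add(m, "dasdv", tf$dasdv, "mV")
    add(m, "integrated_emg", tf$integrated_emg, "mV")
    add(m, "rms", tf$rms, "mV")
    add(m, "activation_level", tf$activation_level, "mV")
    add(m, "variance_of_emg", tf$variance_of_emg, "mV^2")
    add(m, "mean_absolute_value_slope", mean(tf$mean_absolute_value_slope), "mV")
    add(m, "emg_zero_crossing", tf$zero_crossings, "count")
    add(m, "slope_sign_change", tf$slope_sign_changes, "count")
    if (nrow(filt$data) >= 256L && filt$rate > 100) {
      ff <- frequency_features(x, filt$rate)
      add(m, "mean_frequency", ff$mean_frequency, "Hz")
      add(m, "median_frequency", ff$median_frequency, "Hz")
      add(m, "mean_power", ff$mean_power, "mV^2")
      add(m, "frequency_ratio", ff$frequency_ratio, "ratio")
      add(m, "power_spectrum_ratio", ff$power_spectrum_ratio, "ratio")
    }
    if (!is.null(go_cue_s)) {
      on <- muscle_onset(x, filt$rate, go_cue_s)
      add(m, "muscle_onset", on$latency_s, "s")
    }
  }
  if (all(c(agonist, antagonist) %in% colnames(env))) {
    add(paste(agonist, antagonist, sep = "/"), "cocontraction_index",
        cocontraction_index(env[, agonist], env[, antagonist]), "%")
    coh <- intermuscular_coherence(filt$data[, agonist],
                                   filt$data[, antagonist], filt$rate)
    add(paste(agonist, antagonist, sep = "/"), "intermuscular_coherence",
        coh$band_mean, "msc")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
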