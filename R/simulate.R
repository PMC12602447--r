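#' Simulation configuration
#'
#' Parameters of the synthetic driving-session generator. Defaults emulate
#' the study conditions the pipeline targets: a 45-min monotonous driving
#' task containing 8 one-minute straight-road repetitions, 8-channel EEG at
#' 125 Hz with a subject-specific alpha peak, a 1-min eyes-closed rest with
#' the session-maximal alpha amplitude, and wrist PPG at 64 Hz whose
#' inter-beat intervals carry sinusoidal LF/HF modulation.
#'
#' @param seed default RNG seed used by the generators.
#' @param n_segments number of straight-road repetitions.
#' @param segment_len segment duration, s.
#' @param inter_segment_gap gap between consecutive segments, s. With the
#'   defaults (`lead_in = 60`, gap 270, 8 segments of 60 s) the task spans
#'   exactly 45 min.
#' @param lead_in time from task start to the first segment, s.
#' @param rest_duration eyes-closed rest duration, s (>= 60).
#' @param fs_eeg,fs_ppg sampling rates, Hz.
#' @param iaf individual alpha frequency, Hz, within \[7, 13\].
#' @param alpha_rest_amp eyes-closed parietal alpha amplitude, uV.
#' @param alpha_task_base_amp task parietal alpha amplitude at unit fatigue
#'   envelope, uV.
#' @param noise_1f_scale RMS of the 1/f background noise, uV.
#' @param blink_rate blinks per minute.
#' @param blink_duration blink duration, ms (width at 10% of peak height).
#' @param blink_amplitude blink peak amplitude at AFz, uV.
#' @param gross_artifact_rate supra-threshold artifact bursts per minute.
#' @param mean_hr mean heart rate, bpm.
#' @param lf_freq,hf_freq LF and HF modulation frequencies, Hz.
#' @param lf_amp,hf_amp LF and HF IBI modulation amplitudes, ms.
#' @param ectopic_rate fraction of beats displaced by +/-300 ms.
#' @param hr_surge_bpm heart-rate elevation at the peak of the fatigue
#'   envelope, bpm (0 = no coupling between fatigue and heart rate).
#' @return A list of class `fl_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_segments = 8L, segment_len = 60, inter_segment_gap = 270,
                       lead_in = 60, rest_duration = 60,
                       fs_eeg = 125, fs_ppg = 64,
                       iaf = 10, alpha_rest_amp = 20, alpha_task_base_amp = 4,
                       noise_1f_scale = 10,
                       blink_rate = 15, blink_duration = 200,
                       blink_amplitude = 100,
                       gross_artifact_rate = 0,
                       mean_hr = 70, lf_freq = 0.10, hf_freq = 0.25,
                       lf_amp = 30, hf_amp = 15, ectopic_rate = 0,
                       hr_surge_bpm = 0) {
  cfg <- as.list(environment())
  rates <- c("alpha_rest_amp", "alpha_task_base_amp", "noise_1f_scale",
             "blink_rate", "blink_duration", "blink_amplitude",
             "gross_artifact_rate", "lf_amp", "hf_amp", "ectopic_rate",
             "hr_surge_bpm")
  for (nm in rates) {
    if (cfg[[nm]] < 0) abort(paste0("`", nm, "` must be non-negative."))
  }
  if (iaf < 7 || iaf > 13) abort("`iaf` must lie within [7, 13] Hz.")
  if (rest_duration < 60) abort("`rest_duration` must be at least 60 s.")
  if (n_segments < 1) abort("`n_segments` must be >= 1.")
  structure(cfg, class = "fl_sim_config")
}

#' Build the straight-segment schedule implied by a configuration
#'
#' @param cfg an [sim_config()].
#' @return An [lap_schedule()] with `task_start = 0` and
#'   `task_end = lead_in + n_segments * (segment_len + inter_segment_gap)`.
#' @export
sim_schedule <- function(cfg) {
  pitch <- cfg$segment_len + cfg$inter_segment_gap
  starts <- cfg$lead_in + (seq_len(cfg$n_segments) - 1) * pitch
  lap_schedule(
    tibble::tibble(segment = seq_len(cfg$n_segments),
                   t_start_s = starts,
                   t_end_s = starts + cfg$segment_len),
    task_start = 0,
    task_end = cfg$lead_in + cfg$n_segments * pitch,
    target_len = cfg$segment_len, tol = 1
  )
}

#' Fatigue trajectory (ground truth for the synthetic subject)
#'
#' The envelope multiplies the task parietal alpha amplitude over time; the
#' segment at which it peaks is the ground-truth "high fatigue" repetition
#' the EEG-driven labeling should recover.
#'
#' @param schedule an [lap_schedule()].
#' @param peak_segment segment index at which the envelope is maximal.
#' @param shape `"bump"` (localized surge), `"ramp"` (monotone rise to the
#'   peak, then flat) or `"sigmoid"`.
#' @param base,a_max envelope value away from / at the peak (multipliers of
#'   `alpha_task_base_amp`).
#' @param width_s bump standard deviation / sigmoid time constant, s.
#' @return A list of class `fl_trajectory` with an `envelope(t)` function.
#' @export
fatigue_trajectory <- function(schedule, peak_segment,
                               shape = c("bump", "ramp", "sigmoid"),
                               base = 1, a_max = 3.5, width_s = 90) {
  shape <- match.arg(shape)
  if (!peak_segment %in% schedule$segment) {
    abort("`peak_segment` is not a segment of the schedule.")
  }
  i <- match(peak_segment, schedule$segment)
  t_peak <- (schedule$t_start_s[i] + schedule$t_end_s[i]) / 2
  span <- task_span(schedule)
  envelope <- switch(shape,
    bump = function(t) base + (a_max - base) * exp(-(t - t_peak)^2 / (2 * width_s^2)),
    ramp = function(t) {
      u <- pmin(pmax((t - span[["start"]]) / (t_peak - span[["start"]]), 0), 1)
      base + (a_max - base) * u
    },
    sigmoid = function(t) {
      base + (a_max - base) / (1 + exp(-(t - (t_peak - 2 * width_s)) / width_s))
    }
  )
  mids <- (schedule$t_start_s + schedule$t_end_s) / 2
  if (which.max(envelope(mids)) != i) {
    abort("Envelope is not maximal at `peak_segment` among segment midpoints.")
  }
  structure(list(envelope = envelope, peak_segment = peak_segment,
                 shape = shape, base = base, a_max = a_max),
            class = "fl_trajectory")
}

# 1/f (pink) noise by spectral shaping of white noise; exponent 1 in power,
# normalized to unit RMS.
pink_noise <- function(n) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # fold to two-sided frequency index
  X <- X / sqrt(f)
  y <- Re(fft(X, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Raised-cosine blink pulse. `duration_ms` is the width at 10% of peak
# height (the observable duration the detector reports); the full support is
# correspondingly wider by 1/(1 - acos(0.8)/pi).
blink_support_factor <- function() 1 / (1 - acos(0.8) / pi)

blink_pulse <- function(fs, duration_ms, amplitude) {
  support <- duration_ms / 1000 * blink_support_factor()
  n <- max(3L, round(support * fs))
  tt <- seq_len(n) / (n + 1)
  amplitude * 0.5 * (1 - cos(2 * pi * tt))
}

# Per-channel spatial gains of blink and alpha topographies.
BLINK_GAIN <- c(AFz = 1, AF3 = 0.7, AF4 = 0.7, AF7 = 0.5, AF8 = 0.5,
                Pz = 0.1, P3 = 0.1, P4 = 0.1)
ALPHA_GAIN <- c(AFz = 0.25, AF3 = 0.25, AF4 = 0.25, AF7 = 0.25, AF8 = 0.25,
                Pz = 1, P3 = 1, P4 = 1)

#' Simulate task EEG with known ground truth
#'
#' Generates the 8-channel, 125 Hz recording spanning the task: 1/f
#' background noise, an alpha oscillation at the subject's IAF whose parietal
#' amplitude is `alpha_task_base_amp * envelope(t)` (frontal channels carry
#' 25% of the parietal alpha), frontal-dominant raised-cosine blink
#' transients at Poisson times, and optional supra-threshold artifact bursts.
#'
#' @param cfg an [sim_config()].
#' @param traj an [fatigue_trajectory()].
#' @param schedule an [lap_schedule()]; defaults to [sim_schedule()] of `cfg`.
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return A list with elements `recording` ([recording()]), `blinks`
#'   (tibble `peak_time_s`, `duration_ms`, `amplitude_uv`) and `artifacts`
#'   (tibble `t_start_s`, `t_end_s`, `epoch`).
#' @export
simulate_eeg <- function(cfg, traj, schedule = sim_schedule(cfg),
                         seed = cfg$seed) {
  span <- task_span(schedule)
  dur <- span[["end"]] - span[["start"]]
  fs <- cfg$fs_eeg
  n <- round(dur * fs)
  tt <- span[["start"]] + (seq_len(n) - 1) / fs
  with_seed(seed, {
    mat <- matrix(0, n, length(EEG_CHANNELS),
                  dimnames = list(NULL, EEG_CHANNELS))
    if (cfg$noise_1f_scale > 0) {
      for (j in seq_along(EEG_CHANNELS)) {
        mat[, j] <- cfg$noise_1f_scale * pink_noise(n)
      }
    }
    phase <- runif(1, 0, 2 * pi)
    alpha <- sin(2 * pi * cfg$iaf * tt + phase) *
      (cfg$alpha_task_base_amp * traj$envelope(tt))
    for (j in seq_along(EEG_CHANNELS)) {
      mat[, j] <- mat[, j] + ALPHA_GAIN[[EEG_CHANNELS[j]]] * alpha
    }
    blinks <- draw_blink_times(cfg, span[["start"]], span[["end"]])
    mat <- add_blinks(mat, blinks, fs, span[["start"]], cfg)
    artifacts <- tibble::tibble(t_start_s = numeric(), t_end_s = numeric(),
                                epoch = integer())
    if (cfg$gross_artifact_rate > 0) {
      n_art <- rpois(1, cfg$gross_artifact_rate * dur / 60)
      n_art <- min(n_art, floor(dur) - 2L)
      if (n_art > 0) {
        # one burst strictly inside each of n_art distinct 1-s epochs, so the
        # injected supra-threshold epoch count is exact ground truth
        epochs <- sort(sample.int(floor(dur), n_art))
        a_start <- span[["start"]] + (epochs - 1) + 0.3
        a_end <- a_start + 0.4
        ch <- sample.int(ncol(mat), n_art, replace = TRUE)
        for (k in seq_len(n_art)) {
          idx <- which(in_window(tt, a_start[k], a_end[k]))
          mat[idx, ch[k]] <- mat[idx, ch[k]] + 300
        }
        artifacts <- tibble::tibble(t_start_s = a_start, t_end_s = a_end,
                                    epoch = as.integer(epochs))
      }
    }
    list(
      recording = recording(mat, EEG_CHANNELS, fs = fs,
                            start_time = span[["start"]], units = "uV"),
      blinks = blinks,
      artifacts = artifacts
    )
  })
}

# Poisson blink times thinned to a physiological refractory gap (a blink
# cannot start during the previous one); returns the realized ground truth.
draw_blink_times <- function(cfg, t0, t1, refractory = 0.5) {
  dur <- t1 - t0
  n <- rpois(1, cfg$blink_rate * dur / 60)
  if (n == 0) {
    return(tibble::tibble(peak_time_s = numeric(), duration_ms = numeric(),
                          amplitude_uv = numeric()))
  }
  margin <- cfg$blink_duration / 1000 * blink_support_factor()
  times <- sort(runif(n, t0 + margin, t1 - margin))
  keep <- c(TRUE, diff(times) >= refractory)
  while (!all(keep)) {
    times <- times[keep]
    keep <- c(TRUE, diff(times) >= refractory)
  }
  tibble::tibble(peak_time_s = times,
                 duration_ms = rep(cfg$blink_duration, length(times)),
                 amplitude_uv = rep(cfg$blink_amplitude, length(times)))
}

add_blinks <- function(mat, blinks, fs, t0, cfg) {
  if (nrow(blinks) == 0) return(mat)
  gains <- BLINK_GAIN[colnames(mat)]
  for (b in seq_len(nrow(blinks))) {
    pulse <- blink_pulse(fs, blinks$duration_ms[b], blinks$amplitude_uv[b])
    half <- (length(pulse) + 1) %/% 2
    i0 <- round((blinks$peak_time_s[b] - t0) * fs) + 1L - half + 1L
    idx <- i0:(i0 + length(pulse) - 1L)
    ok <- idx >= 1L & idx <= nrow(mat)
    for (j in seq_len(ncol(mat))) {
      mat[idx[ok], j] <- mat[idx[ok], j] + gains[j] * pulse[ok]
    }
  }
  mat
}

#' Simulate the eyes-closed rest recording
#'
#' Alpha at `alpha_rest_amp` on the parietal channels (the session maximum
#' by construction whenever `alpha_rest_amp >= alpha_task_base_amp * a_max`),
#' 1/f noise, and no blinks (eyes closed).
#'
#' @inheritParams simulate_eeg
#' @param duration rest duration, s; must be >= 60.
#' @return An [recording()].
#' @export
simulate_rest_ec <- function(cfg, duration = cfg$rest_duration,
                             seed = cfg$seed + 1L) {
  if (duration < 60) abort("Eyes-closed rest must last at least 60 s.")
  fs <- cfg$fs_eeg
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    mat <- matrix(0, n, length(EEG_CHANNELS),
                  dimnames = list(NULL, EEG_CHANNELS))
    if (cfg$noise_1f_scale > 0) {
      for (j in seq_along(EEG_CHANNELS)) {
        mat[, j] <- cfg$noise_1f_scale * pink_noise(n)
      }
    }
    alpha <- cfg$alpha_rest_amp * sin(2 * pi * cfg$iaf * tt + runif(1, 0, 2 * pi))
    for (j in seq_along(EEG_CHANNELS)) {
      mat[, j] <- mat[, j] + ALPHA_GAIN[[EEG_CHANNELS[j]]] * alpha
    }
    recording(mat, EEG_CHANNELS, fs = fs, start_time = 0, units = "uV")
  })
}

#' Simulate wrist PPG with ground-truth inter-beat intervals
#'
#' Beat times integrate the instantaneous inter-beat interval
#' `IBI(t) = 60000 / hr(t) + lf_amp sin(2 pi lf_freq t) + hf_amp sin(2 pi
#' hf_freq t)` ms, where `hr(t)` is `mean_hr` plus, when a trajectory is
#' supplied, `hr_surge_bpm` scaled by the normalized fatigue envelope. The
#' waveform is a train of fixed-shape symmetric pulses centred at the beat
#' times; a fraction `ectopic_rate` of beats is displaced by +/-300 ms.
#'
#' @inheritParams simulate_eeg
#' @param traj optional [fatigue_trajectory()] coupling heart rate to the
#'   fatigue envelope via `cfg$hr_surge_bpm`.
#' @param duration recording duration, s; defaults to the task span.
#' @return A list with `recording` (single channel `PPG`, `fs_ppg` Hz),
#'   `beats` (tibble `beat_time_s`, `ectopic`) and `ibi` (ground-truth
#'   tibble `t_s`, `ibi_ms`, `ectopic` — intervals adjacent to a displaced
#'   beat are marked).
#' @export
simulate_ppg <- function(cfg, traj = NULL,
                         duration = cfg$lead_in +
                           cfg$n_segments * (cfg$segment_len + cfg$inter_segment_gap),
                         seed = cfg$seed + 2L) {
  fs <- cfg$fs_ppg
  env_norm <- if (!is.null(traj) && cfg$hr_surge_bpm > 0) {
    function(t) {
      (traj$envelope(t) - traj$base) / max(traj$a_max - traj$base, 1e-12)
    }
  } else {
    function(t) 0
  }
  with_seed(seed, {
    ibi_at <- function(t) {
      60000 / (cfg$mean_hr + cfg$hr_surge_bpm * env_norm(t)) +
        cfg$lf_amp * sin(2 * pi * cfg$lf_freq * t) +
        cfg$hf_amp * sin(2 * pi * cfg$hf_freq * t)
    }
    beats <- numeric(ceiling(duration / (60000 / cfg$mean_hr / 1000)) + 8L)
    beats[1] <- 0.5
    k <- 1L
    while (TRUE) {
      nxt <- beats[k] + ibi_at(beats[k]) / 1000
      if (nxt > duration - 0.5) break
      k <- k + 1L
      beats[k] <- nxt
    }
    beats <- beats[seq_len(k)]
    ectopic <- rep(FALSE, k)
    if (cfg$ectopic_rate > 0 && k > 4L) {
      cand <- which(runif(k) < cfg$ectopic_rate)
      cand <- setdiff(cand, c(1L, 2L, k - 1L, k))
      for (i in cand) {
        shift <- sample(c(-0.3, 0.3), 1L)
        moved <- beats[i] + shift
        if (moved - beats[i - 1L] > 0.3 && beats[i + 1L] - moved > 0.3) {
          beats[i] <- moved
          ectopic[i] <- TRUE
        }
      }
    }
    ibi_ms <- diff(beats) * 1000
    ibi_ectopic <- ectopic[-k] | ectopic[-1L]
    n <- round(duration * fs)
    x <- numeric(n)
    sigma <- 0.06
    half <- round(4 * sigma * fs)
    kernel_t <- (-half:half) / fs
    kernel <- exp(-kernel_t^2 / (2 * sigma^2))
    for (b in beats) {
      c0 <- round(b * fs) + 1L
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + kernel[ok]
    }
    list(
      recording = recording(matrix(x, ncol = 1), "PPG", fs = fs,
                            start_time = 0, units = "au"),
      beats = tibble::tibble(beat_time_s = beats, ectopic = ectopic),
      ibi = tibble::tibble(t_s = beats[-k], ibi_ms = ibi_ms,
                           ectopic = ibi_ectopic)
    )
  })
}

#' Simulate a complete session bundle
#'
#' @inheritParams simulate_eeg
#' @param traj optional trajectory; drawn with a uniform-random peak segment
#'   (bump shape) when omitted.
#' @param subject subject identifier stored in `meta`.
#' @param environment,location metadata tags carried through reporting.
#' @return A list of class `fl_session`: `eeg`, `ppg`, `rest_ec`,
#'   `schedule`, `meta`, and `truth` (trajectory, blink, artifact and IBI
#'   ground truth).
#' @export
simulate_session <- function(cfg, traj = NULL, subject = "S01",
                             environment = "Simulated", location = "Italy",
                             seed = cfg$seed) {
  schedule <- sim_schedule(cfg)
  if (is.null(traj)) {
    peak <- with_seed(seed + 3L, sample.int(cfg$n_segments, 1L))
    traj <- fatigue_trajectory(schedule, peak)
  }
  eeg <- simulate_eeg(cfg, traj, schedule, seed = seed)
  rest <- simulate_rest_ec(cfg, seed = seed + 1L)
  ppg <- simulate_ppg(cfg, traj, seed = seed + 2L)
  structure(list(
    eeg = eeg$recording, ppg = ppg$recording, rest_ec = rest,
    schedule = schedule,
    meta = list(subject = subject, environment = environment,
                location = location, seed = seed),
    truth = list(trajectory = traj, blinks = eeg$blinks,
                 artifacts = eeg$artifacts, beats = ppg$beats,
                 ibi = ppg$ibi, cfg = cfg)
  ), class = "fl_session")
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from the master seed;
#' each subject draws an IAF uniform in \[8, 12\] Hz, a mean heart rate
#' uniform in \[60, 80\] bpm, and an alpha-surge (peak) segment uniform over
#' the straight-road repetitions.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param cfg base [sim_config()]; per-subject fields are overridden by the
#'   draws above.
#' @param seed master seed.
#' @param sessions build the signal data (set `FALSE` to obtain only the
#'   per-subject ground-truth draws, e.g. for design checks).
#' @return A list with `sessions` (list of `fl_session`, `NULL` when
#'   `sessions = FALSE`) and `truth` (tibble: subject, seed, iaf, mean_hr,
#'   peak_segment, and n_blinks when sessions are built).
#' @export
simulate_cohort <- function(n_subjects, cfg = sim_config(), seed = cfg$seed,
                            sessions = TRUE) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  draws <- with_seed(seed, {
    tibble::tibble(
      subject = sprintf("S%02d", seq_len(n_subjects)),
      seed = sample.int(2^31 - 10, n_subjects) ,
      iaf = runif(n_subjects, 8, 12),
      mean_hr = runif(n_subjects, 60, 80),
      peak_segment = sample.int(cfg$n_segments, n_subjects, replace = TRUE)
    )
  })
  if (!sessions) {
    return(list(sessions = NULL, truth = draws))
  }
  built <- purrr::pmap(draws, function(subject, seed, iaf, mean_hr,
                                       peak_segment) {
    cfg_i <- cfg
    cfg_i$iaf <- iaf
    cfg_i$mean_hr <- mean_hr
    cfg_i$seed <- seed
    schedule <- sim_schedule(cfg_i)
    traj <- fatigue_trajectory(schedule, peak_segment)
    simulate_session(cfg_i, traj, subject = subject, seed = seed)
  })
  truth <- draws
  truth$n_blinks <- vapply(built, function(s) nrow(s$truth$blinks), 1L)
  list(sessions = built, truth = truth)
}
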