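#' PPG band-pass filtering
#'
#' Zero-phase 5th-order Butterworth band-pass (0.4-4 Hz) rejecting the DC
#' component and high-frequency movement interference, emphasizing the pulse
#' waves prior to beat detection.
#'
#' @param rec single-channel PPG [recording()]; 64 Hz expected (other rates
#'   accepted with a warning).
#' @param lo,hi band edges, Hz.
#' @param order Butterworth order (per pass).
#' @return A filtered [recording()].
#' @export
preprocess_ppg <- function(rec, lo = 0.4, hi = 4, order = 5) {
  fs <- rec_fs(rec)
  if (abs(fs - 64) > 1e-9) {
    warn(sprintf("PPG sampling rate is %.6g Hz (64 Hz expected).", fs))
  }
  bt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  apply_filtfilt(rec, bt$b, bt$a)
}

# AMPD (Automatic Multiscale-based Peak Detection) on one window: build the
# local-maxima scalogram over window scales 1..ceiling(L/2)-1, pick the scale
# lambda whose row has the most local maxima (minimal row-sum of the "not a
# maximum" indicator), and keep samples that are local maxima at every scale
# <= lambda. Deterministic binary formulation; the signal is linearly
# detrended first.
ampd <- function(x) {
  L <- length(x)
  if (L < 8L) return(integer())
  x <- x - (stats::lm.fit(cbind(1, seq_len(L)), x)$fitted.values)
  kmax <- as.integer(ceiling(L / 2) - 1)
  if (kmax < 1L) return(integer())
  gamma <- numeric(kmax)
  for (k in seq_len(kmax)) {
    mid <- x[(k + 1L):(L - k)]
    ismax <- mid > x[1L:(L - 2L * k)] & mid > x[(2L * k + 1L):L]
    gamma[k] <- L - sum(ismax) # boundary samples count as "not a maximum"
  }
  lambda <- which.min(gamma)
  ok <- rep(TRUE, L)
  for (k in seq_len(lambda)) {
    cond <- rep(FALSE, L)
    mid <- x[(k + 1L):(L - k)]
    cond[(k + 1L):(L - k)] <- mid > x[1L:(L - 2L * k)] & mid > x[(2L * k + 1L):L]
    ok <- ok & cond
  }
  which(ok)
}

#' Detect pulse beats in a PPG recording
#'
#' AMPD is applied on sliding windows (default 30 s advanced by 25 s, i.e. a
#' 5-s overlap; a final window anchored at the end covers the tail) and the
#' per-window detections are merged, removing duplicates closer than
#' `dedup` seconds at the seams. A window with no detected beat is skipped
#' with a warning.
#'
#' @param ppg preprocessed PPG [recording()] (see [preprocess_ppg()]).
#' @param window,step AMPD window length and advance, s.
#' @param dedup seam deduplication tolerance, s.
#' @return Numeric vector of beat times, s, strictly increasing.
#' @export
detect_beats <- function(ppg, window = 30, step = 25, dedup = 0.2) {
  fs <- rec_fs(ppg)
  x <- rec_matrix(ppg)[, 1L]
  t0 <- rec_start(ppg)
  dur <- length(x) / fs
  starts <- seq(0, max(0, dur - window), by = step)
  if (dur > window && max(starts) < dur - window) {
    starts <- c(starts, dur - window)
  }
  beats <- numeric()
  for (s in starts) {
    i0 <- round(s * fs)
    idx <- (i0 + 1L):min(length(x), i0 + round(window * fs))
    pk <- ampd(x[idx])
    if (!length(pk)) {
      warn(sprintf("No beat detected in window starting at %.1f s; skipped.", s))
      next
    }
    beats <- c(beats, t0 + (i0 + pk - 1) / fs)
  }
  beats <- sort(beats)
  if (length(beats) > 1L) {
    keep <- c(TRUE, diff(beats) > dedup)
    beats <- beats[keep]
  }
  beats
}

#' Inter-beat interval series from beat times
#'
#' @param beat_times strictly increasing beat times, s.
#' @return A tibble of class `fl_ibi` with columns `t_s` (time of the
#'   interval's first beat), `ibi_ms`, `corrected` (FALSE).
#' @export
ibi_series <- function(beat_times) {
  if (is.unsorted(beat_times, strictly = TRUE)) {
    abort("`beat_times` must be strictly increasing.")
  }
  n <- length(beat_times)
  if (n < 2L) abort("Need at least 2 beats for an IBI series.")
  out <- tibble::tibble(t_s = beat_times[-n],
                        ibi_ms = diff(beat_times) * 1000,
                        corrected = FALSE)
  structure(out, class = c("fl_ibi", class(out)))
}

#' Outlier correction and smoothing of an IBI series
#'
#' One coherent pass over the IBI sequence (never the PPG waveform):
#' (1) linear detrend; (2) flag intervals whose detrended value deviates
#' from the detrended mean by more than `sd_mult` standard deviations;
#' (3) replace each flagged interval by the mean of up to two non-flagged
#' neighbours on each side; (4) smooth with a centred moving average
#' (default 5 points, shrinking at the edges). The `corrected` column marks
#' replacements.
#'
#' The smoothed values (`ibi_smooth_ms`) serve trend-level quantities such
#' as heart rate; spectral HRV is computed from the outlier-replaced but
#' unsmoothed `ibi_ms`, because a moving average over beats acts as a
#' low-pass on the interval series and would suppress the HF band at
#' ordinary heart rates.
#'
#' @param ibi `fl_ibi` from [ibi_series()] (>= 10 intervals).
#' @param sd_mult outlier threshold in standard deviations.
#' @param ma_points moving-average window length, points (odd).
#' @return The corrected `fl_ibi` with columns `ibi_ms` (outlier-replaced),
#'   `ibi_smooth_ms` (additionally smoothed) and `corrected`.
#' @export
correct_ibi <- function(ibi, sd_mult = 2, ma_points = 5) {
  y <- ibi$ibi_ms
  n <- length(y)
  if (n < 10L) abort("Need at least 10 IBIs for correction.")
  det <- y - stats::lm.fit(cbind(1, seq_len(n)), y)$fitted.values
  s <- sd(det)
  flag <- if (s > 0) abs(det - mean(det)) > sd_mult * s else rep(FALSE, n)
  if (mean(flag) > 0.5) abort("IBI series unusable: > 50% flagged as outliers.")
  z <- y
  if (any(flag)) {
    good <- which(!flag)
    for (i in which(flag)) {
      lower <- rev(good[good < i])
      upper <- good[good > i]
      nb <- c(utils::head(lower, 2L), utils::head(upper, 2L))
      if (length(nb)) z[i] <- mean(y[nb])
    }
  }
  half <- (ma_points - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    mean(z[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  out <- ibi
  out$ibi_ms <- z
  out$ibi_smooth_ms <- sm
  out$corrected <- flag
  out
}

#' Heart rate per analysis window
#'
#' HR over a window is `60000 / mean(IBI in window)` bpm; windows with fewer
#' than 3 intervals are missing.
#'
#' @param ibi (corrected) `fl_ibi`.
#' @param windows data frame with `t_start_s`, `t_end_s`; when omitted the
#'   IBI span is tiled with `window`-second windows.
#' @param window tiling window length, s.
#' @return A tibble `t_start_s`, `t_end_s`, `n_beats`, `hr_bpm`.
#' @export
heart_rate <- function(ibi, windows = NULL, window = 60) {
  windows <- windows %||% tile_windows(ibi$t_s, window)
  vals <- if ("ibi_smooth_ms" %in% names(ibi)) ibi$ibi_smooth_ms else ibi$ibi_ms
  purrr::pmap_dfr(windows[, c("t_start_s", "t_end_s")],
    function(t_start_s, t_end_s) {
      sel <- in_window(ibi$t_s, t_start_s, t_end_s)
      tibble::tibble(
        t_start_s = t_start_s, t_end_s = t_end_s, n_beats = sum(sel),
        hr_bpm = if (sum(sel) >= 3L) 60000 / mean(vals[sel]) else NA_real_
      )
    })
}

tile_windows <- function(t, window) {
  t0 <- floor(min(t) / window) * window
  starts <- seq(t0, max(t), by = window)
  tibble::tibble(t_start_s = starts, t_end_s = starts + window)
}

#' Lomb-Scargle periodogram
#'
#' Classical Lomb normalized periodogram of an unevenly sampled series
#' (mean subtracted; normalized by the series variance). On evenly sampled
#' input it agrees with the classical periodogram up to normalization.
#'
#' @param t sample times, s.
#' @param y sample values.
#' @param freq frequencies to evaluate, Hz (> 0).
#' @return A tibble `freq_hz`, `power`.
#' @export
lomb_periodogram <- function(t, y, freq) {
  if (length(t) != length(y)) abort("`t` and `y` lengths differ.")
  yc <- y - mean(y)
  v <- stats::var(y)
  if (v <= 0) {
    return(tibble::tibble(freq_hz = freq, power = rep(0, length(freq))))
  }
  power <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 / v * ((sum(yc * ct))^2 / sum(ct^2) + (sum(yc * st))^2 / sum(st^2))
  }, numeric(1))
  tibble::tibble(freq_hz = freq, power = power)
}

#' Frequency-domain heart rate variability per analysis window
#'
#' Computes the Lomb-Scargle periodogram of the (unevenly sampled) IBI
#' values at their beat times on a fixed grid (default 0.003-0.5 Hz, 0.0025
#' Hz step), then the normalized band powers LF (0.04-0.15 Hz) and HF
#' (0.15-0.4 Hz) — each a fraction of the total spectral power on the grid —
#' and their ratio HRV = LF/HF. Windows with fewer than 30 beats yield
#' missing features.
#'
#' @inheritParams heart_rate
#' @param f_lo,f_hi,f_step frequency grid, Hz.
#' @param lf_band,hf_band band limits, Hz.
#' @return A tibble `t_start_s`, `t_end_s`, `n_beats`, `lf`, `hf`, `hrv`.
#' @export
hrv_spectral <- function(ibi, windows = NULL, window = 60,
                         f_lo = 0.003, f_hi = 0.5, f_step = 0.0025,
                         lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4)) {
  windows <- windows %||% tile_windows(ibi$t_s, window)
  freq <- seq(f_lo, f_hi, by = f_step)
  purrr::pmap_dfr(windows[, c("t_start_s", "t_end_s")],
    function(t_start_s, t_end_s) {
      sel <- in_window(ibi$t_s, t_start_s, t_end_s)
      nb <- sum(sel)
      if (nb < 30L) {
        return(tibble::tibble(t_start_s = t_start_s, t_end_s = t_end_s,
                              n_beats = nb, lf = NA_real_, hf = NA_real_,
                              hrv = NA_real_))
      }
      pg <- lomb_periodogram(ibi$t_s[sel], ibi$ibi_ms[sel], freq)
      total <- sum(pg$power)
      bp <- function(band) {
        sum(pg$power[pg$freq_hz >= band[1] & pg$freq_hz < band[2]]) / total
      }
      lf <- bp(lf_band)
      hf <- bp(hf_band)
      tibble::tibble(t_start_s = t_start_s, t_end_s = t_end_s, n_beats = nb,
                     lf = lf, hf = hf,
                     hrv = if (hf > 0) lf / hf else NA_real_)
    })
}
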