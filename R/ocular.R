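#' Detect eyeblinks on a single frontal EEG channel
#'
#' Blinks are captured as vertical-EOG transients on AFz. The detector:
#' (1) low-passes the channel (default 8 Hz); (2) subtracts a sliding local
#' baseline (median over +/- `baseline_halfwidth` s); (3) auto-detects the
#' blink polarity (sign of the largest deviation) and rectifies; (4) marks
#' candidate peaks where the deviation exceeds an adaptive threshold of
#' `mad_mult` times a sliding MAD-based noise estimate, with a minimum peak
#' separation (default 200 ms); (5) locates onset/offset as the nearest
#' crossings of `height_frac` (default 10%) of the peak height; (6) discards
#' events with duration outside \[50, 1000\] ms. Amplitude is measured on
#' the raw baseline-subtracted channel at the peak, so the low-pass
#' smoothing does not bias it.
#'
#' @param rec an [recording()] containing `channel`; the signal should be
#'   band-limited below ~40 Hz (raw or notch-filtered EEG is fine; avoid the
#'   2 Hz high-pass, which distorts blink morphology).
#' @param channel channel to use (default `"AFz"`).
#' @param lowpass detector low-pass cut-off, Hz.
#' @param baseline_halfwidth sliding-median half-width, s.
#' @param mad_mult adaptive threshold in sliding-MAD units.
#' @param min_sep minimum separation between detected peaks, s.
#' @param height_frac onset/offset crossing level as a fraction of peak
#'   height.
#' @return A tibble of class `fl_blinks` with columns `peak_time_s`,
#'   `onset_s`, `offset_s`, `amplitude_uv`, `duration_ms`, sorted by peak
#'   time.
#' @export
detect_blinks <- function(rec, channel = "AFz", lowpass = 8,
                          baseline_halfwidth = 2, mad_mult = 3,
                          min_sep = 0.2, height_frac = 0.1) {
  if (!channel %in% rec_channels(rec)) {
    abort(paste0("Channel '", channel, "' not present in the recording."))
  }
  fs <- rec_fs(rec)
  x_raw <- rec_matrix(rec)[, match(channel, rec_channels(rec))]
  bt <- signal::butter(4, lowpass / (fs / 2), type = "low")
  x <- signal::filtfilt(bt$b, bt$a, x_raw)
  k <- 2L * round(baseline_halfwidth * fs) + 1L
  k <- min(k, if (length(x) %% 2L == 0L) length(x) - 1L else length(x))
  base <- stats::runmed(x, k, endrule = "median")
  d <- x - base
  # polarity auto-detect: blinks are the dominant deviations
  if (abs(min(d)) > abs(max(d))) {
    d <- -d
    x_raw <- -x_raw
  }
  base_raw <- stats::runmed(x_raw, k, endrule = "median")
  noise <- 1.4826 * stats::runmed(abs(d), k, endrule = "median")
  thr <- mad_mult * noise
  n <- length(d)
  is_peak <- c(FALSE, d[2:(n - 1)] >= d[1:(n - 2)] &
                 d[2:(n - 1)] > d[3:n], FALSE) & d > thr & d > 0
  cand <- which(is_peak)
  if (!length(cand)) return(empty_blinks())
  # a genuine blink stays above the adaptive threshold for a sustained run,
  # while threshold-grazing noise excursions exceed it only briefly; require
  # the suprathreshold run around the peak to last at least the 50 ms lower
  # duration bound
  sustain <- round(0.05 * fs)
  cand <- cand[vapply(cand, function(i) {
    j0 <- i
    while (j0 > 1L && d[j0 - 1L] > thr[j0 - 1L]) j0 <- j0 - 1L
    j1 <- i
    while (j1 < n && d[j1 + 1L] > thr[j1 + 1L]) j1 <- j1 + 1L
    (j1 - j0 + 1L) >= sustain
  }, logical(1))]
  if (!length(cand)) return(empty_blinks())
  # enforce minimum separation, keeping the taller peak
  ord <- cand[order(d[cand], decreasing = TRUE)]
  kept <- integer()
  sep <- round(min_sep * fs)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= sep)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  t0 <- rec_start(rec)
  events <- purrr::map_dfr(kept, function(i) {
    level <- height_frac * d[i]
    j0 <- i
    while (j0 > 1L && d[j0] > level) j0 <- j0 - 1L
    j1 <- i
    while (j1 < n && d[j1] > level) j1 <- j1 + 1L
    # sub-sample crossing times by linear interpolation between the last
    # sample above the level and the first at/below it
    f0 <- if (j0 < i && d[j0 + 1L] != d[j0]) {
      (level - d[j0]) / (d[j0 + 1L] - d[j0])
    } else 0
    f1 <- if (j1 > i && d[j1 - 1L] != d[j1]) {
      (d[j1 - 1L] - level) / (d[j1 - 1L] - d[j1])
    } else 0
    on <- (j0 - 1 + f0) / fs
    off <- (j1 - 1 - 1 + f1) / fs
    win <- max(1L, i - round(0.04 * fs)):min(n, i + round(0.04 * fs))
    tibble::tibble(
      peak_time_s = t0 + (i - 1) / fs,
      onset_s = t0 + on,
      offset_s = t0 + off,
      amplitude_uv = max(x_raw[win] - base_raw[win]),
      duration_ms = (off - on) * 1000
    )
  })
  events <- events[events$duration_ms >= 50 & events$duration_ms <= 1000 &
                     events$amplitude_uv > 0, ]
  structure(events, class = c("fl_blinks", class(events)))
}

empty_blinks <- function() {
  structure(
    tibble::tibble(peak_time_s = numeric(), onset_s = numeric(),
                   offset_s = numeric(), amplitude_uv = numeric(),
                   duration_ms = numeric()),
    class = c("fl_blinks", class(tibble::tibble())))
}

#' Blink features per analysis window
#'
#' Events are assigned to windows by peak time, half-open, so each blink is
#' counted exactly once over a disjoint tiling. EBR is the blink count per
#' minute; EBD and EBA are the mean duration (ms) and mean amplitude (uV) of
#' the window's blinks, missing when the window holds none.
#'
#' @param events `fl_blinks` from [detect_blinks()].
#' @param windows data frame with columns `t_start_s`, `t_end_s` (one row
#'   per analysis window), or a length-2 numeric vector for a single window.
#' @return A tibble with columns `t_start_s`, `t_end_s`, `n_blinks`, `ebr`
#'   (blinks/min), `ebd` (ms), `eba` (uV).
#' @export
blink_features <- function(events, windows) {
  if (is.numeric(windows) && length(windows) == 2L) {
    windows <- tibble::tibble(t_start_s = windows[1], t_end_s = windows[2])
  }
  windows <- tibble::as_tibble(windows)[, c("t_start_s", "t_end_s")]
  if (any(windows$t_end_s <= windows$t_start_s)) {
    abort("Windows must have positive duration.")
  }
  purrr::pmap_dfr(windows, function(t_start_s, t_end_s) {
    sel <- in_window(events$peak_time_s, t_start_s, t_end_s)
    nb <- sum(sel)
    tibble::tibble(
      t_start_s = t_start_s, t_end_s = t_end_s, n_blinks = nb,
      ebr = nb / ((t_end_s - t_start_s) / 60),
      ebd = if (nb) mean(events$duration_ms[sel]) else NA_real_,
      eba = if (nb) mean(events$amplitude_uv[sel]) else NA_real_
    )
  })
}
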