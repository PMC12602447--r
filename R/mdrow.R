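#' Estimate the Individual Alpha Frequency from eyes-closed rest
#'
#' The IAF anchors the subject-specific "strict" alpha band, IAF +/- 1 Hz.
#' It is estimated as the frequency of the maximum of the parietal-averaged
#' Welch power spectrum within the search band. When the maximum falls on a
#' search-band boundary or the band holds no interior local maximum, the
#' spectrum has no distinct alpha peak; the argmax is still returned,
#' flagged.
#'
#' @param rest_ec eyes-closed rest [recording()] (>= 60 s, parietal
#'   channels present).
#' @param search_lo,search_hi search band, Hz.
#' @param seg_len Welch segment length, s (frequency resolution
#'   `1/seg_len` Hz); segments overlap by half.
#' @return A list of class `fl_alpha_spec`: `iaf`, `band_lo = iaf - 1`,
#'   `band_hi = iaf + 1`, `no_distinct_peak`, and the averaged `spectrum`
#'   tibble.
#' @export
estimate_iaf <- function(rest_ec, search_lo = 7, search_hi = 13, seg_len = 8) {
  check_eeg_channels(rest_ec, need = PARIETAL)
  if (rec_duration(rest_ec) < 60) {
    abort("Eyes-closed rest must be at least 60 s for IAF estimation.")
  }
  fs <- rec_fs(rest_ec)
  nseg <- round(seg_len * fs)
  mat <- rec_matrix(rest_ec)[, PARIETAL, drop = FALSE]
  w <- hann_window(nseg)
  starts <- seq(1L, nrow(mat) - nseg + 1L, by = nseg %/% 2L)
  psd <- 0
  for (s in starts) {
    seg <- mat[s:(s + nseg - 1L), , drop = FALSE] * w
    X <- stats::mvfft(seg)
    psd <- psd + rowMeans(Mod(X)^2)
  }
  psd <- psd / length(starts)
  freq <- (seq_len(nseg) - 1) * fs / nseg
  keep <- freq <= fs / 2
  spectrum <- tibble::tibble(freq_hz = freq[keep], power = psd[keep])
  band <- which(spectrum$freq_hz >= search_lo & spectrum$freq_hz <= search_hi)
  p <- spectrum$power[band]
  imax <- which.max(p)
  # a distinct peak is interior to the search band and stands out from the
  # band's background (a flat or monotone spectrum fails both ways)
  interior_peak <- imax > 1 && imax < length(p) &&
    p[imax] > p[imax - 1] && p[imax] > p[imax + 1] &&
    p[imax] >= 2 * median(p)
  if (!interior_peak) {
    warn("No distinct alpha peak in the search band; using the argmax.")
  }
  iaf <- spectrum$freq_hz[band[imax]]
  structure(list(iaf = iaf, band_lo = iaf - 1, band_hi = iaf + 1,
                 no_distinct_peak = !interior_peak, spectrum = spectrum),
            class = "fl_alpha_spec")
}

#' @export
print.fl_alpha_spec <- function(x, ...) {
  cat(sprintf("<alpha spec> IAF %.3g Hz, strict band [%.3g, %.3g] Hz%s\n",
              x$iaf, x$band_lo, x$band_hi,
              if (x$no_distinct_peak) " (no distinct peak)" else ""))
  invisible(x)
}

#' Parietal strict-alpha Global Field Power per epoch
#'
#' For each retained (non-rejected, non-blink) 1-s epoch, each parietal
#' channel's periodogram is computed with a Hanning taper of the epoch
#' length (1 Hz frequency resolution for 1-s epochs); the channel's alpha
#' power is the sum of periodogram bins whose centre frequency lies in the
#' strict band, and the GFP value is the mean of the channel alpha powers
#' over Pz, P3, P4.
#'
#' @param rec preprocessed EEG [recording()].
#' @param grid `fl_epochs` from [epoch_reject()] (optionally blink-flagged).
#' @param spec `fl_alpha_spec` from [estimate_iaf()].
#' @param channels parietal channels to average.
#' @param exclude_blinks drop blink-flagged epochs as well as rejected ones.
#' @return A tibble of class `fl_gfp` with columns `epoch`, `t_start_s`,
#'   `gfp` (uV^2), and attributes `channels`, `band`, `epoch_len`.
#' @export
alpha_gfp <- function(rec, grid, spec, channels = PARIETAL,
                      exclude_blinks = TRUE) {
  missing <- setdiff(channels, rec_channels(rec))
  if (length(missing)) {
    abort(paste0("Missing parietal channel(s): ", paste(missing, collapse = ", ")))
  }
  fs <- rec_fs(rec)
  len <- attr(grid, "epoch_len")
  spe <- round(len * fs)
  keep <- !grid$reject
  if (exclude_blinks) keep <- keep & !grid$blink
  kept <- grid[keep, ]
  if (nrow(kept) == 0) abort("No retained epochs.")
  w <- hann_window(spe)
  freq <- (seq_len(spe) - 1) * fs / spe
  bins <- which(freq >= spec$band_lo & freq <= spec$band_hi & freq <= fs / 2)
  if (!length(bins)) abort("Strict alpha band contains no frequency bins.")
  scale <- 2 / (fs * sum(w^2))
  mat <- rec_matrix(rec)
  t0 <- rec_start(rec)
  power <- matrix(0, nrow(kept), length(channels))
  for (j in seq_along(channels)) {
    x <- mat[, match(channels[j], rec_channels(rec))]
    idx0 <- round((kept$t_start_s - t0) * fs)
    segs <- vapply(idx0, function(i) x[(i + 1L):(i + spe)], numeric(spe))
    X <- stats::mvfft(segs * w)
    P <- scale * Mod(X[bins, , drop = FALSE])^2
    power[, j] <- colSums(P)
  }
  out <- tibble::tibble(epoch = kept$epoch, t_start_s = kept$t_start_s,
                        gfp = rowMeans(power))
  structure(out, channels = channels,
            band = c(spec$band_lo, spec$band_hi), epoch_len = len,
            class = c("fl_gfp", class(out)))
}

#' MDrow mental-drowsiness index series
#'
#' The index is the ratio of task strict-alpha parietal GFP to the maximum
#' strict-alpha parietal GFP during the eyes-closed rest:
#' `MDrow = alpha GFP task / max(alpha GFP rest)`. The closer the ratio is
#' to 1 (or above), the drowsier the subject. The per-epoch series is
#' stabilized over sliding windows (default 60-s windows advancing by 15 s,
#' i.e. a 15-s output resolution); a window retaining fewer than
#' `min_epochs` epochs is reported missing.
#'
#' @param task_gfp,rest_gfp `fl_gfp` series from [alpha_gfp()] for the task
#'   and the eyes-closed rest.
#' @param window,step window length and advance, s.
#' @param min_epochs minimum retained epochs for a window value.
#' @param rest_stat `"max"` (literal maximum over retained rest epochs) or
#'   `"q95"` (robust 95th percentile, guarding against a single noisy rest
#'   epoch deflating the whole series).
#' @return A tibble of class `fl_mdrow` with columns `window_start_s`,
#'   `n_epochs`, `mdrow`, and attributes `rest_denominator`, `window`,
#'   `step`.
#' @export
compute_mdrow <- function(task_gfp, rest_gfp, window = 60, step = 15,
                          min_epochs = 30, rest_stat = c("max", "q95")) {
  rest_stat <- match.arg(rest_stat)
  if (nrow(rest_gfp) == 0) abort("Empty rest GFP series.")
  if (nrow(task_gfp) == 0) abort("Empty task GFP series.")
  den <- switch(rest_stat,
    max = max(rest_gfp$gfp),
    q95 = unname(quantile(rest_gfp$gfp, 0.95, type = 7))
  )
  if (!is.finite(den) || den <= 0) {
    abort("Rest GFP denominator is zero or non-finite.")
  }
  len <- attr(task_gfp, "epoch_len") %||% 1
  t0 <- min(task_gfp$t_start_s)
  t1 <- max(task_gfp$t_start_s) + len
  starts <- seq(t0, t1 - window, by = step)
  vals <- vapply(starts, function(s) {
    g <- task_gfp$gfp[in_window(task_gfp$t_start_s, s, s + window)]
    if (length(g) < min_epochs) NA_real_ else mean(g) / den
  }, numeric(1))
  ns <- vapply(starts, function(s) {
    sum(in_window(task_gfp$t_start_s, s, s + window))
  }, numeric(1))
  out <- tibble::tibble(window_start_s = starts, n_epochs = as.integer(ns),
                        mdrow = vals)
  structure(out, rest_denominator = den, window = window, step = step,
            class = c("fl_mdrow", class(out)))
}
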