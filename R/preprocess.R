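#' EEG filtering
#'
#' `notch_50()` removes mains interference with a zero-phase second-order
#' IIR notch (default Q = 30); `bandpass_2_40()` applies a zero-phase
#' 4th-order Butterworth band-pass. Both run forward-backward
#' ([signal::filtfilt()]), so the group delay is zero and blink/alpha timing
#' is undistorted. The band-pass design cut-offs are widened numerically so
#' that the half-power points of the combined two-pass response sit at the
#' nominal edges (a filter designed at the nominal edges would put them
#' about 10% inside the band after the second pass).
#'
#' @param rec an [recording()].
#' @param freq notch centre frequency, Hz.
#' @param q notch quality factor (centre / -3 dB bandwidth).
#' @return A filtered [recording()].
#' @export
notch_50 <- function(rec, freq = 50, q = 30) {
  fs <- rec_fs(rec)
  if (fs <= 2 * freq) {
    abort(sprintf("Sampling rate %.6g Hz too low for a %g Hz notch.", fs, freq))
  }
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  apply_filtfilt(rec, b, a)
}

#' @rdname notch_50
#' @param lo,hi band edges, Hz.
#' @param order Butterworth order (per pass).
#' @export
bandpass_2_40 <- function(rec, lo = 2, hi = 40, order = 4) {
  fs <- rec_fs(rec)
  if (fs <= 2 * hi) {
    abort(sprintf("Sampling rate %.6g Hz too low for a %g Hz band edge.", fs, hi))
  }
  # widen each design edge so the *two-pass* amplitude at the nominal edge
  # is 1/sqrt(2); |H|^2 at the edge must then equal 2^(-1/2)
  gain2 <- function(bt, f) {
    w <- 2 * pi * f / fs
    h <- sum(bt$b * exp(-1i * w * (seq_along(bt$b) - 1))) /
      sum(bt$a * exp(-1i * w * (seq_along(bt$a) - 1)))
    Mod(h)^2
  }
  design <- function(a, b) {
    signal::butter(order, c(lo * a, hi * b) / (fs / 2), type = "pass")
  }
  target <- 2^(-1 / 2)
  a <- stats::uniroot(function(a) gain2(design(a, 1.1), lo) - target,
                      c(0.5, 1))$root
  b_max <- min(1.5, 0.99 * (fs / 2) / hi)
  b <- stats::uniroot(function(b) gain2(design(a, b), hi) - target,
                      c(1.0001, b_max))$root
  bt <- design(a, b)
  apply_filtfilt(rec, bt$b, bt$a)
}

apply_filtfilt <- function(rec, b, a) {
  mat <- rec_matrix(rec)
  out <- apply(mat, 2L, function(x) signal::filtfilt(b, a, x))
  rec_update(rec, out)
}

#' Epoching and amplitude-based artifact rejection
#'
#' Splits a recording into non-overlapping epochs (trailing partial epoch
#' dropped) and flags every epoch in which any channel exceeds the amplitude
#' threshold. The per-channel rejection fraction counts an epoch against a
#' channel only when that channel itself exceeds the threshold.
#'
#' @param rec a filtered EEG [recording()] in microvolts.
#' @param epoch_len epoch length, s.
#' @param threshold rejection threshold, uV; an epoch is rejected iff any
#'   sample on any channel has `|value| > threshold`.
#' @return An epoch-grid tibble of class `fl_epochs` with columns `epoch`,
#'   `t_start_s`, `reject`, `blink`, and attributes `epoch_len` and
#'   `channel_rejection` (tibble of per-channel rejection fractions).
#' @export
epoch_reject <- function(rec, epoch_len = 1, threshold = 200) {
  fs <- rec_fs(rec)
  spe <- round(epoch_len * fs)
  n_epochs <- nrow(rec) %/% spe
  if (n_epochs < 1) abort("Recording shorter than one epoch.")
  mat <- rec_matrix(rec)[seq_len(n_epochs * spe), , drop = FALSE]
  epoch_of <- rep(seq_len(n_epochs), each = spe)
  over <- abs(mat) > threshold
  by_channel <- rowsum(over + 0, epoch_of) > 0  # epochs x channels
  reject <- rowSums(by_channel) > 0
  grid <- tibble::tibble(
    epoch = seq_len(n_epochs),
    t_start_s = rec_start(rec) + (seq_len(n_epochs) - 1) * epoch_len,
    reject = unname(reject),
    blink = FALSE
  )
  structure(grid,
    epoch_len = epoch_len,
    channel_rejection = tibble::tibble(
      channel = rec_channels(rec),
      fraction = unname(colMeans(by_channel))
    ),
    class = c("fl_epochs", class(grid)))
}

#' Flag epochs overlapping blink events
#'
#' Marks, in the epoch grid's `blink` column, every epoch whose half-open
#' interval overlaps a blink interval. Downstream alpha/GFP computation
#' excludes epochs flagged either for amplitude artifacts or for blinks;
#' this flag-and-exclude handling replaces template-based blink correction
#' and is conservative: the drowsiness index uses parietal channels, where
#' blink contamination is smallest.
#'
#' @param grid an `fl_epochs` from [epoch_reject()].
#' @param blinks tibble of blink events with either `onset_s`/`offset_s`
#'   columns ([detect_blinks()] output) or `peak_time_s`/`duration_ms`
#'   (generator ground truth; the interval is centred on the peak).
#' @return The updated `fl_epochs`.
#' @export
flag_blink_epochs <- function(grid, blinks) {
  if (nrow(blinks) == 0) return(grid)
  if (all(c("onset_s", "offset_s") %in% names(blinks))) {
    on <- blinks$onset_s
    off <- blinks$offset_s
  } else if (all(c("peak_time_s", "duration_ms") %in% names(blinks))) {
    half <- blinks$duration_ms / 2000
    on <- blinks$peak_time_s - half
    off <- blinks$peak_time_s + half
  } else {
    abort("`blinks` needs onset_s/offset_s or peak_time_s/duration_ms columns.")
  }
  len <- attr(grid, "epoch_len")
  e_start <- grid$t_start_s
  e_end <- e_start + len
  flag <- grid$blink
  for (b in seq_along(on)) {
    flag <- flag | (e_start < off[b] & e_end > on[b])
  }
  grid$blink <- flag
  grid
}

#' @export
print.fl_epochs <- function(x, ...) {
  cat(sprintf("<epoch grid> %d epochs of %g s; %d rejected, %d blink-flagged\n",
              nrow(x), attr(x, "epoch_len"), sum(x$reject), sum(x$blink)))
  NextMethod()
}
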